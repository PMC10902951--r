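#' Network hyperparameter configuration
#'
#' Defaults follow the reference setting of the method: hidden layers of
#' 1000 and 500 units, an embedding of 10/20/50 units, learning rate from
#' {1e-6, 1e-7, 1e-8}, at most 2000 epochs, and task weights
#' `gamma = 1` (reconstruction) and `beta = 10` (clustering). The Cox
#' partial-likelihood task always has weight 1. Small cohorts train fine
#' with far smaller layers and a larger learning rate; see the vignette.
#'
#' @param n_hidden1,n_hidden2 Encoder hidden layer widths.
#' @param n_embedding Width of the embedding (bottleneck) layer.
#' @param learning_rate Optimizer step size.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param gamma Weight of the reconstruction loss.
#' @param beta Weight of the clustering loss.
#' @param dropout_rate Dropout probability after each hidden layer.
#' @param weight_decay L2 penalty on all weights and biases.
#' @param cluster_warmup Fraction of epochs trained before the clustering
#'   task switches on. Soft assignments sharpened from a randomly
#'   initialized embedding only amplify noise, so cluster centers are
#'   initialized (and the KL term activated) after the embedding has had
#'   this warm-up; 0 enables clustering from the first epoch.
#' @param k_range Integer interval of candidate cluster counts.
#' @param seed Integer seed for initialization, dropout and clustering.
#' @return A `network_config` list.
#' @export
network_config <- function(n_hidden1 = 1000, n_hidden2 = 500,
                           n_embedding = 20, learning_rate = 1e-6,
                           max_epochs = 2000, gamma = 1, beta = 10,
                           dropout_rate = 0.1, weight_decay = 1e-5,
                           cluster_warmup = 0.5, k_range = c(2L, 4L),
                           seed = 1) {
  cfg <- list(n_hidden1 = as.integer(n_hidden1),
              n_hidden2 = as.integer(n_hidden2),
              n_embedding = as.integer(n_embedding),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              gamma = gamma, beta = beta,
              dropout_rate = dropout_rate, weight_decay = weight_decay,
              cluster_warmup = cluster_warmup,
              k_range = as.integer(k_range), seed = as.integer(seed))
  stopifnot(cfg$n_hidden1 >= 1, cfg$n_hidden2 >= 1, cfg$n_embedding >= 1,
            cfg$max_epochs >= 1, cfg$learning_rate > 0,
            cfg$gamma >= 0, cfg$beta >= 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$weight_decay >= 0,
            cfg$cluster_warmup >= 0, cfg$cluster_warmup < 1,
            length(cfg$k_range) == 2L,
            cfg$k_range[1L] >= 2L, cfg$k_range[2L] >= cfg$k_range[1L])
  class(cfg) <- "network_config"
  cfg
}

layer_names <- c("sp", "e1", "e2", "em", "d1", "d2", "out", "rk")

#' Initialize model weights for a pathway-masked network
#'
#' Layer sizes are input p -> q (sparse, gated by the pathway mask) ->
#' `n_hidden1` -> `n_hidden2` -> `n_embedding`; the decoder mirrors the
#' encoder back to p with a linear output; the risk head is one linear unit
#' on the embedding. Weights are uniform in `+/- 1/sqrt(fan_in)`, seeded;
#' biases start at zero. Masked sparse-layer weights are structurally inert:
#' they are zeroed at init and their gradient is zero throughout.
#'
#' @param config A `network_config`.
#' @param mask A `pathway_mask` whose gene count defines the input width.
#' @return A `survnet_model`: list with `config`, `mask`, weight list `W`,
#'   bias list `b`, and (after training) `centers`, `labels`, `k`.
#' @export
init_model <- function(config, mask) {
  stopifnot(inherits(config, "network_config"), inherits(mask, "pathway_mask"))
  p <- ncol(mask$matrix); q <- nrow(mask$matrix)
  if (config$n_embedding >= config$n_hidden2) {
    stop("n_embedding (", config$n_embedding,
         ") must be smaller than n_hidden2 (", config$n_hidden2,
         "): the embedding must compress")
  }
  dims <- list(sp = c(p, q), e1 = c(q, config$n_hidden1),
               e2 = c(config$n_hidden1, config$n_hidden2),
               em = c(config$n_hidden2, config$n_embedding),
               d1 = c(config$n_embedding, config$n_hidden2),
               d2 = c(config$n_hidden2, config$n_hidden1),
               out = c(config$n_hidden1, p),
               rk = c(config$n_embedding, 1L))
  set.seed(derive_seed(config$seed, "init"))
  W <- lapply(dims, function(d) {
    lim <- 1 / sqrt(d[1L])
    matrix(stats::runif(d[1L] * d[2L], -lim, lim), d[1L], d[2L])
  })
  b <- lapply(dims, function(d) numeric(d[2L]))
  W$sp <- W$sp * t(mask$matrix)
  structure(list(config = config, mask = mask, W = W, b = b,
                 centers = NULL, labels = NULL, k = NULL,
                 input_center = NULL, input_scale = NULL),
            class = "survnet_model")
}

#' @export
print.survnet_model <- function(x, ...) {
  cat(sprintf(paste0("survnet_model: %d genes -> %d pathways -> %d -> %d -> ",
                     "%d embedding; k = %s\n"),
              nrow(x$W$sp), ncol(x$W$sp), x$config$n_hidden1,
              x$config$n_hidden2, x$config$n_embedding,
              if (is.null(x$k)) "unset" else x$k))
  invisible(x)
}

# Sample dropout structures. `unit = TRUE` returns per-unit keep vectors
# (one thinned subnetwork, shared by every row -- used by the MC-dropout
# attribution runs); otherwise per-element masks as in ordinary training.
# Inverted dropout: kept units are scaled by 1/(1-rate).
sample_dropout <- function(rate, n, widths, unit = FALSE) {
  if (rate <= 0) return(NULL)
  lapply(widths, function(w) {
    if (unit) {
      stats::rbinom(w, 1L, 1 - rate) / (1 - rate)
    } else {
      matrix(stats::rbinom(n * w, 1L, 1 - rate) / (1 - rate), n, w)
    }
  })
}

apply_mask <- function(H, m) {
  if (is.null(m)) return(H)
  if (is.matrix(m)) H * m else sweep(H, 2L, m, `*`)
}

#' Forward pass through the network
#'
#' ReLU activations at the sparse layer, both hidden layers, and the
#' embedding; the decoder output and the risk head are linear. Dropout
#' (when enabled) acts after the two encoder hidden layers and the two
#' decoder hidden layers, never after the sparse layer or on the embedding.
#'
#' @param model A `survnet_model`.
#' @param X Numeric n x p matrix, columns in the model's gene order.
#' @param dropout_on Sample and apply dropout masks (training / MC runs).
#' @param masks Optional pre-sampled dropout masks (list `e1`, `e2`, `d1`,
#'   `d2` of per-unit vectors or per-element matrices); overrides sampling.
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return List with `embedding` (n x n_embedding), `reconstruction`
#'   (n x p), `risk` (length-n vector), and optionally `cache`.
#' @export
forward <- function(model, X, dropout_on = FALSE, masks = NULL,
                    keep_cache = FALSE) {
  stopifnot(inherits(model, "survnet_model"), is.matrix(X))
  p <- nrow(model$W$sp)
  if (ncol(X) != p) {
    stop("input has ", ncol(X), " columns but the model expects ", p, " genes")
  }
  if (dropout_on && is.null(masks)) {
    masks <- sample_dropout(model$config$dropout_rate, nrow(X),
                            list(e1 = model$config$n_hidden1,
                                 e2 = model$config$n_hidden2,
                                 d1 = model$config$n_hidden2,
                                 d2 = model$config$n_hidden1))
  }
  Wsp <- model$W$sp * t(model$mask$matrix)
  S_pre <- sweep(X %*% Wsp, 2L, model$b$sp, `+`);  S <- relu(S_pre)
  H1_pre <- sweep(S %*% model$W$e1, 2L, model$b$e1, `+`); H1 <- relu(H1_pre)
  H1d <- apply_mask(H1, masks$e1)
  H2_pre <- sweep(H1d %*% model$W$e2, 2L, model$b$e2, `+`); H2 <- relu(H2_pre)
  H2d <- apply_mask(H2, masks$e2)
  Z_pre <- sweep(H2d %*% model$W$em, 2L, model$b$em, `+`); Z <- relu(Z_pre)
  D1_pre <- sweep(Z %*% model$W$d1, 2L, model$b$d1, `+`); D1 <- relu(D1_pre)
  D1d <- apply_mask(D1, masks$d1)
  D2_pre <- sweep(D1d %*% model$W$d2, 2L, model$b$d2, `+`); D2 <- relu(D2_pre)
  D2d <- apply_mask(D2, masks$d2)
  Xp <- sweep(D2d %*% model$W$out, 2L, model$b$out, `+`)
  risk <- drop(Z %*% model$W$rk) + model$b$rk
  out <- list(embedding = Z, reconstruction = Xp, risk = risk)
  if (keep_cache) {
    out$cache <- list(X = X, Wsp = Wsp, S_pre = S_pre, S = S,
                      H1_pre = H1_pre, H1d = H1d, H2_pre = H2_pre, H2d = H2d,
                      Z_pre = Z_pre, Z = Z, D1_pre = D1_pre, D1d = D1d,
                      D2_pre = D2_pre, D2d = D2d, masks = masks)
  }
  out
}

#' Predict log-hazard risk scores
#'
#' Deterministic forward pass (dropout off) returning only the risk head.
#'
#' @param model A trained `survnet_model`.
#' @param X n x p matrix or a `cohort_dataset`; columns are matched to the
#'   model's genes by name when dimnames are present.
#' @return Numeric vector of length n.
#' @export
predict_risk <- function(model, X) {
  X <- align_genes(model, X)
  forward(model, X, dropout_on = FALSE)$risk
}

# Match input columns (and apply the training standardization, if any) to
# the model's gene order.
align_genes <- function(model, X) {
  if (inherits(X, "cohort_dataset")) X <- X$expression
  genes <- model$mask$gene_ids
  if (!is.null(colnames(X))) {
    missing <- setdiff(genes, colnames(X))
    if (length(missing) > 0L) {
      stop("input is missing ", length(missing), " model gene(s), e.g. ",
           missing[1L])
    }
    X <- X[, genes, drop = FALSE]
  } else if (ncol(X) != length(genes)) {
    stop("unnamed input must have exactly ", length(genes), " columns")
  }
  if (!is.null(model$input_center)) {
    X <- sweep(X, 2L, model$input_center, `-`)
    X <- sweep(X, 2L, model$input_scale, `/`)
  }
  X
}

# Gradient of the summed risk output with respect to the input, row-wise.
# Only the encoder + risk head are involved. Used by integrated gradients;
# `masks` fixes one dropout realization (per-unit vectors).
input_gradient <- function(model, X, masks = NULL) {
  fw <- forward(model, X, dropout_on = FALSE, masks = masks,
                keep_cache = TRUE)
  cc <- fw$cache
  n <- nrow(X)
  dZ <- matrix(model$W$rk, n, length(model$W$rk), byrow = TRUE)
  dZ_pre <- dZ * (cc$Z_pre > 0)
  dH2 <- apply_mask(dZ_pre %*% t(model$W$em), cc$masks$e2)
  dH2_pre <- dH2 * (cc$H2_pre > 0)
  dH1 <- apply_mask(dH2_pre %*% t(model$W$e2), cc$masks$e1)
  dH1_pre <- dH1 * (cc$H1_pre > 0)
  dS_pre <- (dH1_pre %*% t(model$W$e1)) * (cc$S_pre > 0)
  dS_pre %*% t(cc$Wsp)
}

# Backpropagation of the weighted multitask loss. `s_target` (constant
# within an epoch) and `centers` feed the clustering term; gamma/beta are
# the loss weights actually applied this epoch (0 disables a task).
# Returns per-parameter gradients plus the loss components.
model_gradients <- function(model, X, time, event, gamma, beta,
                            s_target = NULL, centers = NULL, masks = NULL) {
  fw <- forward(model, X, dropout_on = !is.null(masks), masks = masks,
                keep_cache = TRUE)
  cc <- fw$cache
  n <- nrow(X)
  W <- model$W

  L_D <- if (gamma > 0) reconstruction_loss(X, fw$reconstruction) else NA_real_
  L_P <- cox_loss(fw$risk, time, event)
  L_C <- NA_real_
  dZ_extra <- 0
  if (beta > 0) {
    t_soft <- soft_assignment(fw$embedding, centers)
    L_C <- clustering_loss(s_target, t_soft)
    dZ_extra <- beta * dec_gradient_z(fw$embedding, centers, s_target, t_soft)
  }

  g <- list()
  # decoder path (reconstruction)
  if (gamma > 0) {
    dXp <- gamma * 2 * (fw$reconstruction - X) / n
    g$W_out <- crossprod(cc$D2d, dXp); g$b_out <- colSums(dXp)
    dD2_pre <- apply_mask(dXp %*% t(W$out), cc$masks$d2) * (cc$D2_pre > 0)
    g$W_d2 <- crossprod(cc$D1d, dD2_pre); g$b_d2 <- colSums(dD2_pre)
    dD1_pre <- apply_mask(dD2_pre %*% t(W$d2), cc$masks$d1) * (cc$D1_pre > 0)
    g$W_d1 <- crossprod(cc$Z, dD1_pre); g$b_d1 <- colSums(dD1_pre)
    dZ_dec <- dD1_pre %*% t(W$d1)
  } else {
    zero <- function(m) array(0, dim(m))
    g$W_out <- zero(W$out); g$b_out <- numeric(length(model$b$out))
    g$W_d2 <- zero(W$d2); g$b_d2 <- numeric(length(model$b$d2))
    g$W_d1 <- zero(W$d1); g$b_d1 <- numeric(length(model$b$d1))
    dZ_dec <- 0
  }
  # risk head
  dRisk <- cox_gradient(fw$risk, time, event)
  g$W_rk <- crossprod(cc$Z, matrix(dRisk, ncol = 1L))
  g$b_rk <- sum(dRisk)
  dZ_rk <- matrix(dRisk, ncol = 1L) %*% t(W$rk)

  dZ <- dZ_dec + dZ_rk + dZ_extra
  dZ_pre <- dZ * (cc$Z_pre > 0)
  g$W_em <- crossprod(cc$H2d, dZ_pre); g$b_em <- colSums(dZ_pre)
  dH2_pre <- apply_mask(dZ_pre %*% t(W$em), cc$masks$e2) * (cc$H2_pre > 0)
  g$W_e2 <- crossprod(cc$H1d, dH2_pre); g$b_e2 <- colSums(dH2_pre)
  dH1_pre <- apply_mask(dH2_pre %*% t(W$e2), cc$masks$e1) * (cc$H1_pre > 0)
  g$W_e1 <- crossprod(cc$S, dH1_pre); g$b_e1 <- colSums(dH1_pre)
  dS_pre <- (dH1_pre %*% t(W$e1)) * (cc$S_pre > 0)
  g$W_sp <- crossprod(X, dS_pre) * t(model$mask$matrix)
  g$b_sp <- colSums(dS_pre)

  # L2 regularization on all weights and biases
  wd <- model$config$weight_decay
  if (wd > 0) {
    for (nm in layer_names) {
      g[[paste0("W_", nm)]] <- g[[paste0("W_", nm)]] + 2 * wd * W[[nm]]
      g[[paste0("b_", nm)]] <- g[[paste0("b_", nm)]] + 2 * wd * model$b[[nm]]
    }
    # masked sparse weights stay inert under regularization too
    g$W_sp <- g$W_sp * t(model$mask$matrix)
  }
  total <- (if (gamma > 0) gamma * L_D else 0) +
    (if (beta > 0) beta * L_C else 0) + L_P
  list(grads = g, L_D = L_D, L_C = L_C, L_P = L_P, total = total,
       forward = fw)
}

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in layer_names) {
    st$m[[paste0("W_", nm)]] <- array(0, dim(model$W[[nm]]))
    st$v[[paste0("W_", nm)]] <- array(0, dim(model$W[[nm]]))
    st$m[[paste0("b_", nm)]] <- numeric(length(model$b[[nm]]))
    st$v[[paste0("b_", nm)]] <- numeric(length(model$b[[nm]]))
  }
  st
}

adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in layer_names) {
    for (kind in c("W_", "b_")) {
      key <- paste0(kind, nm)
      gk <- grads[[key]]
      opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * gk
      opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * gk * gk
      step <- lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + eps)
      if (kind == "W_") model$W[[nm]] <- model$W[[nm]] - step
      else model$b[[nm]] <- model$b[[nm]] - drop(step)
    }
  }
  model$W$sp <- model$W$sp * t(model$mask$matrix)
  list(model = model, opt = opt)
}

#' Save a trained model checkpoint
#'
#' Single-file checkpoint holding a schema version, the configuration, the
#' pathway mask, all weights, and the cluster state.
#'
#' @param model A `survnet_model`.
#' @param path Output file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "survnet_model"))
  saveRDS(list(schema = 1L, package_version = "0.1.0", model = model), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `survnet_model`.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, 1L)) stop("unsupported checkpoint schema")
  ck$model
}
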