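#' Initialize clusters on the embedding by k-means with silhouette selection
#'
#' Runs k-means for every k in `k_range` and keeps the k with the largest
#' mean silhouette width.
#'
#' @param Z n x d embedding matrix.
#' @param k_range Integer interval of candidate cluster counts.
#' @param seed Integer seed.
#' @return List with `k`, `labels`, `centers`, and the per-k `silhouette`
#'   scores.
#' @export
init_clusters <- function(Z, k_range = c(2L, 4L), seed = 1) {
  Z <- as.matrix(Z)
  ks <- seq.int(k_range[1L], k_range[2L])
  if (nrow(Z) < max(ks) + 1L) stop("too few samples for k up to ", max(ks))
  if (all(apply(Z, 2L, function(col) diff(range(col)) == 0))) {
    stop("degenerate embedding: all points identical")
  }
  dZ <- stats::dist(Z)
  sil <- stats::setNames(numeric(length(ks)), ks)
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(derive_seed(seed, paste0("kmeans", ks[i])))
    fits[[i]] <- stats::kmeans(Z, centers = ks[i], nstart = 10L,
                               iter.max = 100L)
    sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, dZ)[, 3L])
  }
  best <- which.max(sil)
  list(k = ks[best], labels = fits[[best]]$cluster,
       centers = fits[[best]]$centers, silhouette = sil)
}

#' Refresh cluster labels and centers on current embeddings
#'
#' One warm-started Lloyd refit: points are assigned to their nearest
#' current center and centers are recomputed as cluster means, iterated to
#' a (local) fixed point. The cluster count k never changes; a cluster that
#' empties is re-seeded at the point farthest from its assigned center.
#'
#' @param Z n x d embedding matrix.
#' @param centers k x d current centers.
#' @param max_iter Lloyd iterations per refresh.
#' @return List with `labels` and `centers`.
#' @export
update_clusters <- function(Z, centers, max_iter = 10L) {
  Z <- as.matrix(Z); centers <- as.matrix(centers)
  k <- nrow(centers)
  labels <- integer(nrow(Z))
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(Z^2), rowSums(centers^2), `+`) - 2 * Z %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(new_labels))
    for (j in empty) {
      # re-seed from the point farthest from its current center
      nearest <- d2[cbind(seq_len(nrow(Z)), new_labels)]
      far <- which.max(nearest)
      centers[j, ] <- Z[far, ]
      new_labels[far] <- j
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(Z[new_labels == j, , drop = FALSE])
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels, centers = centers)
}

#' Train the pathway-masked multitask survival network
#'
#' Full-batch gradient descent with Adam and L2 weight decay over the
#' combined loss `gamma * L_D + beta * L_C + L_P`. Per epoch: forward pass
#' (dropout active when `dropout_rate > 0`), target distribution recomputed
#' from the current soft assignment and held constant for the epoch's
#' gradient step, parameter update, then one warm-started cluster refresh
#' on the new embeddings. The cluster count k is chosen once, after
#' initialization, by silhouette over `k_range`.
#'
#' @param cohort A `cohort_dataset` with at least one observed event.
#' @param mask A `pathway_mask` built from the cohort's genes.
#' @param config A `network_config`.
#' @param ablation `"none"` (full multitask), `"-DR"` (drop reconstruction),
#'   `"-SS"` (drop clustering), or `"-DRSS"` (prediction task only).
#' @param standardize Center/scale each gene before training (stored in the
#'   model and re-applied at prediction time).
#' @param verbose Print the loss every 50 epochs.
#' @return List with `model` (a `survnet_model`) and `report` (per-epoch
#'   loss trace, chosen k, silhouette scores, seed).
#' @export
train <- function(cohort, mask, config, ablation = c("none", "-DR", "-SS", "-DRSS"),
                  standardize = TRUE, verbose = FALSE) {
  ablation <- match.arg(ablation)
  stopifnot(inherits(cohort, "cohort_dataset"), inherits(mask, "pathway_mask"),
            inherits(config, "network_config"))
  if (sum(cohort$survival$event) < 1L) stop("cohort has no observed events")
  gamma <- if (ablation %in% c("-DR", "-DRSS")) 0 else config$gamma
  beta <- if (ablation %in% c("-SS", "-DRSS")) 0 else config$beta

  model <- init_model(config, mask)
  X <- cohort$expression[, mask$gene_ids, drop = FALSE]
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    model$input_center <- ctr
    model$input_scale <- scl
    X <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  }
  time <- cohort$survival$time
  event <- cohort$survival$event
  opt <- adam_init(model)

  # The clustering task activates only after `cluster_warmup` of the epoch
  # budget: sharpening soft assignments of a randomly initialized embedding
  # would lock in noise clusters. Cluster centers are initialized by
  # silhouette-selected k-means on the warmed-up embedding.
  centers <- NULL; s_target <- NULL; sil <- NULL
  n_ep <- config$max_epochs
  warmup <- if (beta > 0) floor(config$cluster_warmup * n_ep) else n_ep + 1L
  start_clusters <- function(model) {
    Z0 <- forward(model, X)$embedding
    ini <- init_clusters(Z0, config$k_range, derive_seed(config$seed, "clusters"))
    model$k <- ini$k
    model$labels <- ini$labels
    list(model = model, centers = ini$centers, sil = ini$silhouette)
  }
  if (beta > 0 && warmup == 0L) {
    st0 <- start_clusters(model)
    model <- st0$model; centers <- st0$centers; sil <- st0$sil
  }
  trace <- data.frame(epoch = seq_len(n_ep), total = NA_real_,
                      recon = NA_real_, clust = NA_real_, cox = NA_real_)
  set.seed(derive_seed(config$seed, "dropout"))
  for (ep in seq_len(n_ep)) {
    if (beta > 0 && is.null(centers) && ep > warmup) {
      st0 <- start_clusters(model)
      model <- st0$model; centers <- st0$centers; sil <- st0$sil
    }
    clustering_on <- beta > 0 && !is.null(centers)
    masks <- if (config$dropout_rate > 0) {
      sample_dropout(config$dropout_rate, nrow(X),
                     list(e1 = config$n_hidden1, e2 = config$n_hidden2,
                          d1 = config$n_hidden2, d2 = config$n_hidden1))
    } else NULL
    if (clustering_on) {
      t_now <- soft_assignment(forward(model, X, masks = masks)$embedding,
                               centers)
      s_target <- target_distribution(t_now)
    }
    gr <- model_gradients(model, X, time, event, gamma,
                          if (clustering_on) beta else 0,
                          s_target = s_target, centers = centers,
                          masks = masks)
    if (!is.finite(gr$total)) {
      stop(sprintf("non-finite loss at epoch %d (L_D=%.4g, L_C=%.4g, L_P=%.4g); try a smaller learning rate",
                   ep, gr$L_D, gr$L_C, gr$L_P))
    }
    trace$total[ep] <- gr$total
    trace$recon[ep] <- gr$L_D
    trace$clust[ep] <- gr$L_C
    trace$cox[ep] <- gr$L_P
    st <- adam_step(model, gr$grads, opt, config$learning_rate)
    model <- st$model; opt <- st$opt
    if (clustering_on) {
      Znew <- forward(model, X)$embedding
      upd <- update_clusters(Znew, centers)
      centers <- upd$centers
      model$labels <- upd$labels
    }
    if (verbose && (ep %% 50L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d total %.4f (recon %.4f clust %.4f cox %.4f)",
                      ep, gr$total, gr$L_D, gr$L_C, gr$L_P))
    }
  }
  model$centers <- centers
  list(model = model,
       report = list(trace = trace, k = model$k, silhouette = sil,
                     ablation = ablation, seed = config$seed,
                     config = config))
}

#' Five-fold cross-validated hyperparameter selection
#'
#' Grid search over embedding width and learning rate. Folds are stratified
#' by the event indicator so every fold keeps events; each configuration is
#' trained on the complement of a fold and scored by the validation
#' concordance index; the configuration with the highest mean validation
#' C-index is selected.
#'
#' @param cohort A `cohort_dataset`.
#' @param mask A `pathway_mask`.
#' @param config Base `network_config` (grid values override its
#'   `n_embedding` / `learning_rate`).
#' @param n_embedding_grid Candidate embedding widths.
#' @param learning_rate_grid Candidate learning rates.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @return List with `results` (one row per config x fold), `summary`
#'   (mean C-index per config), `best` (selected parameter pair), `folds`.
#' @export
cross_validate <- function(cohort, mask, config,
                           n_embedding_grid = c(10L, 20L, 50L),
                           learning_rate_grid = c(1e-6, 1e-7, 1e-8),
                           n_folds = 5L, seed = 1) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  n <- nrow(cohort$expression)
  if (n < n_folds) stop("fewer samples than folds")
  ev <- cohort$survival$event
  if (sum(ev) < n_folds) stop("need at least one event per fold")
  set.seed(derive_seed(seed, "folds"))
  folds <- integer(n)
  folds[ev == 1] <- sample(rep_len(seq_len(n_folds), sum(ev == 1)))
  folds[ev == 0] <- sample(rep_len(seq_len(n_folds), sum(ev == 0)))

  grid <- expand.grid(n_embedding = n_embedding_grid,
                      learning_rate = learning_rate_grid,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid) * n_folds)
  r <- 0L
  for (gidx in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_embedding <- as.integer(grid$n_embedding[gidx])
    cfg$learning_rate <- grid$learning_rate[gidx]
    for (f in seq_len(n_folds)) {
      tr_idx <- which(folds != f)
      va_idx <- which(folds == f)
      tr <- subset_cohort(cohort, tr_idx)
      va <- subset_cohort(cohort, va_idx)
      fit <- train(tr, mask, cfg)
      ci <- concordance_index(predict_risk(fit$model, va),
                              va$survival$time, va$survival$event)
      r <- r + 1L
      results[[r]] <- data.frame(n_embedding = cfg$n_embedding,
                                 learning_rate = cfg$learning_rate,
                                 fold = f, c_index = ci)
    }
  }
  results <- do.call(rbind, results)
  agg <- stats::aggregate(c_index ~ n_embedding + learning_rate, results, mean)
  best <- agg[which.max(agg$c_index), , drop = FALSE]
  list(results = results, summary = agg, best = best, folds = folds)
}

#' Subset a cohort by sample indices
#' @param cohort A `cohort_dataset`.
#' @param idx Integer sample indices.
#' @return A `cohort_dataset`.
#' @export
subset_cohort <- function(cohort, idx) {
  cohort_dataset(cohort$expression[idx, , drop = FALSE],
                 cohort$survival[idx, , drop = FALSE])
}
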