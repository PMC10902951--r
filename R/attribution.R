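#' Attribution configuration
#'
#' @param n_quadrature Number of Gauss-Legendre nodes on `[0, 1]` used to
#'   approximate the path integral (default 64).
#' @param n_mc_runs Number of Monte Carlo dropout inference runs T
#'   (default 100).
#' @param dropout_rates Dropout rate(s) cycled across the T runs; `NULL`
#'   means "use the model's training dropout rate".
#' @param baseline Per-gene baseline vector; `NULL` means all-zero (the
#'   cohort mean when inputs are standardized).
#' @param input `"per-sample"` attributes every sample and averages the
#'   signed attributions; `"cohort-mean"` attributes the single mean
#'   expression vector.
#' @param mean_floor Denominator guard for the uncertainty ratio: genes
#'   whose mean attribution magnitude falls below it are flagged unstable.
#' @param seed Integer seed for the dropout realizations.
#' @return An `attribution_config` list.
#' @export
attribution_config <- function(n_quadrature = 64L, n_mc_runs = 100L,
                               dropout_rates = NULL, baseline = NULL,
                               input = c("per-sample", "cohort-mean"),
                               mean_floor = 1e-8, seed = 1) {
  cfg <- list(n_quadrature = as.integer(n_quadrature),
              n_mc_runs = as.integer(n_mc_runs),
              dropout_rates = dropout_rates, baseline = baseline,
              input = match.arg(input), mean_floor = mean_floor,
              seed = as.integer(seed))
  stopifnot(cfg$n_quadrature >= 2L, cfg$n_mc_runs >= 2L, cfg$mean_floor > 0)
  class(cfg) <- "attribution_config"
  cfg
}

#' Gauss-Legendre path integral of a gradient field
#'
#' Core quadrature used by integrated gradients:
#' `IG_i = (x_i - baseline_i) * sum_q w_q grad_i(baseline + a_q (x - baseline))`
#' with `(a_q, w_q)` the n-node Gauss-Legendre rule mapped to `[0, 1]`.
#'
#' @param grad_fn Function taking an n x p matrix of inputs and returning
#'   the n x p matrix of partial derivatives of the scalar output for each
#'   row.
#' @param X n x p matrix of points to attribute.
#' @param baseline Length-p baseline vector.
#' @param n_nodes Number of quadrature nodes.
#' @return n x p matrix of attributions.
#' @export
ig_quadrature <- function(grad_fn, X, baseline, n_nodes = 64L) {
  X <- rbind(X)  # promote a vector to a 1-row matrix
  p <- ncol(X)
  stopifnot(length(baseline) == p, n_nodes >= 2L)
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  B <- matrix(baseline, nrow(X), p, byrow = TRUE)
  diffX <- X - B
  acc <- matrix(0, nrow(X), p)
  for (qi in seq_len(n_nodes)) {
    acc <- acc + gl$w[qi] * grad_fn(B + gl$x[qi] * diffX)
  }
  diffX * acc
}

#' Integrated gradients of the risk output
#'
#' Attribution of the model's log-hazard output to each input gene along
#' the straight path from the baseline, approximated by Gauss-Legendre
#' quadrature. When `masks` is supplied, that single dropout realization is
#' held fixed across all quadrature nodes, so one well-defined thinned
#' network is attributed.
#'
#' @param model A trained `survnet_model`.
#' @param X n x p matrix (model gene order; standardization is applied via
#'   [predict_risk()] conventions when dimnames are present).
#' @param config An `attribution_config`.
#' @param masks Optional fixed dropout realization (per-unit vectors).
#' @return n x p matrix of per-sample, per-gene attributions.
#' @export
integrated_gradients <- function(model, X, config = attribution_config(),
                                 masks = NULL) {
  X <- align_genes(model, X)
  baseline <- config$baseline %||% numeric(ncol(X))
  ig_quadrature(function(Xa) input_gradient(model, Xa, masks = masks),
                X, baseline, config$n_quadrature)
}

#' Monte Carlo dropout attribution runs
#'
#' Repeats integrated gradients T times, each under an independent seeded
#' dropout realization (rates cycled from `config$dropout_rates`). Each run
#' yields one length-p attribution vector: the signed per-sample
#' attributions averaged over samples (or the attribution of the cohort
#' mean vector, per `config$input`).
#'
#' @param model A trained `survnet_model`.
#' @param X n x p expression matrix.
#' @param config An `attribution_config`.
#' @return T x p matrix of per-run attributions (columns named by gene).
#' @export
mc_dropout_attributions <- function(model, X, config = attribution_config()) {
  stopifnot(inherits(config, "attribution_config"))
  if (config$n_mc_runs < 2L) stop("at least 2 MC runs required")
  if (inherits(X, "cohort_dataset")) X <- X$expression
  # alignment/standardization happens inside integrated_gradients; here we
  # only collapse to the cohort mean when requested
  if (config$input == "cohort-mean") X <- rbind(colMeans(X))
  rates <- config$dropout_rates %||% model$config$dropout_rate
  widths <- list(e1 = model$config$n_hidden1, e2 = model$config$n_hidden2)
  p <- ncol(X)
  lg <- matrix(NA_real_, config$n_mc_runs, p,
               dimnames = list(NULL, model$mask$gene_ids))
  for (t_run in seq_len(config$n_mc_runs)) {
    rate <- rates[((t_run - 1L) %% length(rates)) + 1L]
    masks <- if (rate > 0) {
      set.seed(derive_seed(config$seed, paste0("mc", t_run)))
      sample_dropout(rate, nrow(X), widths, unit = TRUE)
    } else NULL
    ig <- integrated_gradients(model, X, config, masks = masks)
    lg[t_run, ] <- colMeans(ig)
  }
  lg
}

#' Per-gene attribution uncertainty across MC runs
#'
#' `U_i = sd over runs of lg_i / |mean over runs of lg_i|` (sample standard
#' deviation, T - 1 denominator). The denominator is floored at
#' `mean_floor`; affected genes are flagged unstable via the
#' `"unstable"` attribute.
#'
#' @param lg T x p matrix of per-run attributions.
#' @param mean_floor Denominator guard.
#' @return Nonnegative numeric vector of length p with attribute
#'   `unstable` (logical).
#' @export
uncertainty <- function(lg, mean_floor = 1e-8) {
  if (nrow(lg) < 2L) stop("uncertainty needs at least 2 MC runs")
  s <- apply(lg, 2L, stats::sd)
  m <- abs(colMeans(lg))
  unstable <- m < mean_floor
  U <- s / pmax(m, mean_floor)
  attr(U, "unstable") <- unstable
  U
}

#' Adjusted uncertainty: log transform and min-max normalization
#'
#' `U' = minmax(log(1 + U))`, mapping the least uncertain gene to 0 and the
#' most uncertain to 1. If all uncertainties are equal (e.g. all zero with
#' dropout disabled), U' is identically 0 so the importance reduces to the
#' plain integrated gradients.
#'
#' @param U Nonnegative uncertainty vector.
#' @return Vector in `[0, 1]`.
#' @export
adjust_uncertainty <- function(U) {
  stopifnot(all(U >= 0))
  l <- log1p(U)
  rng <- range(l)
  if (diff(rng) < 1e-12) return(rep(0, length(U)))
  (l - rng[1L]) / diff(rng)
}

#' Uncertainty-discounted importance weights and gene ranking
#'
#' `V_i = (1 - U'_i) * IG_i`; genes are ranked by decreasing `|V|`, ties
#' broken by gene index.
#'
#' @param ig_mean Per-gene mean attribution across MC runs.
#' @param U_adj Adjusted uncertainty in `[0, 1]`.
#' @return List with `V` and `rank` (permutation: `rank[1]` is the index of
#'   the top gene).
#' @export
importance <- function(ig_mean, U_adj) {
  stopifnot(length(ig_mean) == length(U_adj))
  V <- (1 - U_adj) * ig_mean
  list(V = V, rank = order(-abs(V), seq_along(V)))
}

#' Full attribution pipeline: MC-dropout integrated gradients to ranking
#'
#' @param model A trained `survnet_model`.
#' @param X n x p expression matrix (or a `cohort_dataset`).
#' @param config An `attribution_config`.
#' @return An `attribution_result`: list with `runs` (T x p), `table` (one
#'   row per gene: `gene`, `mean_IG`, `U`, `U_adj`, `V`, `rank`,
#'   `unstable_flag`, sorted by rank).
#' @export
attribute_genes <- function(model, X, config = attribution_config()) {
  lg <- mc_dropout_attributions(model, X, config)
  ig_mean <- colMeans(lg)
  U <- uncertainty(lg, config$mean_floor)
  U_adj <- adjust_uncertainty(U)
  imp <- importance(ig_mean, U_adj)
  tab <- data.frame(gene = colnames(lg), mean_IG = ig_mean, U = as.numeric(U),
                    U_adj = U_adj, V = imp$V,
                    unstable_flag = attr(U, "unstable"),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[imp$rank, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(runs = lg, table = tab), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, n = 10L, ...) {
  cat(sprintf("attribution_result: %d genes, %d MC runs; top %d:\n",
              ncol(x$runs), nrow(x$runs), n))
  print(utils::head(x$table, n))
  invisible(x)
}
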