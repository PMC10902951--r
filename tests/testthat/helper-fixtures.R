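# Shared fixtures and independent oracles, all generated in code.

tiny_cohort <- function(n = 30, p = 12, q = 4, seed = 11, censoring = 0.4,
                        effect = 0.5, planted = 4) {
  spec <- synthetic_spec(n_samples = n, n_genes = p, n_pathways = q,
                         pathway_size = ceiling(p / q), planted_genes = planted,
                         effect_size = effect, target_censoring = censoring,
                         seed = seed)
  sim <- simulate_cohort(spec)
  pw <- simulate_pathways(spec)
  mask <- build_pathway_mask(pw, colnames(sim$cohort$expression))
  list(spec = spec, cohort = sim$cohort, truth = sim$truth, pathways = pw,
       mask = mask)
}

tiny_config <- function(..., seed = 3) {
  defaults <- list(n_hidden1 = 8, n_hidden2 = 6, n_embedding = 3,
                   learning_rate = 1e-3, max_epochs = 30, dropout_rate = 0,
                   weight_decay = 1e-4, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(network_config, args)
}

# A small trained model (p = 20 genes, q = 4 pathways) reused by the
# attribution tests; cached per session.
toy_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_cohort(n = 60, p = 20, q = 4, seed = 7, planted = 4)
      cfg <- tiny_config(n_hidden1 = 12, n_hidden2 = 8, n_embedding = 4,
                         max_epochs = 150, dropout_rate = 0.1, seed = 5)
      fit <- train(fx$cohort, fx$mask, cfg)
      cache <<- list(fixture = fx, fit = fit)
    }
    cache
  }
})

# O(n^2) double-loop Cox partial likelihood (independent of cox_loss's
# sorted-cumsum implementation)
brute_cox_loss <- function(h, time, event) {
  s <- 0
  for (i in seq_along(h)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      s <- s + h[i] - log(sum(exp(h[rs])))
    }
  }
  -s
}

# O(n^2) double-loop concordance index
brute_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Riemann-sum (midpoint) integrated gradients oracle; grad_fn maps a point
# to its gradient vector
riemann_ig <- function(grad_fn, x, baseline, n_steps = 1e5) {
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  acc <- numeric(length(x))
  for (a in alphas) acc <- acc + grad_fn(baseline + a * (x - baseline))
  (x - baseline) * acc / n_steps
}

# central-difference gradient of a scalar function of a parameter vector
numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1L))
}

expect_rows_sum_to_one <- function(m, tol = 1e-6) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
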