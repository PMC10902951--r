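test_that("quadrature IG is exact on a linear model", {
  w <- c(0.5, -1.2, 2, 0)
  grad_fn <- function(X) matrix(w, nrow(X), 4, byrow = TRUE)
  x <- c(1, 2, -1, 3)
  ig <- ig_quadrature(grad_fn, x, baseline = rep(0, 4), n_nodes = 64)
  expect_equal(drop(ig), w * x, tolerance = 1e-6)
})

test_that("quadrature IG matches a Riemann oracle on the 2-gene ReLU toy", {
  # F(x) = ReLU(x1 + x2 - 1), subgradient 0 at the kink
  grad_fn1 <- function(x) if (sum(x) > 1) c(1, 1) else c(0, 0)
  grad_fn <- function(X) t(apply(X, 1, grad_fn1))
  x <- c(1, 1)
  ig64 <- drop(ig_quadrature(grad_fn, x, baseline = c(0, 0), n_nodes = 64))
  oracle <- riemann_ig(grad_fn1, x, baseline = c(0, 0), n_steps = 1e5)
  expect_equal(ig64, oracle, tolerance = 1e-3)
  expect_equal(sum(ig64), 1, tolerance = 1e-3)  # completeness: F(x) - F(0) = 1
})

test_that("IG on a trained toy model approximately satisfies completeness", {
  # The path gradient of a ReLU network is piecewise constant with jumps
  # where units flip along the path, so a fixed Gauss-Legendre rule
  # converges slowly across those kinks; completeness holds to quadrature
  # accuracy (a few percent at 64 nodes), tightening with more nodes.
  tt <- toy_trained()
  model <- tt$fit$model
  X <- tt$fixture$cohort$expression[1:5, ]
  f_x <- predict_risk(model, X)
  f_0 <- forward(model, matrix(0, 1, 20))$risk
  delta <- f_x - f_0
  err_of <- function(nq) {
    ig <- integrated_gradients(model, X,
                               attribution_config(n_quadrature = nq,
                                                  n_mc_runs = 2, seed = 1))
    max(abs(rowSums(ig) - delta) / pmax(abs(delta), 1e-8))
  }
  expect_lt(err_of(64L), 0.05)
  expect_lt(err_of(1024L), err_of(16L))
})

test_that("IG stabilizes as quadrature nodes increase", {
  tt <- toy_trained()
  model <- tt$fit$model
  X <- tt$fixture$cohort$expression[1:5, ]
  igs <- lapply(c(64L, 256L, 1024L), function(nq) {
    integrated_gradients(model, X, attribution_config(n_quadrature = nq,
                                                      n_mc_runs = 2, seed = 1))
  })
  d64 <- max(abs(igs[[1]] - igs[[3]])) / max(abs(igs[[3]]))
  d256 <- max(abs(igs[[2]] - igs[[3]])) / max(abs(igs[[3]]))
  expect_lt(d64, 0.01)
  expect_lt(d256, d64)
})

test_that("MC runs are shaped, seeded, and collapse without dropout", {
  tt <- toy_trained()
  model <- tt$fit$model
  X <- tt$fixture$cohort$expression
  cfg <- attribution_config(n_quadrature = 16, n_mc_runs = 5,
                            dropout_rates = 0.3, seed = 4)
  lg <- mc_dropout_attributions(model, X, cfg)
  expect_equal(dim(lg), c(5L, ncol(X)))
  lg2 <- mc_dropout_attributions(model, X, cfg)
  expect_identical(lg, lg2)
  # all rows identical when every run uses dropout rate 0
  cfg0 <- attribution_config(n_quadrature = 16, n_mc_runs = 4,
                             dropout_rates = 0, seed = 4)
  lg0 <- mc_dropout_attributions(model, X, cfg0)
  expect_true(all(apply(lg0, 2, function(col) length(unique(col)) == 1L)))
  expect_error(attribution_config(n_mc_runs = 1), "n_mc_runs")
})

test_that("uncertainty follows the std-over-mean definition with guards", {
  lg <- rbind(c(1, 2, 0), c(3, 2, 0))
  U <- uncertainty(lg)
  expect_equal(U[[1]], sqrt(2) / 2, tolerance = 1e-10)  # ~0.7071
  expect_equal(U[[2]], 0)
  expect_equal(U[[3]], 0)          # sd 0 / guarded mean 0
  expect_false(attr(U, "unstable")[1])
  expect_true(attr(U, "unstable")[3])
  # near-zero mean: guarded, flagged, finite
  lgz <- rbind(c(1e-12, 1), c(-1e-12, 1.1))
  Uz <- uncertainty(lgz)
  expect_true(is.finite(Uz[[1]]) && attr(Uz, "unstable")[1])
  expect_error(uncertainty(lg[1, , drop = FALSE]), "2 MC runs")
})

test_that("adjusted uncertainty maps to [0,1], monotonically, with degenerate case", {
  U <- c(0, 0.5, 2, 10)
  Ua <- adjust_uncertainty(U)
  expect_equal(Ua[1], 0)
  expect_equal(Ua[4], 1)
  expect_true(all(diff(Ua) > 0))
  expect_equal(adjust_uncertainty(rep(0.7, 5)), rep(0, 5))
})

test_that("importance discounts by uncertainty and ranks by |V|", {
  imp <- importance(c(2, -3, 1), c(0, 0.5, 1))
  expect_equal(imp$V, c(2, -1.5, 0))
  expect_equal(imp$rank, c(1L, 2L, 3L))
  # full discount kills the weight; no discount preserves IG
  expect_equal(importance(c(5, 5), c(1, 0))$V, c(0, 5))
  # deterministic index tie-break
  expect_equal(importance(c(1, -1, 1), c(0, 0, 0))$rank, c(1L, 2L, 3L))
})

test_that("sign-flipping genes receive above-median uncertainty", {
  set.seed(20)
  p <- 40
  stable <- matrix(rnorm(10 * (p - 5), mean = 3, sd = 0.3), 10)
  flippy <- matrix(rnorm(10 * 5, mean = 0, sd = 3), 10)
  lg <- cbind(stable, flippy)
  U <- uncertainty(lg)
  flips <- apply(lg, 2, function(col) min(col) < 0 && max(col) > 0)
  if (any(flips)) {
    expect_true(all(U[flips] > stats::median(U)))
  }
})
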