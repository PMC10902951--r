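#' Reconstruction loss
#'
#' Sum of squared differences over all gene features, averaged over the
#' samples in the batch (so the loss weight `gamma` keeps its meaning
#' independently of cohort size).
#'
#' @param X Original n x p matrix.
#' @param Xp Reconstructed n x p matrix.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(X, Xp) {
  if (!identical(dim(X), dim(Xp))) stop("X and X' must have identical shape")
  sum((X - Xp)^2) / nrow(X)
}

#' Student-t soft cluster assignment
#'
#' `t_ij` is the (1 degree of freedom) Student-t kernel similarity between
#' embedded point `z_i` and cluster center `mu_j`, normalized over clusters:
#' `t_ij = (1 + ||z_i - mu_j||^2)^-1 / sum_j (...)`.
#'
#' @param Z n x d embedding matrix.
#' @param centers k x d matrix of cluster centers, k >= 2.
#' @return n x k matrix with rows summing to 1.
#' @export
soft_assignment <- function(Z, centers) {
  Z <- as.matrix(Z); centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("at least 2 cluster centers required")
  if (ncol(Z) != ncol(centers)) stop("embedding and centers dimension mismatch")
  if (any(!is.finite(centers))) stop("cluster centers must be finite")
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), `+`) - 2 * Z %*% t(centers)
  d2[d2 < 0] <- 0
  q <- 1 / (1 + d2)
  q / rowSums(q)
}

#' Sharpened target distribution for the clustering task
#'
#' `s_ij = (t_ij^2 / f_j) / sum_j (t_ij^2 / f_j)` with `f_j = sum_i t_ij`
#' the soft cluster frequency: squaring sharpens confident assignments and
#' the `1/f_j` factor prevents large clusters from absorbing everything.
#'
#' @param t_soft n x k soft assignment matrix.
#' @return n x k matrix with rows summing to 1.
#' @export
target_distribution <- function(t_soft) {
  t_soft <- as.matrix(t_soft)
  f <- colSums(t_soft)
  s <- sweep(t_soft^2, 2L, f, `/`)
  s / rowSums(s)
}

#' Clustering loss: KL divergence KL(S || T)
#'
#' `sum_ij s_ij log(s_ij / t_ij)`, with `0 log 0 = 0` and `t` floored at
#' `eps` inside the logarithm.
#'
#' @param s Target distribution (n x k).
#' @param t_soft Soft assignment (n x k).
#' @param eps Guard inside the logarithm.
#' @return Nonnegative scalar; 0 iff `s == t` elementwise.
#' @export
clustering_loss <- function(s, t_soft, eps = 1e-10) {
  s <- as.matrix(s); t_soft <- as.matrix(t_soft)
  if (!identical(dim(s), dim(t_soft))) stop("S and T must have identical shape")
  terms <- ifelse(s > 0, s * log(s / pmax(t_soft, eps)), 0)
  sum(terms)
}

# Gradient of KL(S||T) w.r.t. the embedding Z, with S and the centers held
# constant: dL/dz_i = 2 sum_j q_ij (s_ij - t_ij) (z_i - mu_j), where q_ij
# is the unnormalized Student-t kernel. Verified against finite differences
# in the test suite.
dec_gradient_z <- function(Z, centers, s, t_soft) {
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), `+`) - 2 * Z %*% t(centers)
  d2[d2 < 0] <- 0
  q <- 1 / (1 + d2)
  G <- 2 * q * (s - t_soft)
  rowSums(G) * Z - G %*% centers
}

#' Negative Cox partial log-likelihood
#'
#' `-sum over events i of (h_i - log sum_{j in R(T_i)} exp(h_j))` with the
#' risk set `R(T_i) = {j : T_j >= T_i}`. Tied event times are handled
#' Breslow-style: tied subjects appear in each other's risk sets. The
#' log-sum-exp is max-shifted for numerical stability.
#'
#' @param risk Numeric vector of log-hazard scores.
#' @param time Nonnegative follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @return Scalar loss (a sum over events, not an average).
#' @export
cox_loss <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) == 0) stop("no events: Cox partial likelihood undefined")
  m <- max(risk)
  e <- exp(risk - m)
  ord <- order(time, decreasing = TRUE)
  cs <- cumsum(e[ord])
  # tied times share the full tie group's cumulative sum (Breslow)
  t_sorted <- time[ord]
  last_of_group <- tie_runs(t_sorted)$last
  log_denom <- log(cs[last_of_group]) + m
  ev_sorted <- event[ord] == 1
  -sum((risk[ord] - log_denom)[ev_sorted])
}

# For a sorted vector, first and last index of the run of equal values
# containing each position.
tie_runs <- function(t_sorted) {
  n <- length(t_sorted)
  first <- integer(n); last <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && t_sorted[j + 1L] == t_sorted[i]) j <- j + 1L
    first[i:j] <- i; last[i:j] <- j
    i <- j + 1L
  }
  list(first = first, last = last)
}

# Gradient of cox_loss w.r.t. the risk vector:
# dL/dh_k = -event_k + exp(h_k) * sum over events i with T_i <= T_k of
# 1 / denom_i (tie groups included on both sides, Breslow).
cox_gradient <- function(risk, time, event) {
  n <- length(risk)
  m <- max(risk)
  e <- exp(risk - m)
  ord <- order(time, decreasing = TRUE)
  t_sorted <- time[ord]
  cs <- cumsum(e[ord])
  runs <- tie_runs(t_sorted)
  denom <- cs[runs$last]                          # shifted by exp(-m)
  ev_sorted <- as.numeric(event[ord] == 1)
  # k belongs to R(T_i) iff T_i <= T_k: in decreasing-time order that is
  # every position from the first index of k's own tie group onward
  inv_contrib <- ev_sorted / denom
  rev_cum <- rev(cumsum(rev(inv_contrib)))        # suffix sums
  suffix_sum <- rev_cum[runs$first]
  grad_sorted <- -ev_sorted + e[ord] * suffix_sum
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  grad
}

#' Weighted multitask total loss
#'
#' `gamma * L_D + beta * L_C + L_P`. Setting `gamma = beta = 0` reduces to
#' the prediction-only ablation; `beta = 0` removes the clustering task;
#' `gamma = 0` removes the reconstruction task.
#'
#' @param L_D Reconstruction loss.
#' @param L_C Clustering loss.
#' @param L_P Cox partial-likelihood loss.
#' @param gamma,beta Task weights (defaults 1 and 10).
#' @return Scalar.
#' @export
total_loss <- function(L_D, L_C, L_P, gamma = 1, beta = 10) {
  stopifnot(is.finite(L_P))
  (if (gamma != 0) gamma * L_D else 0) +
    (if (beta != 0) beta * L_C else 0) + L_P
}
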