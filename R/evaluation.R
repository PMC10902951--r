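#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risks order their
#' event times correctly. A pair is comparable when the earlier time
#' carries an observed event (equal times are not comparable); it is
#' concordant when the earlier-event patient has the higher risk; risk
#' ties receive half credit.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return Fraction in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  # comparable pair (i, j): T_i < T_j and event_i == 1
  earlier <- outer(time, time, `<`) & (event == 1)
  conc <- outer(risk, risk, `>`)
  tied <- outer(risk, risk, `==`)
  n_comp <- sum(earlier)
  if (n_comp == 0) stop("no comparable pairs")
  (sum(conc & earlier) + 0.5 * sum(tied & earlier)) / n_comp
}

#' Median split into low/high risk groups
#'
#' @param risk Numeric risk scores, `n >= 4`.
#' @return Factor with levels `low`, `high` (`high` = above the median).
#' @export
risk_group_split <- function(risk) {
  if (length(risk) < 4L) stop("need at least 4 samples to split")
  if (diff(range(risk)) == 0) stop("degenerate split: all risk scores identical")
  factor(ifelse(risk > stats::median(risk), "high", "low"),
         levels = c("low", "high"))
}

#' Log-rank significance of a two-group risk stratification
#'
#' Standard unweighted two-sample log-rank test (chi-square, 1 df);
#' returns `|log10(p)|`, computed on the log scale so very small p-values
#' do not underflow.
#'
#' @param groups Two-level factor of group labels.
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return Nonnegative scalar `|log10(p)|`.
#' @export
logrank_neglog10p <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required")
  if (sum(event) < 1L) stop("no events: log-rank test undefined")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- sd_fit$chisq
  if (chisq <= 0) return(0)
  # -log10(p) with p = P(X2_1 > chisq)
  -stats::pchisq(chisq, df = 1L, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Discrimination of the risk score for events occurring by time t
#' (cases: `T <= t`, event observed) versus survivors past t (controls:
#' `T > t`). Cases are weighted by the inverse Kaplan-Meier estimate of the
#' censoring distribution at their event time. The headline value is the
#' mean over the grid; by default the grid is the inner deciles of the
#' observed event times. Grid times with no cases or no controls are
#' dropped with a warning.
#'
#' @param risk Numeric risk scores.
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param times Evaluation time grid (default: deciles of event times).
#' @return List with `times`, `auc` (per-time), and `mean_auc`.
#' @export
time_dependent_auc <- function(risk, time, event, times = NULL) {
  if (sum(event) < 1L) stop("no events observed")
  if (is.null(times)) {
    times <- unique(stats::quantile(time[event == 1], probs = seq(0.1, 0.9, 0.1),
                                    names = FALSE, type = 1L))
  }
  # censoring survival G(t): KM of the flipped indicator
  G_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G_step <- stats::stepfun(G_fit$time, c(1, G_fit$surv))
  G_minus <- function(t) {
    # left-continuous limit G(t-)
    vapply(t, function(ti) {
      prior <- G_fit$time < ti
      if (!any(prior)) 1 else G_fit$surv[max(which(prior))]
    }, numeric(1L))
  }
  aucs <- rep(NA_real_, length(times))
  for (i in seq_along(times)) {
    t0 <- times[i]
    case <- which(time <= t0 & event == 1)
    ctrl <- which(time > t0)
    if (length(case) == 0L || length(ctrl) == 0L) next
    w <- 1 / pmax(G_minus(time[case]), 1e-8)
    cmp <- outer(risk[case], risk[ctrl], `>`) +
      0.5 * outer(risk[case], risk[ctrl], `==`)
    aucs[i] <- sum(w * rowSums(cmp)) / (sum(w) * length(ctrl))
  }
  keep <- !is.na(aucs)
  if (!all(keep)) {
    warning(sum(!keep), " grid time(s) dropped (no cases or no controls)")
  }
  list(times = times[keep], auc = aucs[keep], mean_auc = mean(aucs[keep]))
}

#' Kaplan-Meier step table per risk group
#'
#' Product-limit survival estimates at each observed event time; censored
#' subjects leave the risk set without a step.
#'
#' @param groups Factor of group labels.
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return `data.frame` with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_table <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  if (nlevels(groups) == 1L) {
    strata_lab <- rep(levels(groups), length(fit$time))
  } else {
    strata_lab <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata_lab, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on a cohort
#'
#' Computes the concordance index, the `|log10(p)|` of the log-rank test
#' between median-split risk groups, the mean IPCW time-dependent AUC, and
#' the per-group Kaplan-Meier table.
#'
#' @param model A trained `survnet_model`.
#' @param cohort A `cohort_dataset`.
#' @param times Optional AUC time grid.
#' @return An `evaluation_report` list: `c_index`, `neglog10_p`, `td_auc`,
#'   `mean_td_auc`, `group_sizes`, `km_table`, `risk`.
#' @export
evaluate_model <- function(model, cohort, times = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  risk <- predict_risk(model, cohort)
  time <- cohort$survival$time
  event <- cohort$survival$event
  grp <- risk_group_split(risk)
  auc <- time_dependent_auc(risk, time, event, times)
  structure(list(c_index = concordance_index(risk, time, event),
                 neglog10_p = logrank_neglog10p(grp, time, event),
                 td_auc = auc, mean_td_auc = auc$mean_auc,
                 group_sizes = table(grp), km_table = km_table(grp, time, event),
                 risk = risk),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: C-index %.3f, |log10(P)| %.3f, mean td-AUC %.3f (groups %d/%d)\n",
              x$c_index, x$neglog10_p, x$mean_td_auc,
              x$group_sizes[1L], x$group_sizes[2L]))
  invisible(x)
}
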