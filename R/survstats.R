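#' Performance-estimate container
#'
#' Bundles a statistic with its standard error, 95% CI, p-value and
#' provenance.  For the D-index the point estimate is on the hazard-ratio
#' (exp) scale while \code{se} and pooling apply to its log
#' (\code{scale = "log"}).
#'
#' @param statistic one of "auroc", "cindex", "dindex".
#' @param value point estimate (exp scale for dindex).
#' @param se standard error (log scale for dindex).
#' @param p_value two-sided p against the null (0.5 for auroc/cindex,
#'   log D = 0 for dindex).
#' @param n number of samples (or comparable pairs where noted).
#' @param cohort cohort label.
#' @param scale "raw" or "log" (the scale \code{se} lives on).
#' @return object of class \code{perf_estimate}.
#' @export
perf_estimate <- function(statistic, value, se, p_value, n, cohort = "",
                          scale = c("raw", "log")) {
  scale <- match.arg(scale)
  ci <- if (is.na(se)) c(NA_real_, NA_real_)
        else if (scale == "log") exp(log(value) + c(-1, 1) * 1.96 * se)
        else value + c(-1, 1) * 1.96 * se
  structure(list(statistic = statistic, value = value, se = se,
                 ci95 = ci, p_value = p_value, n = n, cohort = cohort,
                 scale = scale),
            class = "perf_estimate")
}

#' @export
print.perf_estimate <- function(x, ...) {
  cat(sprintf("%s [%s] = %.4f (se %.4f, 95%% CI %.4f-%.4f, p = %.3g, n = %d)\n",
              x$statistic, x$cohort, x$value, x$se, x$ci95[1], x$ci95[2],
              x$p_value, x$n))
  invisible(x)
}

#' Area under the ROC curve by the Mann-Whitney rank formulation
#'
#' AUROC = P(score of a high-class sample exceeds a low-class sample) +
#' half the tie probability, computed from ranks.  The p-value is the
#' two-sided tie-corrected normal-approximation Mann-Whitney test of
#' AUROC != 0.5; the standard error is Hanley-McNeil.
#'
#' @param scores numeric risk scores.
#' @param labels "high"/"low" (or logical, TRUE = high).
#' @param cohort label carried into the estimate.
#' @return a [perf_estimate()] with statistic "auroc".
#' @export
auroc <- function(scores, labels, cohort = "") {
  labels <- as_high_logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  stop_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(scores)
  a <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # Hanley-McNeil standard error
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))

  # tie-corrected Mann-Whitney normal test vs 0.5
  n <- n1 + n0
  u <- a * n1 * n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs((u - n1 * n0 / 2) / sqrt(v)))

  perf_estimate("auroc", a, se, p, n, cohort)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, with "high" as the positive class.
#'
#' @param pred_labels,true_labels "high"/"low" vectors (or logical).
#' @return numeric in [0, 1].
#' @export
balanced_accuracy <- function(pred_labels, true_labels) {
  p <- as_high_logical(pred_labels); t <- as_high_logical(true_labels)
  stop_if(!any(t) || !any(!t), "both classes must be present in truth")
  sens <- mean(p[t]); spec <- mean(!p[!t])
  (sens + spec) / 2
}

#' Harrell's concordance index for censored survival
#'
#' A pair is comparable when the shorter time carries an observed event
#' (or the times tie with exactly one event, in which case the event case
#' is the shorter).  A comparable pair is concordant when the shorter
#' survivor has the higher risk score; score ties count 1/2.  The
#' standard error uses Noether's approximation
#' \eqn{\sqrt{C(1-C)/n_{comparable}}}; the p-value is a two-sided Wald
#' test against 0.5.
#'
#' @param scores risk scores (higher = worse prognosis).
#' @param times,events survival times and 0/1 event indicators.
#' @param cohort label carried into the estimate.
#' @return a [perf_estimate()] with statistic "cindex"; \code{n} is the
#'   number of comparable pairs.
#' @export
concordance_index <- function(scores, times, events, cohort = "") {
  n <- length(scores)
  stop_if(n < 2 || length(times) != n || length(events) != n,
          "scores, times, events must share length >= 2")
  events <- as.logical(events)
  dt <- outer(times, times, "-")          # dt[a,b] = t_a - t_b
  ea <- matrix(events, n, n)              # event of row index a
  eb <- t(ea)
  # a strictly shorter with event, or tied times with event only in a;
  # the diagonal is FALSE under both clauses, and each unordered pair is
  # counted once (only from its "shorter" side)
  a_short <- (dt < 0 & ea) | (dt == 0 & ea & !eb)
  ds <- outer(scores, scores, "-")        # s_a - s_b
  conc <- sum(a_short & ds > 0)
  tied <- sum(a_short & ds == 0)
  n_comp <- sum(a_short)
  stop_if(n_comp == 0, "no comparable pairs")
  cidx <- (conc + 0.5 * tied) / n_comp
  se <- sqrt(cidx * (1 - cidx) / n_comp)
  p <- if (se == 0) 0 else 2 * stats::pnorm(-abs((cidx - 0.5) / se))
  perf_estimate("cindex", cidx, se, p, n_comp, cohort)
}

#' Royston-Sauerbrei D-index of prognostic separation
#'
#' The risk scores are rank-transformed to Blom rankits
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, scaled by
#' \eqn{\kappa = \sqrt{8/\pi}}, and entered as the single covariate of a
#' Cox proportional-hazards model (Breslow ties).  The D-index is the
#' exponentiated coefficient: a robust, scale-free hazard-ratio analogue
#' measuring separation between the survival distributions implied by
#' the score ordering.
#'
#' @inheritParams concordance_index
#' @return a [perf_estimate()] with statistic "dindex" on the exp scale
#'   (se on the log scale).  Constant scores give D = 1 with an undefined
#'   se, flagged via \code{se = NA}.
#' @export
d_index <- function(scores, times, events, cohort = "") {
  n <- length(scores)
  stop_if(n < 10, "need n >= 10")
  stop_if(sum(events) < 2, "need at least 2 events")
  if (length(unique(scores)) == 1)
    return(perf_estimate("dindex", 1, NA_real_, NA_real_, n, cohort, "log"))
  r <- rank(scores, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
  fit <- survival::coxph(survival::Surv(times, events) ~ z,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  stop_if(!is.null(fit$info) && grepl("did not converge", fit$info %||% ""),
          "Cox fit did not converge")
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(stats::vcov(fit)[1, 1]))
  p <- 2 * stats::pnorm(-abs(beta / se))
  perf_estimate("dindex", exp(beta), se, p, n, cohort, "log")
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator; the median is the first time at which the
#' survival estimate drops to 0.5 or below (undefined if it never does).
#'
#' @param times,events survival times and 0/1 event indicators.
#' @return object of class \code{km_curve}: list with \code{times},
#'   \code{survival}, \code{n_at_risk}, \code{n_events}, \code{median}.
#' @export
km_curve <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(times = fit$time, survival = fit$surv,
                 n_at_risk = fit$n.risk, n_events = fit$n.event,
                 median = if (is.na(med)) NA_real_ else med),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' @param times,events survival data.
#' @param groups vector with exactly two distinct values.
#' @return list with \code{chi2} and \code{p} (1 df).
#' @export
logrank_test <- function(times, events, groups) {
  stop_if(length(unique(groups)) != 2, "exactly two groups required")
  sd <- survival::survdiff(survival::Surv(times, as.numeric(events)) ~ groups)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Median split of risk scores
#'
#' High-risk group = scores strictly above the within-cohort median;
#' ties at the median go to the low-risk group.
#'
#' @param scores numeric vector, length >= 2, not all equal.
#' @return character vector "high"/"low".
#' @export
median_split <- function(scores) {
  stop_if(length(scores) < 2, "need at least two scores")
  stop_if(length(unique(scores)) == 1, "degenerate split: all scores equal")
  ifelse(scores > stats::median(scores), "high", "low")
}
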