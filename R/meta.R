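#' DerSimonian-Laird random-effects pooling of per-cohort estimates
#'
#' Given k per-cohort estimates with standard errors, computes fixed
#' weights \eqn{w = 1/v}, Cochran's \eqn{Q = \sum w (\theta - \bar\theta_{FE})^2},
#' the method-of-moments between-cohort variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))},
#' random-effects weights \eqn{w^* = 1/(v + \tau^2)}, and the pooled
#' estimate with \eqn{se = (\sum w^*)^{-1/2}}.  AUROC and C-index pool on
#' the raw scale (Wald null 0.5); the D-index pools on the log scale
#' (null log D = 0) and is reported exponentiated.
#'
#' @param estimates list of [perf_estimate()]s sharing one statistic.
#' @param scale "raw" or "log"; defaults to the estimates' own scale.
#' @param null_value null for the Wald p; defaults to 0.5 (raw) or 0 (log).
#' @return object of class \code{meta_estimate}: list with
#'   \code{statistic}, \code{pooled} (pooling scale), \code{value}
#'   (display scale: exp of pooled when log), \code{se}, \code{ci95}
#'   (display scale), \code{p_value}, \code{tau2}, \code{Q}, \code{k},
#'   \code{cohort_estimates}, \code{scale}.
#' @export
pool_random_effects <- function(estimates, scale = NULL, null_value = NULL) {
  stop_if(length(estimates) < 2, "need at least two cohort estimates")
  stats_seen <- unique(vapply(estimates, function(e) e$statistic, ""))
  stop_if(length(stats_seen) != 1, "estimates mix statistics: ",
          paste(stats_seen, collapse = ", "))
  scale <- scale %||% estimates[[1]]$scale
  theta <- vapply(estimates, function(e)
    if (scale == "log") log(e$value) else e$value, 0)
  se <- vapply(estimates, function(e) e$se, 0)
  stop_if(any(!is.finite(se)) || any(se == 0),
          "all estimates need a finite nonzero se")

  w <- 1 / se^2
  theta_fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_fe)^2)
  k <- length(theta)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * theta) / sum(w_star)
  pooled_se <- 1 / sqrt(sum(w_star))
  null_value <- null_value %||% if (scale == "log") 0 else 0.5
  p <- 2 * stats::pnorm(-abs((pooled - null_value) / pooled_se))
  ci_pool <- pooled + c(-1, 1) * 1.96 * pooled_se
  structure(list(statistic = stats_seen, pooled = pooled,
                 value = if (scale == "log") exp(pooled) else pooled,
                 se = pooled_se,
                 ci95 = if (scale == "log") exp(ci_pool) else ci_pool,
                 p_value = p, tau2 = tau2, Q = q, k = k,
                 cohort_estimates = estimates, scale = scale),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("meta-%s over %d cohorts: %.4f (95%% CI %.4f-%.4f, p = %.3g, tau2 = %.4g)\n",
              x$statistic, x$k, x$value, x$ci95[1], x$ci95[2], x$p_value,
              x$tau2))
  invisible(x)
}

#' Leave-one-out sensitivity of a pooled estimate
#'
#' Re-pools the estimates k times, omitting one cohort each time, to show
#' how much any single cohort drives the meta-estimate.
#'
#' @inheritParams pool_random_effects
#' @return named list of \code{meta_estimate}s, one per omitted cohort.
#' @export
leave_one_out <- function(estimates, scale = NULL, null_value = NULL) {
  stop_if(length(estimates) < 3, "need at least three cohort estimates")
  out <- lapply(seq_along(estimates), function(i)
    pool_random_effects(estimates[-i], scale, null_value))
  names(out) <- vapply(estimates, function(e) e$cohort, "")
  out
}

#' Compare two meta-estimates
#'
#' One-sided z test of \code{a > b}:
#' \eqn{z = (\hat a - \hat b)/\sqrt{se_a^2 + se_b^2}} treating the two
#' pooled estimates as independent.  When the same cohorts underlie both
#' models this is anti-conservative; \code{paired = TRUE} instead pools
#' the per-cohort differences (matched by cohort label) against zero by
#' DerSimonian-Laird.
#'
#' @param a,b \code{meta_estimate}s of the same statistic and scale.
#' @param alternative only \code{"a_greater"} is defined.
#' @param paired use per-cohort difference pooling.
#' @return list with \code{z} and \code{p_one_sided}.
#' @export
compare_meta <- function(a, b, alternative = "a_greater", paired = FALSE) {
  alternative <- match.arg(alternative, "a_greater")
  stop_if(a$statistic != b$statistic || a$scale != b$scale,
          "meta-estimates must share statistic and scale")
  if (!paired) {
    z <- (a$pooled - b$pooled) / sqrt(a$se^2 + b$se^2)
  } else {
    ca <- a$cohort_estimates; cb <- b$cohort_estimates
    na <- vapply(ca, function(e) e$cohort, "")
    nb <- vapply(cb, function(e) e$cohort, "")
    shared <- intersect(na, nb)
    stop_if(length(shared) < 2, "paired comparison needs >= 2 shared cohorts")
    diffs <- lapply(shared, function(co) {
      ea <- ca[[match(co, na)]]; eb <- cb[[match(co, nb)]]
      va <- if (a$scale == "log") log(ea$value) else ea$value
      vb <- if (a$scale == "log") log(eb$value) else eb$value
      perf_estimate("difference", va - vb, sqrt(ea$se^2 + eb$se^2),
                    NA_real_, ea$n, co)
    })
    pooled_diff <- pool_random_effects(diffs, scale = "raw", null_value = 0)
    z <- pooled_diff$pooled / pooled_diff$se
  }
  list(z = z, p_one_sided = stats::pnorm(z, lower.tail = FALSE))
}

#' Forest-plot data for a meta-estimate
#'
#' @param meta a [pool_random_effects()] result.
#' @return data.frame with one row per cohort (estimate, CI, relative
#'   random-effects weight) plus a pooled row flagged in \code{pooled}.
#' @export
forest_data <- function(meta) {
  rows <- lapply(meta$cohort_estimates, function(e) {
    data.frame(cohort = e$cohort, estimate = e$value,
               lo = e$ci95[1], hi = e$ci95[2],
               weight = NA_real_, pooled = FALSE)
  })
  df <- do.call(rbind, rows)
  se <- vapply(meta$cohort_estimates, function(e) e$se, 0)
  w <- 1 / (se^2 + meta$tau2)
  df$weight <- w / sum(w)
  rbind(df, data.frame(cohort = "pooled", estimate = meta$value,
                       lo = meta$ci95[1], hi = meta$ci95[2],
                       weight = 1, pooled = TRUE))
}
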