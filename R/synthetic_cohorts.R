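#' Configuration for a synthetic multi-cohort study
#'
#' Defines the statistical structure the downstream analysis assumes: a
#' dual-platform training cohort plus several validation cohorts, planted
#' prognostic gene pairs whose within-sample ordering probability differs
#' between latent risk classes, platform-specific strictly monotone
#' transforms, cohort batch shifts, and right-censored exponential
#' disease-free survival.
#'
#' @param n_genes total number of genes.
#' @param n_signal_pairs number of planted prognostic pairs (uses
#'   \code{2 * n_signal_pairs} distinct genes).
#' @param effect_delta target difference in ordering probability,
#'   \eqn{P(X_i < X_j \mid high) - P(X_i < X_j \mid low)}, in (0, 1].
#' @param cohort_specs data.frame with columns \code{name},
#'   \code{n_samples}, \code{platform} ("sequencing"/"array"),
#'   \code{transform} ("identity", "log2", "affine", "quantile_rankscale"),
#'   \code{affine_a}, \code{affine_b}, \code{batch_shift}, \code{role}
#'   ("train"/"validate").  With dual-platform training there are exactly
#'   two "train" rows with equal \code{n_samples} (same patients, two
#'   platforms).
#' @param prevalence_high probability a patient belongs to the latent
#'   high-risk class.
#' @param hazard_ratio_high hazard multiplier of the high class (> 1).
#' @param baseline_median_dfs_days median DFS of the low class (exponential
#'   baseline, \eqn{\lambda_{low} = \ln 2 / median}).
#' @param censor_rate target fraction of records censored by independent
#'   uniform censoring, in [0, 1).
#' @param dual_platform_training if \code{TRUE}, the training patients are
#'   profiled on both platforms.
#' @param seed root seed; the same config is reproduced byte-identically.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_genes = 500,
                              n_signal_pairs = 5,
                              effect_delta = 0.6,
                              cohort_specs = default_cohort_specs(),
                              prevalence_high = 0.5,
                              hazard_ratio_high = 25,
                              baseline_median_dfs_days = 1825,
                              censor_rate = 0.2,
                              dual_platform_training = TRUE,
                              seed = 1) {
  stop_if(2 * n_signal_pairs > n_genes,
          "need 2 * n_signal_pairs <= n_genes")
  stop_if(effect_delta < 0 || effect_delta > 1, "effect_delta must be in [0, 1]")
  stop_if(prevalence_high <= 0 || prevalence_high >= 1,
          "prevalence_high must be in (0, 1)")
  stop_if(censor_rate < 0 || censor_rate >= 1, "censor_rate must be in [0, 1)")
  stop_if(any(cohort_specs$n_samples <= 0), "cohort sizes must be positive")
  tr <- cohort_specs[cohort_specs$role == "train", , drop = FALSE]
  if (dual_platform_training) {
    stop_if(nrow(tr) != 2 || length(unique(tr$n_samples)) != 1,
            "dual-platform training needs two 'train' rows with equal n_samples")
  } else {
    stop_if(nrow(tr) != 1, "need exactly one 'train' row")
  }
  structure(list(n_genes = n_genes, n_signal_pairs = n_signal_pairs,
                 effect_delta = effect_delta, cohort_specs = cohort_specs,
                 prevalence_high = prevalence_high,
                 hazard_ratio_high = hazard_ratio_high,
                 baseline_median_dfs_days = baseline_median_dfs_days,
                 censor_rate = censor_rate,
                 dual_platform_training = dual_platform_training,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default cohort layout: dual-platform training plus five validation cohorts
#'
#' Mirrors the intended study design at one-tenth scale: 50 training
#' patients profiled on a sequencing and an array platform, and five
#' validation cohorts of 40-80 patients, each with its own monotone
#' transform and batch shift.
#'
#' @return data.frame accepted by [simulation_config()].
#' @export
default_cohort_specs <- function() {
  data.frame(
    name = c("train_seq", "train_array", "V1", "V2", "V3", "V4", "V5"),
    n_samples = c(50, 50, 40, 50, 60, 70, 80),
    platform = c("sequencing", "array", "sequencing", "sequencing",
                 "array", "array", "array"),
    transform = c("identity", "quantile_rankscale", "identity", "log2",
                  "affine", "quantile_rankscale", "log2"),
    affine_a = c(1, 1, 1, 1, 3, 1, 1),
    affine_b = c(0, 0, 0, 0, 10, 0, 0),
    batch_shift = c(0, 0, 0, 1, -2, 0.5, 3),
    role = c("train", "train", rep("validate", 5)),
    stringsAsFactors = FALSE
  )
}

# Strictly increasing within-sample transform; preserves gene orderings.
apply_transform <- function(x, transform, affine_a = 1, affine_b = 0) {
  switch(transform,
    identity = x,
    log2 = apply(x, 2, function(col) log2(col - min(col) + 1)),
    affine = {
      stop_if(affine_a <= 0, "affine slope must be > 0")
      affine_a * x + affine_b
    },
    quantile_rankscale = apply(x, 2, function(col) rank(col) / (length(col) + 1)),
    stop("unknown transform: ", transform)
  )
}

# Upper bound of the uniform censoring distribution solving
# P(C < T) = censor_rate for T ~ mixture of exponentials.
calibrate_censoring <- function(censor_rate, lambdas, probs) {
  if (censor_rate == 0) return(Inf)
  pcens <- function(cmax) {
    s_int <- sum(probs * (1 - exp(-lambdas * cmax)) / lambdas)
    s_int / cmax
  }
  f <- function(cmax) pcens(cmax) - censor_rate
  lo <- 1e-6
  hi <- 10 / min(lambdas)
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
  stop_if(f(hi) > 0, "infeasible censoring calibration")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic multi-cohort study
#'
#' Each patient is drawn into the latent high-risk class with probability
#' \code{prevalence_high}.  For every planted pair a per-sample latent
#' uniform decides the ordering indicator \eqn{I(X_i < X_j)} with
#' probability \eqn{0.5 + \delta/2} in the high class and
#' \eqn{0.5 - \delta/2} in the low class; the two gene values are the
#' sorted pair of two standard normal draws assigned to match the
#' indicator, so the quantity the pair score estimates is controlled
#' exactly.  Noise genes are i.i.d. standard normal in both classes.
#' DFS times are exponential with \eqn{\lambda_{low} = \ln 2 / median}
#' and \eqn{\lambda_{high} = HR \cdot \lambda_{low}}; independent uniform
#' censoring is calibrated to the target censor rate.  The configured
#' monotone transform and batch shift are applied per cohort.
#'
#' @param config a [simulation_config()].
#' @return a \code{synthetic_study} list with elements \code{training}
#'   (list of [cohort_profile()]s, two when dual-platform), \code{validation}
#'   (list of cohort profiles), and \code{truth} (planted pairs and the
#'   per-cohort latent risk classes).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- sprintf("g%04d", seq_len(G))
    sig_idx <- matrix(sample.int(G, 2 * config$n_signal_pairs),
                      ncol = 2, byrow = TRUE)
    truth_pairs <- data.frame(
      gene_i = genes[sig_idx[, 1]], gene_j = genes[sig_idx[, 2]],
      p_high = 0.5 + config$effect_delta / 2,
      p_low = 0.5 - config$effect_delta / 2,
      stringsAsFactors = FALSE)

    lam_low <- log(2) / config$baseline_median_dfs_days
    lam_high <- config$hazard_ratio_high * lam_low
    cmax <- calibrate_censoring(config$censor_rate,
                                c(lam_high, lam_low),
                                c(config$prevalence_high,
                                  1 - config$prevalence_high))

    draw_patients <- function(n, cohort_name) {
      cls_high <- stats::runif(n) < config$prevalence_high
      latent <- matrix(stats::rnorm(G * n), nrow = G,
                       dimnames = list(genes, sprintf("%s_s%03d", cohort_name,
                                                      seq_len(n))))
      for (p in seq_len(nrow(sig_idx))) {
        i <- sig_idx[p, 1]; j <- sig_idx[p, 2]
        p_cls <- ifelse(cls_high, truth_pairs$p_high[p], truth_pairs$p_low[p])
        b <- stats::runif(n) < p_cls          # I(Xi < Xj)
        v <- matrix(stats::rnorm(2 * n), nrow = 2)
        lo <- pmin(v[1, ], v[2, ]); hi <- pmax(v[1, ], v[2, ])
        latent[i, ] <- ifelse(b, lo, hi)
        latent[j, ] <- ifelse(b, hi, lo)
      }
      rate <- ifelse(cls_high, lam_high, lam_low)
      t_event <- stats::rexp(n, rate)
      c_time <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
      time <- pmax(pmin(t_event, c_time), 1e-3)
      event <- as.integer(t_event <= c_time)
      # mild class association for the stage covariate; age uninformative
      figo <- ifelse(cls_high,
                     sample(2:4, n, replace = TRUE, prob = c(0.15, 0.35, 0.5)),
                     sample(2:4, n, replace = TRUE, prob = c(0.4, 0.4, 0.2)))
      clin <- data.frame(sample_id = colnames(latent),
                         dfs_time_days = time, dfs_event = event,
                         age = round(stats::rnorm(n, 60, 10), 1),
                         figo_stage = figo, stringsAsFactors = FALSE)
      list(latent = latent, clinical = clin, class_high = cls_high)
    }

    make_cohort <- function(spec, pat) {
      expr <- apply_transform(pat$latent, spec$transform,
                              spec$affine_a, spec$affine_b) + spec$batch_shift
      colnames(expr) <- colnames(pat$latent)
      suppressMessages(
        cohort_profile(spec$name, expr, pat$clinical, spec$platform))
    }

    specs <- config$cohort_specs
    tr_specs <- specs[specs$role == "train", , drop = FALSE]
    va_specs <- specs[specs$role == "validate", , drop = FALSE]

    tr_pat <- draw_patients(tr_specs$n_samples[1], "train")
    training <- lapply(seq_len(nrow(tr_specs)),
                       function(r) make_cohort(tr_specs[r, ], tr_pat))
    classes <- list(train = tr_pat$class_high)

    validation <- vector("list", nrow(va_specs))
    for (r in seq_len(nrow(va_specs))) {
      pat <- draw_patients(va_specs$n_samples[r], va_specs$name[r])
      validation[[r]] <- make_cohort(va_specs[r, ], pat)
      classes[[va_specs$name[r]]] <- pat$class_high
    }

    structure(list(training = training, validation = validation,
                   truth = list(pairs = truth_pairs, class_high = classes),
                   config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d training profile(s), %d validation cohort(s), %d planted pair(s)\n",
              length(x$training), length(x$validation), nrow(x$truth$pairs)))
  invisible(x)
}

#' Summarize what a synthetic study actually realized
#'
#' Reports, per cohort, the counts of high/low/undefined early-relapse
#' labels and the realized censoring fraction, plus the realized ordering
#' effect of every planted pair (computed against the latent risk class,
#' pooled over all cohorts; barcodes are transform-invariant so the latent
#' or observed scale give the same counts).
#'
#' @param study a [simulate_study()] result.
#' @return list with data.frames \code{cohorts} and \code{pairs}.
#' @export
truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  all_cohorts <- c(study$training[1], study$validation)
  cohort_names <- vapply(all_cohorts, function(co) co$name, "")
  rows <- lapply(all_cohorts, function(co) {
    lab <- co$clinical$label
    data.frame(cohort = co$name, n = length(lab),
               n_high = sum(lab == "high"), n_low = sum(lab == "low"),
               n_undefined = sum(lab == "undefined"),
               censor_rate = mean(co$clinical$dfs_event == 0))
  })
  cohorts <- do.call(rbind, rows)

  cls_key <- c("train", vapply(study$validation, function(co) co$name, ""))
  pairs <- study$truth$pairs
  d_hat <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    num_h <- num_l <- den_h <- den_l <- 0
    for (w in seq_along(all_cohorts)) {
      co <- all_cohorts[[w]]
      cls <- study$truth$class_high[[cls_key[w]]]
      b <- co$expression[pairs$gene_i[p], ] < co$expression[pairs$gene_j[p], ]
      num_h <- num_h + sum(b[cls]); den_h <- den_h + sum(cls)
      num_l <- num_l + sum(b[!cls]); den_l <- den_l + sum(!cls)
    }
    d_hat[p] <- num_h / den_h - num_l / den_l
  }
  pairs$realized_delta <- d_hat
  list(cohorts = cohorts, pairs = pairs)
}
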