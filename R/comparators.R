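#' Clinicopathologic logistic model of early relapse
#'
#' Fits early relapse (label "high" vs "low") on age and ordinal FIGO
#' stage by maximum-likelihood logistic regression (IRLS, tolerance 1e-8,
#' at most 100 iterations).  Samples with an undefined label or a missing
#' covariate are dropped and counted, never imputed.
#'
#' @param clinical data.frame with columns \code{label}, \code{age},
#'   \code{figo_stage}.
#' @param covariates covariate columns to include.
#' @return object of class \code{logistic_model}: list with
#'   \code{coefficients}, \code{covariates}, \code{converged}, \code{n},
#'   \code{n_dropped} and the underlying \code{fit}.
#' @export
fit_clinical_model <- function(clinical, covariates = c("age", "figo_stage")) {
  stop_if(!all(covariates %in% names(clinical)),
          "missing covariate columns: ",
          paste(setdiff(covariates, names(clinical)), collapse = ", "))
  use <- clinical$label != "undefined"
  for (cv in covariates) use <- use & !is.na(clinical[[cv]])
  n_dropped <- sum(!use)
  dat <- clinical[use, , drop = FALSE]
  y <- dat$label == "high"
  stop_if(sum(y) < 10 || sum(!y) < 10,
          "need at least 10 samples per class with complete covariates")
  form <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = cbind(dat, y = y), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  # IRLS reports convergence even under complete separation, where some
  # fitted probabilities are driven to the 0/1 boundary and coefficients
  # diverge; flag that case as non-converged (coefficients are the last
  # iterate).
  separated <- sep_warn ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  structure(list(coefficients = stats::coef(fit), covariates = covariates,
                 converged = fit$converged && !separated,
                 n = nrow(dat), n_dropped = n_dropped, fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n = %d (%d dropped), converged = %s\n",
              x$n, x$n_dropped, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted early-relapse probability from a clinical model
#'
#' @param model a [fit_clinical_model()] result.
#' @param clinical data.frame with the model's covariate columns.
#' @return numeric probabilities (NA where a covariate is missing).
#' @export
predict_clinical <- function(model, clinical) {
  out <- rep(NA_real_, nrow(clinical))
  ok <- rep(TRUE, nrow(clinical))
  for (cv in model$covariates) ok <- ok & !is.na(clinical[[cv]])
  if (any(ok))
    out[ok] <- stats::predict(model$fit, newdata = clinical[ok, , drop = FALSE],
                              type = "response")
  out
}

#' Univariable logistic screen of clinical covariates
#'
#' One logistic fit per covariate against early relapse; covariates that
#' are constant among usable samples are excluded with a warning.
#'
#' @inheritParams fit_clinical_model
#' @return data.frame (one row per usable covariate) with \code{covariate},
#'   \code{odds_ratio}, \code{se_log_or}, \code{p}, \code{n}, sorted by p.
#' @export
univariable_screen <- function(clinical, covariates = c("age", "figo_stage")) {
  rows <- list()
  for (cv in covariates) {
    use <- clinical$label != "undefined" & !is.na(clinical[[cv]])
    dat <- clinical[use, , drop = FALSE]
    if (length(unique(dat[[cv]])) < 2) {
      warning("covariate '", cv, "' is constant among usable samples; excluded",
              call. = FALSE)
      next
    }
    y <- dat$label == "high"
    if (sum(y) < 2 || sum(!y) < 2) {
      warning("covariate '", cv, "': too few samples per class; excluded",
              call. = FALSE)
      next
    }
    fit <- suppressWarnings(
      stats::glm(y ~ x, data = data.frame(y = y, x = dat[[cv]]),
                 family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    sm <- summary(fit)$coefficients
    rows[[cv]] <- data.frame(covariate = cv,
                             odds_ratio = exp(sm["x", "Estimate"]),
                             se_log_or = sm["x", "Std. Error"],
                             p = sm["x", "Pr(>|z|)"],
                             n = nrow(dat), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(covariate = character(0),
                                      odds_ratio = numeric(0),
                                      se_log_or = numeric(0),
                                      p = numeric(0), n = integer(0)))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted gene-signature score
#'
#' Per sample, \eqn{score = \sum_g w_g \tilde x_g / \sum_g |w_g|}, where
#' \eqn{\tilde x_g} is the gene's expression rescaled within the cohort
#' to [-1, 1] via its 2.5%/97.5% quantile range (values clipped to the
#' range first).  Weighted genes absent from the matrix are dropped from
#' both sums and reported.
#'
#' @param expr genes x samples matrix.
#' @param weights named numeric vector of gene weights; zero weights are
#'   ignored.
#' @param q_lo,q_hi rescaling quantiles.
#' @return list of class \code{signature_score}: \code{scores} (named
#'   numeric per sample), \code{gene_weights} (those used),
#'   \code{missing_genes}.
#' @export
signature_score <- function(expr, weights, q_lo = 0.025, q_hi = 0.975) {
  weights <- weights[weights != 0]
  present <- intersect(names(weights), rownames(expr))
  missing <- setdiff(names(weights), present)
  stop_if(length(present) == 0, "no weighted genes present in expression matrix")
  if (length(missing) > 0)
    message("signature_score: dropped absent genes: ",
            paste(missing, collapse = ", "))
  w <- weights[present]
  xt <- t(vapply(present, function(g) {
    x <- expr[g, ]
    qs <- stats::quantile(x, c(q_lo, q_hi), names = FALSE)
    if (qs[2] == qs[1]) return(rep(0, length(x)))
    x <- pmin(pmax(x, qs[1]), qs[2])
    2 * (x - qs[1]) / (qs[2] - qs[1]) - 1
  }, numeric(ncol(expr))))
  scores <- colSums(w * xt) / sum(abs(w))
  structure(list(scores = setNames(scores, colnames(expr)),
                 gene_weights = w, missing_genes = missing),
            class = "signature_score")
}

#' Model-size reduction sweep
#'
#' Retrains the ensemble under shrinking pair budgets (the number of
#' disjoint pairs k each member may use) and reports, per budget, the
#' number of distinct genes and pairs used and the validation meta-AUROC;
#' flags the smallest budget whose AUROC is within \code{tolerance} of
#' the largest budget's.  Because each member's greedy selection list
#' depends only on its resample (not on k), the selections are nested
#' across budgets and the distinct-gene count is non-decreasing in the
#' budget by construction.
#'
#' @param training,validation lists of [cohort_profile()]s.
#' @param sizes vector (length >= 2) of odd pair budgets k to sweep.
#' @param train_config as in [label_shuffle_test()] (its \code{k_grid}
#'   entry is overridden by each budget).
#' @param tolerance AUROC tolerance for the "as good as full" flag.
#' @param seed training seed shared across budgets.
#' @return data.frame with \code{k_budget}, \code{distinct_genes},
#'   \code{distinct_pairs}, \code{meta_auroc}, \code{within_tolerance}.
#' @export
reduction_sweep <- function(training, validation, sizes,
                            train_config = list(), tolerance = 0.01,
                            seed = 1) {
  stop_if(length(sizes) < 2, "need at least two sizes")
  tc <- modifyList(list(B = 512, resample_fraction = 0.8, m = 200),
                   train_config)
  sizes <- sort(sizes)
  rows <- lapply(sizes, function(kk) {
    ens <- train_ensemble(training, B = tc$B,
                          resample_fraction = tc$resample_fraction,
                          m = tc$m, k_grid = kk, cv_folds = 1, seed = seed)
    res <- eval_validation_auroc(ens, validation)
    data.frame(k_budget = kk, distinct_genes = length(ens$distinct_genes),
               distinct_pairs = length(ens$distinct_pairs),
               meta_auroc = res$value)
  })
  out <- do.call(rbind, rows)
  full <- out$meta_auroc[nrow(out)]
  out$within_tolerance <- out$meta_auroc >= full - tolerance
  out
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each set, the one-sided hypergeometric tail probability of drawing
#' at least the observed overlap when \code{|signature|} genes are drawn
#' without replacement from the universe, with \code{|set ∩ universe|}
#' successes.  False-discovery rates are Benjamini-Hochberg across sets.
#'
#' @param signature_genes character vector (intersected with universe).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe character vector of all candidate genes.
#' @return data.frame with \code{set}, \code{set_size}, \code{overlap},
#'   \code{p}, \code{fdr}, sorted by p.
#' @export
hypergeometric_enrichment <- function(signature_genes, gene_sets, universe) {
  stop_if(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  sig <- intersect(unique(signature_genes), universe)
  n_draw <- length(sig)
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(set_u, sig))
    p <- stats::phyper(ov - 1, length(set_u),
                       length(universe) - length(set_u), n_draw,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set_u), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
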