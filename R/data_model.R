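#' Dichotomize disease-free survival into an early-relapse label
#'
#' Patients are labelled \code{"high"} (early relapse) when a relapse or
#' progression event is observed within the threshold, \code{"low"} when
#' follow-up extends past the threshold (regardless of later events), and
#' \code{"undefined"} when the record is censored at or before the threshold
#' (lost to follow-up within the window), in which case the binary endpoint
#' cannot be evaluated.
#'
#' @param dfs_time numeric vector of disease-free survival times in days
#'   (strictly positive).
#' @param dfs_event 0/1 or logical vector; 1 means relapse/progression
#'   observed at \code{dfs_time}.
#' @param threshold_days the early-relapse window; default 365.
#' @param inclusive if \code{TRUE} (default) an event at exactly
#'   \code{threshold_days} counts as early relapse (window is
#'   \eqn{\le} threshold); if \code{FALSE} the window is strict \eqn{<}.
#' @return character vector in \code{c("high", "low", "undefined")}.
#' @examples
#' dichotomize(c(200, 200, 400, 400), c(1, 0, 0, 1))
#' @export
dichotomize <- function(dfs_time, dfs_event, threshold_days = 365,
                        inclusive = TRUE) {
  stop_if(any(!is.finite(dfs_time)) || any(dfs_time <= 0),
          "dfs_time must be finite and > 0")
  dfs_event <- as.logical(dfs_event)
  stop_if(any(is.na(dfs_event)), "dfs_event must be 0/1 with no missing values")
  in_window <- if (inclusive) dfs_time <= threshold_days else dfs_time < threshold_days
  ifelse(!in_window, "low", ifelse(dfs_event, "high", "undefined"))
}

DAYS_PER_MONTH <- 30.44

#' Assemble a cohort profile from an expression matrix and clinical table
#'
#' A cohort profile bundles one cohort's expression matrix (genes x samples),
#' its clinical records and its platform tag, with samples aligned between
#' the two components.  Samples present in only one component are dropped
#' with a message.
#'
#' @param name cohort name.
#' @param expression numeric matrix, genes in rows (unique rownames),
#'   samples in columns (unique colnames), all values finite.
#' @param clinical data.frame with columns \code{sample_id},
#'   \code{dfs_time_days}, \code{dfs_event} and optionally \code{age},
#'   \code{figo_stage} (NA where absent).
#' @param platform \code{"sequencing"} or \code{"array"}.
#' @param threshold_days,inclusive passed to [dichotomize()] to derive the
#'   \code{label} column.
#' @return an object of class \code{cohort_profile}: a list with elements
#'   \code{name}, \code{expression}, \code{clinical} (including a
#'   \code{label} column) and \code{platform}.
#' @export
cohort_profile <- function(name, expression, clinical,
                           platform = c("sequencing", "array"),
                           threshold_days = 365, inclusive = TRUE) {
  platform <- match.arg(platform)
  stop_if(!is.matrix(expression) || !is.numeric(expression),
          "expression must be a numeric matrix")
  stop_if(is.null(rownames(expression)) || is.null(colnames(expression)),
          "expression must have gene rownames and sample colnames")
  stop_if(anyDuplicated(rownames(expression)) > 0,
          "duplicate gene identifiers in expression matrix")
  stop_if(anyDuplicated(colnames(expression)) > 0,
          "duplicate sample identifiers in expression matrix")
  stop_if(any(!is.finite(expression)), "expression values must all be finite")
  req <- c("sample_id", "dfs_time_days", "dfs_event")
  stop_if(!all(req %in% names(clinical)),
          "clinical table must contain columns: ", paste(req, collapse = ", "))
  stop_if(anyDuplicated(clinical$sample_id) > 0,
          "duplicate sample identifiers in clinical table")
  clinical$sample_id <- as.character(clinical$sample_id)
  if (!"age" %in% names(clinical)) clinical$age <- NA_real_
  if (!"figo_stage" %in% names(clinical)) clinical$figo_stage <- NA_integer_

  shared <- intersect(colnames(expression), clinical$sample_id)
  stop_if(length(shared) == 0, "no samples shared between expression and clinical")
  n_drop_expr <- ncol(expression) - length(shared)
  n_drop_clin <- nrow(clinical) - length(shared)
  if (n_drop_expr + n_drop_clin > 0)
    message(sprintf("cohort '%s': dropped %d expression-only and %d clinical-only samples",
                    name, n_drop_expr, n_drop_clin))
  expression <- expression[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL

  stop_if(any(clinical$dfs_time_days <= 0), "dfs_time_days must be > 0")
  clinical$label <- dichotomize(clinical$dfs_time_days, clinical$dfs_event,
                                threshold_days, inclusive)
  structure(list(name = name, expression = expression, clinical = clinical,
                 platform = platform),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> '%s' (%s): %d genes x %d samples; labels: %s\n",
              x$name, x$platform, nrow(x$expression), ncol(x$expression),
              paste(names(table(x$clinical$label)), table(x$clinical$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Load one cohort from a TSV expression matrix and CSV clinical table
#'
#' The expression file is tab-delimited with a \code{gene_id} first column
#' and one column per sample.  The clinical file is CSV with header
#' \code{sample_id,dfs_time_days,dfs_event,age,figo_stage,cohort,platform};
#' empty strings mean absent.  Gene identifiers are matched as exact
#' strings; an optional two-column mapping file (source_id, target_id,
#' tab-delimited) relabels genes before alignment.
#'
#' @param expression_path,clinical_path file paths.
#' @param platform \code{"sequencing"} or \code{"array"}.
#' @param name cohort name; defaults to the clinical table's \code{cohort}
#'   column when present, else the expression file stem.
#' @param time_unit unit of the survival time column: \code{"days"} or
#'   \code{"months"} (converted at 30.44 days/month).
#' @param gene_map optional path to a two-column TSV (source_id, target_id).
#' @param threshold_days,inclusive passed to [dichotomize()].
#' @return a [cohort_profile()].
#' @export
load_cohort <- function(expression_path, clinical_path,
                        platform = c("sequencing", "array"),
                        name = NULL, time_unit = c("days", "months"),
                        gene_map = NULL, threshold_days = 365,
                        inclusive = TRUE) {
  platform <- match.arg(platform)
  time_unit <- match.arg(time_unit)

  raw <- utils::read.delim(expression_path, check.names = FALSE,
                           colClasses = "character")
  stop_if(names(raw)[1] != "gene_id",
          "expression file must have 'gene_id' as its first column")
  genes <- raw$gene_id
  stop_if(anyDuplicated(genes) > 0, "duplicate gene identifiers in ",
          expression_path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]), call. = FALSE)
  rownames(num) <- genes

  if (!is.null(gene_map)) {
    map <- utils::read.delim(gene_map, header = TRUE, colClasses = "character")
    idx <- match(rownames(num), map[[1]])
    keep <- !is.na(idx)
    num <- num[keep, , drop = FALSE]
    rownames(num) <- map[[2]][idx[keep]]
    stop_if(anyDuplicated(rownames(num)) > 0,
            "gene map produced duplicate target identifiers")
  }

  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  req <- c("sample_id", "dfs_time_days", "dfs_event")
  stop_if(!all(req %in% names(clin)),
          "clinical file must contain columns: ", paste(req, collapse = ", "))
  if (time_unit == "months")
    clin$dfs_time_days <- clin$dfs_time_days * DAYS_PER_MONTH
  stop_if(any(clin$dfs_time_days <= 0, na.rm = TRUE), "dfs_time_days must be > 0")
  if (is.null(name))
    name <- if ("cohort" %in% names(clin) && !all(is.na(clin$cohort)))
      clin$cohort[!is.na(clin$cohort)][1]
    else sub("\\.[^.]*$", "", basename(expression_path))

  cohort_profile(name, num, clin, platform, threshold_days, inclusive)
}

#' Write a cohort profile to the package's on-disk formats
#'
#' Writes \code{<name>_expression.tsv} (gene_id + one column per sample)
#' and \code{<name>_clinical.csv} under \code{dir}.
#'
#' @param cohort a [cohort_profile()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, paste0(cohort$name, "_expression.tsv"))
  cf <- file.path(dir, paste0(cohort$name, "_clinical.csv"))
  df <- data.frame(gene_id = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE)
  utils::write.table(df, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- cohort$clinical
  clin$cohort <- cohort$name
  clin$platform <- cohort$platform
  cols <- c("sample_id", "dfs_time_days", "dfs_event", "age", "figo_stage",
            "cohort", "platform")
  utils::write.csv(clin[, cols], cf, row.names = FALSE, na = "")
  invisible(c(expression = ef, clinical = cf))
}

#' Restrict a cohort to samples with a defined early-relapse label
#'
#' Samples censored within the early-relapse window carry no information
#' about the binary endpoint and are excluded from binary evaluation
#' (AUROC, balanced accuracy).  The input cohort is unchanged.
#'
#' @param cohort a [cohort_profile()].
#' @return a new \code{cohort_profile} containing only samples with label
#'   \code{"high"} or \code{"low"}; the number excluded is attached as
#'   attribute \code{"n_excluded"}.
#' @export
filter_for_binary_eval <- function(cohort) {
  keep <- cohort$clinical$label != "undefined"
  stop_if(!any(keep), "no evaluable samples: all censored within the window")
  out <- cohort
  out$expression <- cohort$expression[, keep, drop = FALSE]
  out$clinical <- cohort$clinical[keep, , drop = FALSE]
  rownames(out$clinical) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}
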