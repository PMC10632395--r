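#' Top-scoring-pair statistics for all gene pairs
#'
#' For every unordered gene pair (i, j) computes the TSP score
#' \eqn{\Delta_{ij} = |\hat P(X_i < X_j \mid high) - \hat P(X_i < X_j \mid low)|},
#' where the probabilities are within-class fractions of samples with
#' \code{value(i) < value(j)}; the orientation (\code{TRUE} when
#' \eqn{X_i < X_j} is more frequent in the high class, i.e. that ordering
#' votes high-risk); and the secondary rank-difference score
#' \eqn{\gamma_{ij}}, the absolute difference between the two classes'
#' mean within-sample rank gaps, used to break score ties.
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels logical (or "high"/"low") vector, one per sample;
#'   \code{TRUE}/"high" marks the early-relapse class.
#' @return data.frame with one row per pair: \code{gene_i}, \code{gene_j}
#'   (lexicographically ordered within the pair), \code{delta},
#'   \code{orientation}, \code{gamma}, \code{pair_id}.
#' @export
pair_score_table <- function(expr, labels) {
  labels <- as_high_logical(labels)
  stop_if(length(labels) != ncol(expr), "labels must match sample count")
  stop_if(!any(labels) || !any(!labels), "both classes must be non-empty")
  G <- nrow(expr)
  stop_if(G < 2, "need at least two genes")
  hi <- which(labels); lo <- which(!labels)

  # P(Xi < Xj | class) for all (i, j): row i of p_hi holds, per j, the
  # high-class fraction of samples with x_i < x_j.  Counts are exact
  # integers; a single double division keeps the statistic bit-identical
  # to a per-sample counting oracle (rowMeans' long-double accumulation
  # would double-round).
  n_hi <- length(hi); n_lo <- length(lo)
  p_hi <- p_lo <- matrix(0, G, G)
  for (i in seq_len(G)) {
    less <- sweep(expr, 2, expr[i, ], ">")   # [j, s] TRUE iff x_i < x_j
    p_hi[i, ] <- rowSums(less[, hi, drop = FALSE]) / n_hi
    p_lo[i, ] <- rowSums(less[, lo, drop = FALSE]) / n_lo
  }
  # within-sample ranks over the genes supplied; rank sums are exact
  # multiples of 1/2
  R <- apply(expr, 2, rank)
  s_hi <- rowSums(R[, hi, drop = FALSE])
  s_lo <- rowSums(R[, lo, drop = FALSE])

  idx <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d_signed <- p_hi[idx] - p_lo[idx]
  gamma <- abs((s_hi[j] - s_hi[i]) / n_hi - (s_lo[j] - s_lo[i]) / n_lo)
  gn <- rownames(expr) %||% as.character(seq_len(G))
  # canonical order: lexicographically smaller gene id first
  swap <- gn[i] > gn[j]
  a <- ifelse(swap, gn[j], gn[i]); b <- ifelse(swap, gn[i], gn[j])
  d_signed[swap] <- -d_signed[swap]
  data.frame(gene_i = a, gene_j = b,
             delta = abs(d_signed),
             orientation = d_signed >= 0,
             gamma = gamma,
             pair_id = paste(a, b, sep = "|"),
             stringsAsFactors = FALSE)
}

as_high_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "high"
}

#' Score one gene pair
#'
#' @inheritParams pair_score_table
#' @param gene_i,gene_j gene identifiers present in \code{expr}.
#' @return list with \code{delta}, \code{orientation}, \code{gamma}.
#' @export
pair_score <- function(expr, labels, gene_i, gene_j) {
  stop_if(gene_i == gene_j, "gene_i and gene_j must differ")
  for (g in c(gene_i, gene_j))
    stop_if(!g %in% rownames(expr), "gene not in expression matrix: ", g)
  labels <- as_high_logical(labels)
  stop_if(!any(labels) || !any(!labels), "both classes must be non-empty")
  xi <- expr[gene_i, ]; xj <- expr[gene_j, ]
  p_h <- sum(xi[labels] < xj[labels]) / sum(labels)
  p_l <- sum(xi[!labels] < xj[!labels]) / sum(!labels)
  R <- apply(expr, 2, rank)
  gap <- R[gene_j, ] - R[gene_i, ]
  gamma <- abs(sum(gap[labels]) / sum(labels) -
                 sum(gap[!labels]) / sum(!labels))
  list(delta = abs(p_h - p_l), orientation = p_h >= p_l, gamma = gamma)
}

#' Rank-sum gene filter
#'
#' Retains the \code{m} genes whose expression best separates the two
#' classes by the absolute standardized Wilcoxon rank-sum statistic
#' (normal approximation with tie correction).  Deterministic ordering:
#' statistic descending, gene id ascending.
#'
#' @inheritParams pair_score_table
#' @param m number of genes to keep.
#' @return character vector of \code{m} gene identifiers.
#' @export
wilcoxon_filter <- function(expr, labels, m) {
  stop_if(m <= 0, "m must be positive")
  stop_if(m > nrow(expr), "m exceeds number of genes")
  labels <- as_high_logical(labels)
  stop_if(!any(labels) || !any(!labels), "both classes must be non-empty")
  n <- ncol(expr); n1 <- sum(labels); n0 <- n - n1
  z <- apply(expr, 1, function(x) {
    r <- rank(x)
    w <- sum(r[labels])
    mu <- n1 * (n + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n0 / 12 * ((n + 1) - tie_term)
    if (v <= 0) 0 else (w - mu) / sqrt(v)
  })
  gn <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  ord <- order(-abs(z), gn)
  gn[ord][seq_len(m)]
}

# Greedy disjoint selection: pairs sorted by (delta desc, gamma desc,
# pair_id asc); a pair is taken when neither gene is already used.
select_disjoint_pairs <- function(ptab, k_max = Inf) {
  ord <- order(-ptab$delta, -ptab$gamma, ptab$pair_id)
  ptab <- ptab[ord, , drop = FALSE]
  used <- character(0)
  keep <- integer(0)
  for (r in seq_len(nrow(ptab))) {
    if (length(keep) >= k_max) break
    if (ptab$gene_i[r] %in% used || ptab$gene_j[r] %in% used) next
    keep <- c(keep, r)
    used <- c(used, ptab$gene_i[r], ptab$gene_j[r])
  }
  out <- ptab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

vote_high <- function(bits, orientation) {
  # bits: pairs x samples; oriented vote = bit agrees with orientation
  votes <- bits == orientation          # recycles orientation down columns
  colSums(votes) > nrow(bits) / 2
}

#' Train a single k-TSP model
#'
#' (1) filters to \code{m} genes by [wilcoxon_filter()]; (2) scores all
#' pairs of retained genes; (3) greedily selects disjoint pairs in
#' (delta desc, gamma desc, pair id asc) order; (4) picks \code{k} from
#' \code{k_grid} by stratified cross-validated balanced accuracy
#' (smallest \code{k} on ties; skipped when the grid has one entry);
#' (5) returns the top-k disjoint pairs scored on all data.
#'
#' @inheritParams pair_score_table
#' @param m gene-filter size.
#' @param k_grid candidate numbers of pairs, odd integers.
#' @param cv_folds stratified folds for the k selection.
#' @param seed seed for fold assignment.
#' @return an object of class \code{ktsp_model}: list with \code{pairs}
#'   (data.frame gene_i, gene_j, delta, orientation, gamma), \code{k},
#'   and \code{training_meta}.
#' @export
train_ktsp <- function(expr, labels, m = 200, k_grid = seq(3, 25, by = 2),
                       cv_folds = 5, seed = 1) {
  labels <- as_high_logical(labels)
  stop_if(sum(labels) < 2 || sum(!labels) < 2,
          "need at least two samples per class")
  stop_if(any(k_grid %% 2 == 0) || any(k_grid < 1),
          "k_grid must contain odd integers >= 1")
  m <- min(m, nrow(expr))
  genes <- wilcoxon_filter(expr, labels, m)
  # sort so every pair is scored in canonical orientation: P(Xi < Xj)
  # computed from the complementary count differs by 1 ulp, which would
  # make tie-breaking depend on the filter's ordering
  sub <- expr[sort(genes), , drop = FALSE]
  ptab <- pair_score_table(sub, labels)
  sel <- select_disjoint_pairs(ptab, max(k_grid))
  stop_if(nrow(sel) < min(k_grid),
          "fewer than min(k_grid) disjoint pairs available")

  k_grid <- sort(unique(k_grid[k_grid <= nrow(sel)]))
  if (length(k_grid) == 0) k_grid <- nrow(sel) - (nrow(sel) + 1) %% 2
  k <- if (length(k_grid) == 1) k_grid else {
    folds <- with_seed(seed, stratified_folds(labels, cv_folds))
    bac_sum <- setNames(numeric(length(k_grid)), k_grid)
    bac_n <- bac_sum
    for (f in seq_len(cv_folds)) {
      tr <- folds != f; te <- folds == f
      if (sum(labels[tr]) < 1 || sum(!labels[tr]) < 1 ||
          sum(labels[te]) < 1 || sum(!labels[te]) < 1) next
      genes_f <- wilcoxon_filter(expr[, tr, drop = FALSE], labels[tr], m)
      ptab_f <- pair_score_table(expr[sort(genes_f), tr, drop = FALSE],
                                 labels[tr])
      sel_f <- select_disjoint_pairs(ptab_f, max(k_grid))
      bits <- barcode_transform(expr[, te, drop = FALSE], sel_f)
      for (gi in seq_along(k_grid)) {
        kk <- min(k_grid[gi], nrow(sel_f))
        pred <- vote_high(bits[seq_len(kk), , drop = FALSE],
                          sel_f$orientation[seq_len(kk)])
        bac_sum[gi] <- bac_sum[gi] +
          balanced_accuracy(ifelse(pred, "high", "low"),
                            ifelse(labels[te], "high", "low"))
        bac_n[gi] <- bac_n[gi] + 1
      }
    }
    stop_if(all(bac_n == 0), "cross-validation produced no usable folds")
    mean_bac <- bac_sum / pmax(bac_n, 1)
    k_grid[which.max(mean_bac)]   # smallest k on ties: which.max takes first
  }

  structure(list(pairs = sel[seq_len(k), , drop = FALSE], k = k,
                 training_meta = list(n_samples = ncol(expr), m = m,
                                      seed = seed)),
            class = "ktsp_model")
}

stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("<ktsp_model> k = %d disjoint pairs (trained on %d samples, filter m = %d)\n",
              x$k, x$training_meta$n_samples, x$training_meta$m))
  invisible(x)
}

#' Binary gene-pair barcode of expression profiles
#'
#' Bit value 1 when \code{expression(gene_i) < expression(gene_j)} within
#' the sample; ties score 0.  Barcodes are invariant to any strictly
#' increasing transform applied within a sample, which is what makes
#' pair-rule predictions portable across platforms.
#'
#' @param expr genes x samples matrix.
#' @param pairs data.frame with \code{gene_i}, \code{gene_j} columns
#'   (e.g. a \code{ktsp_model$pairs}).
#' @return integer matrix, pairs x samples, rownames \code{pair_id}.
#' @export
barcode_transform <- function(expr, pairs) {
  miss <- setdiff(unique(c(pairs$gene_i, pairs$gene_j)), rownames(expr))
  stop_if(length(miss) > 0, "genes missing from expression matrix: ",
          paste(miss, collapse = ", "))
  bits <- expr[pairs$gene_i, , drop = FALSE] < expr[pairs$gene_j, , drop = FALSE]
  bits <- matrix(as.integer(bits), nrow = nrow(pairs),
                 dimnames = list(paste(pairs$gene_i, pairs$gene_j, sep = "|"),
                                 colnames(expr)))
  bits
}

#' Predict early-relapse class with a single k-TSP model
#'
#' Majority vote: a sample is called high-risk when more than half of the
#' k oriented pair rules vote high.
#'
#' @param model a [train_ktsp()] model.
#' @param expr genes x samples matrix.
#' @return character vector ("high"/"low") named by sample.
#' @export
predict_model <- function(model, expr) {
  bits <- barcode_transform(expr, model$pairs)
  pred <- vote_high(bits, model$pairs$orientation)
  setNames(ifelse(pred, "high", "low"), colnames(expr))
}

#' Train an ensemble of k-TSP models on resampled training instances
#'
#' With dual-platform training each patient contributes one instance per
#' platform (same label), so models see both platforms' orderings.  Each
#' of the B members is trained on a class-balanced resample (a fraction of
#' each class, without replacement within a resample) of the instances.
#' Samples with an undefined early-relapse label are excluded from
#' training.
#'
#' @param training list of 1 or 2 [cohort_profile()]s; with 2 they must
#'   share sample ids and labels (the same patients on two platforms).
#' @param B number of ensemble members.
#' @param resample_fraction per-class fraction drawn for each member.
#' @param m,k_grid,cv_folds passed to [train_ktsp()].
#' @param seed root seed; member b uses a derived substream.
#' @return an object of class \code{ktsp_ensemble}: list with
#'   \code{models}, \code{distinct_pairs}, \code{distinct_genes},
#'   \code{gene_universe} and \code{meta}.
#' @export
train_ensemble <- function(training, B = 512, resample_fraction = 0.8,
                           m = 200, k_grid = seq(3, 25, by = 2),
                           cv_folds = 5, seed = 1) {
  stop_if(B < 1, "B must be >= 1")
  if (inherits(training, "cohort_profile")) training <- list(training)
  stop_if(length(training) < 1 || length(training) > 2,
          "training must hold one or two cohort profiles")
  if (length(training) == 2) {
    stop_if(!identical(colnames(training[[1]]$expression),
                       colnames(training[[2]]$expression)),
            "dual-platform training cohorts must share sample ids")
    stop_if(!identical(training[[1]]$clinical$label,
                       training[[2]]$clinical$label),
            "dual-platform training cohorts must share labels")
  }
  common <- Reduce(intersect, lapply(training, function(co) rownames(co$expression)))
  stop_if(length(common) < 4, "too few shared genes across platforms")

  # one instance per patient per platform, with distinct instance ids
  mats <- lapply(seq_along(training), function(w) {
    mm <- training[[w]]$expression[common, , drop = FALSE]
    colnames(mm) <- paste0(colnames(mm), ".p", w)
    mm
  })
  expr <- do.call(cbind, mats)
  labels <- unlist(lapply(training, function(co) co$clinical$label),
                   use.names = FALSE)
  keep <- labels != "undefined"
  stop_if(sum(keep) < 4, "too few labelled training instances")
  expr <- expr[, keep, drop = FALSE]
  lab <- labels[keep] == "high"
  stop_if(sum(lab) < 2 || sum(!lab) < 2, "need two labelled instances per class")

  models <- vector("list", B)
  for (b in seq_len(B)) {
    sb <- substream(seed, b)
    idx <- with_seed(sb, {
      hi <- which(lab); lo <- which(!lab)
      c(sample(hi, max(2, ceiling(resample_fraction * length(hi)))),
        sample(lo, max(2, ceiling(resample_fraction * length(lo)))))
    })
    models[[b]] <- train_ktsp(expr[, idx, drop = FALSE], lab[idx],
                              m = m, k_grid = k_grid, cv_folds = cv_folds,
                              seed = sb)
  }
  pair_ids <- unlist(lapply(models, function(mo) mo$pairs$pair_id))
  genes <- unlist(lapply(models, function(mo) c(mo$pairs$gene_i, mo$pairs$gene_j)))
  structure(list(models = models,
                 distinct_pairs = sort(unique(pair_ids)),
                 distinct_genes = sort(unique(genes)),
                 gene_universe = common,
                 meta = list(B = B, resample_fraction = resample_fraction,
                             m = m, k_grid = k_grid, cv_folds = cv_folds,
                             seed = seed)),
            class = "ktsp_ensemble")
}

#' @export
print.ktsp_ensemble <- function(x, ...) {
  cat(sprintf("<ktsp_ensemble> B = %d models; %d distinct pairs over %d distinct genes\n",
              length(x$models), length(x$distinct_pairs),
              length(x$distinct_genes)))
  invisible(x)
}

#' Continuous ensemble risk score
#'
#' The risk score of a sample is the fraction of ensemble members whose
#' majority vote is high-risk; it lies in [0, 1] and, like every pair-rule
#' quantity, is invariant to within-sample monotone transforms of
#' expression.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param expr genes x samples matrix.
#' @return numeric vector in [0, 1], named by sample.
#' @export
score_ensemble <- function(ensemble, expr) {
  votes <- vapply(ensemble$models,
                  function(mo) predict_model(mo, expr) == "high",
                  logical(ncol(expr)))
  if (ncol(expr) == 1) votes <- matrix(votes, nrow = 1)
  setNames(rowMeans(votes), colnames(expr))
}

#' Write / read an ensemble as stable JSON
#'
#' @param ensemble a [train_ensemble()] result.
#' @param path output file.
#' @return \code{write_model_json} invisibly returns \code{path};
#'   \code{read_model_json} returns a \code{ktsp_ensemble}.
#' @export
write_model_json <- function(ensemble, path) {
  obj <- list(
    models = lapply(ensemble$models, function(mo) {
      list(k = mo$k,
           pairs = lapply(seq_len(nrow(mo$pairs)), function(r)
             list(i = mo$pairs$gene_i[r], j = mo$pairs$gene_j[r],
                  orientation = mo$pairs$orientation[r],
                  delta = mo$pairs$delta[r], gamma = mo$pairs$gamma[r])))
    }),
    meta = ensemble$meta,
    gene_universe = ensemble$gene_universe)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  models <- lapply(obj$models, function(mo) {
    pr <- do.call(rbind, lapply(mo$pairs, function(p)
      data.frame(gene_i = p$i, gene_j = p$j, delta = p$delta,
                 orientation = p$orientation, gamma = p$gamma,
                 pair_id = paste(p$i, p$j, sep = "|"),
                 stringsAsFactors = FALSE)))
    structure(list(pairs = pr, k = mo$k, training_meta = list()),
              class = "ktsp_model")
  })
  pair_ids <- unlist(lapply(models, function(mo) mo$pairs$pair_id))
  genes <- unlist(lapply(models, function(mo) c(mo$pairs$gene_i, mo$pairs$gene_j)))
  structure(list(models = models,
                 distinct_pairs = sort(unique(pair_ids)),
                 distinct_genes = sort(unique(genes)),
                 gene_universe = unlist(obj$gene_universe),
                 meta = obj$meta),
            class = "ktsp_ensemble")
}
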