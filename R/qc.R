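#' Control gene sets for normalization and QC
#'
#' @param essential_genes character vector of common-essential (positive
#'   control) gene labels.
#' @param nonessential_genes character vector of nonessential (negative
#'   control) gene labels; must be disjoint from the essentials.
#' @param expression optional cell line x gene matrix of expression values on
#'   a linear-like scale where `< 0.01` means unexpressed.
#' @return a list of class `control_sets`.
#' @export
control_sets <- function(essential_genes, nonessential_genes,
                         expression = NULL) {
  if (length(intersect(essential_genes, nonessential_genes)))
    stop("essential and nonessential control lists overlap")
  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (is.null(rownames(expression)) || is.null(colnames(expression)))
      stop("expression matrix needs cell line rownames and gene colnames")
  }
  structure(list(essential_genes = essential_genes,
                 nonessential_genes = nonessential_genes,
                 expression = expression),
            class = "control_sets")
}

#' Globally normalize a gene-effect matrix against control genes
#'
#' One affine transform (shift and scale, shared by the whole matrix) chosen
#' so that the median over cell lines of the per-line medians of nonessential
#' control genes is 0 and of essential control genes is -1. Rank-based
#' metrics are unchanged; only the scale becomes interpretable.
#'
#' @param ge a [gene_effect_matrix()].
#' @param controls a [control_sets()] list.
#' @return the normalized matrix, tagged `globally_scaled`, with the applied
#'   `shift`/`scale` in attributes.
#' @export
normalize_global <- function(ge, controls) {
  ess <- intersect(controls$essential_genes, colnames(ge))
  non <- intersect(controls$nonessential_genes, colnames(ge))
  if (!length(ess) || !length(non))
    stop("need at least one essential and one nonessential control gene ",
         "present in the matrix")
  mm <- function(genes)
    stats::median(apply(ge[, genes, drop = FALSE], 1L, stats::median,
                        na.rm = TRUE), na.rm = TRUE)
  m_non <- mm(non); m_ess <- mm(ess)
  if (m_non == m_ess)
    stop("essential and nonessential control medians coincide; ",
         "scale is undefined")
  scale <- m_non - m_ess
  out <- (unclass(ge) - m_non) / scale
  out <- gene_effect_matrix(out, "globally_scaled")
  attr(out, "shift") <- m_non
  attr(out, "scale") <- scale
  out
}

#' Null-normalized median difference
#'
#' `(median(pos) - median(neg)) / MAD(neg)` with the raw (unscaled) median
#' absolute deviation. More negative values mean better separation of
#' depleted positive controls from the negative-control null.
#'
#' @param positive_scores,negative_scores numeric score vectors.
#' @return scalar NNMD.
#' @export
nnmd <- function(positive_scores, negative_scores) {
  positive_scores <- positive_scores[is.finite(positive_scores)]
  negative_scores <- negative_scores[is.finite(negative_scores)]
  if (!length(positive_scores) || !length(negative_scores))
    stop("both score sets must be nonempty")
  med_neg <- stats::median(negative_scores)
  mad_neg <- stats::median(abs(negative_scores - med_neg))
  if (mad_neg == 0) stop("negative controls have zero MAD")
  (stats::median(positive_scores) - med_neg) / mad_neg
}

# genes unexpressed in a given line: expression below the threshold
unexpressed_genes <- function(controls, line, genes, threshold = 0.01) {
  ex <- controls$expression
  if (is.null(ex)) stop("control_sets has no expression matrix")
  if (!line %in% rownames(ex)) return(character())
  g <- intersect(genes, colnames(ex))
  g[which(ex[line, g] < threshold)]
}

#' Unexpressed false-positive rate
#'
#' For each cell line, the fraction of that line's unexpressed genes
#' (expression < 0.01) whose fitness-effect scores fall within the line's
#' most-depleted `depleted_fraction` of all gene scores. Unexpressed genes
#' should have no true knockout phenotype, so any such call is a false
#' positive. Lines without unexpressed genes get `NA` and are excluded from
#' the pooled rate.
#'
#' @param ge a [gene_effect_matrix()].
#' @param controls a [control_sets()] with an expression matrix.
#' @param depleted_fraction depleted quantile defining a "hit" (default 0.15,
#'   roughly the prevalence of true dependencies per line).
#' @return list with `per_line` (named vector) and `pooled` (scalar).
#' @export
unexpressed_false_positive_rate <- function(ge, controls,
                                            depleted_fraction = 0.15) {
  lines <- rownames(ge)
  fp <- total <- stats::setNames(numeric(length(lines)), lines)
  for (cl in lines) {
    unexp <- unexpressed_genes(controls, cl, colnames(ge))
    if (!length(unexp)) { fp[cl] <- NA; total[cl] <- 0; next }
    scores <- ge[cl, ]
    thr <- stats::quantile(scores, depleted_fraction, na.rm = TRUE,
                           names = FALSE)
    fp[cl] <- sum(ge[cl, unexp] <= thr, na.rm = TRUE)
    total[cl] <- sum(is.finite(ge[cl, unexp]))
  }
  per_line <- ifelse(total > 0, fp / total, NA_real_)
  pooled <- sum(fp[total > 0]) / sum(total)
  list(per_line = per_line, pooled = pooled)
}

#' Precision-recall curve
#'
#' Step-style precision-recall computation: candidates are sorted by
#' decreasing score, tied scores are grouped at a single threshold, and the
#' curve records precision and recall after each threshold. The area is the
#' sum of precision times recall increments (no interpolation), matching the
#' usual average-precision convention.
#'
#' @param scores numeric vector (higher = more confidently positive).
#' @param labels logical vector, `TRUE` for positives.
#' @return list with `precision`, `recall`, `thresholds`, `auc`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  P <- sum(labels)
  if (P == 0 || P == length(labels))
    stop("precision-recall needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # cumulative counts at each distinct threshold (ties grouped)
  last_of_tie <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  precision <- tp / (tp + fp)
  recall <- tp / P
  auc <- sum(precision * diff(c(0, recall)))
  list(precision = precision, recall = recall,
       thresholds = s[last_of_tie], auc = auc)
}

#' Essential-gene recall metrics per cell line
#'
#' For each cell line, positives are the essential control genes and
#' negatives are that line's unexpressed genes; the score is the negated gene
#' effect (deeper depletion = higher score). Reports the area under the
#' precision-recall curve and the recall at the deepest threshold reaching
#' precision >= 0.90 (0 if none does).
#'
#' @param ge a [gene_effect_matrix()].
#' @param controls a [control_sets()] with an expression matrix.
#' @return data.frame with columns `cell_line`, `pr_auc`,
#'   `recall_at_90_precision` (NA with a warning when a line lacks one of the
#'   classes).
#' @export
essential_recall_metrics <- function(ge, controls) {
  lines <- rownames(ge)
  out <- data.frame(cell_line = lines, pr_auc = NA_real_,
                    recall_at_90_precision = NA_real_,
                    stringsAsFactors = FALSE)
  ess <- intersect(controls$essential_genes, colnames(ge))
  for (i in seq_along(lines)) {
    unexp <- setdiff(unexpressed_genes(controls, lines[i], colnames(ge)), ess)
    if (!length(unexp) || !length(ess)) {
      warning("cell line ", lines[i], " lacks a control class; metrics are NA")
      next
    }
    genes <- c(ess, unexp)
    labels <- c(rep(TRUE, length(ess)), rep(FALSE, length(unexp)))
    scores <- -ge[lines[i], genes]
    keep <- is.finite(scores)
    if (length(unique(labels[keep])) < 2L) {
      warning("cell line ", lines[i], " lacks a control class; metrics are NA")
      next
    }
    pr <- pr_curve(scores[keep], labels[keep])
    out$pr_auc[i] <- pr$auc
    hit <- pr$precision >= 0.90
    out$recall_at_90_precision[i] <- if (any(hit)) max(pr$recall[hit]) else 0
  }
  out
}
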