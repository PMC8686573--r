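#' Reads-per-million normalization
#'
#' Scales each row (sequenced sample) so its unmasked entries sum to 1e6.
#' `NA` entries are excluded from the denominator and preserved.
#'
#' @param counts numeric matrix, sequences x sgRNAs.
#' @return matrix of the same shape in RPM units.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts, na.rm = TRUE)
  bad <- !is.finite(totals) | totals <= 0
  if (any(bad))
    stop("cannot RPM-normalize sequence(s) with zero or all-NA counts: ",
         paste(rownames(counts)[bad], collapse = ", "))
  counts / totals * 1e6
}

#' Collapse pDNA sequencings to one row per batch
#'
#' Elementwise sums of raw counts over each batch's pDNA sequencings,
#' computed before any RPM scaling. The summed row replaces the batch's pDNA
#' rows and is named `pDNA_<batch>`. `NA` entries in a pDNA row are treated as
#' 0 in the sum (with a message); a fully-`NA` column stays `NA`.
#'
#' @param sd a [screen_data()] object.
#' @return a `screen_data` object with exactly one pDNA row per batch.
#' @export
sum_pdna_batches <- function(sd) {
  stopifnot(inherits(sd, "screen_data"))
  sm <- sd$sequence_map
  pd <- is_pdna_row(sm)
  batches <- unique(sm$pdna_batch[pd])

  pdna_rows <- lapply(batches, function(b) {
    idx <- which(pd & sm$pdna_batch == b)
    block <- sd$counts[idx, , drop = FALSE]
    if (anyNA(block))
      message(sum(is.na(block)), " NA pDNA count(s) in batch ", b,
              " treated as 0 when summing")
    s <- colSums(block, na.rm = TRUE)
    s[colSums(!is.na(block)) == 0L] <- NA_real_
    s
  })
  pdna_mat <- do.call(rbind, pdna_rows)
  rownames(pdna_mat) <- paste0("pDNA_", batches)

  counts <- rbind(pdna_mat, sd$counts[!pd, , drop = FALSE])
  sequence_map <- rbind(
    data.frame(sequence_ID = rownames(pdna_mat), cell_line = "pDNA",
               pdna_batch = batches, days = 0, stringsAsFactors = FALSE),
    sm[!pd, c("sequence_ID", "cell_line", "pdna_batch", "days"), drop = FALSE])
  screen_data(counts, sequence_map, sd$guide_map)
}

#' Log fold change relative to pDNA
#'
#' For each late-time-point sequence k and sgRNA j,
#' `lfc[k, j] = log2(RPM_kj + 1) - log2(RPM_pDNA(b(k)), j + 1)` where b(k) is
#' the pDNA batch of sequence k. pDNA measurements within a batch are summed
#' before RPM scaling.
#'
#' @param sd a [screen_data()] object.
#' @return numeric matrix, late-time-point sequences x sgRNAs, log2 units.
#' @export
compute_lfc <- function(sd) {
  stopifnot(inherits(sd, "screen_data"))
  sd <- sum_pdna_batches(sd)
  rpm <- normalize_rpm(sd$counts)
  sm <- sd$sequence_map
  pd <- is_pdna_row(sm)
  pdna_rpm <- rpm[pd, , drop = FALSE]
  pdna_batch_of_row <- sm$pdna_batch[pd]

  reps <- which(!pd)
  b_idx <- match(sm$pdna_batch[reps], pdna_batch_of_row)
  if (anyNA(b_idx))
    stop("no pDNA measurement for batch(es): ",
         paste(unique(sm$pdna_batch[reps][is.na(b_idx)]), collapse = ", "))
  lfc <- log2(rpm[reps, , drop = FALSE] + 1) - log2(pdna_rpm[b_idx, , drop = FALSE] + 1)
  rownames(lfc) <- sm$sequence_ID[reps]
  lfc
}

#' Naive per-gene fitness scores from log fold changes
#'
#' Per replicate, the gene score is the median LFC over the gene's sgRNAs;
#' per cell line, the median of its replicates' gene scores. This is the
#' model-free baseline estimate of gene fitness effect.
#'
#' @param lfc matrix from [compute_lfc()].
#' @param guide_map data.frame with columns `sgrna`, `gene`.
#' @param sequence_map data.frame mapping `sequence_ID` to `cell_line`.
#' @return a `raw` [gene_effect_matrix()], cell lines x genes.
#' @export
naive_gene_effect <- function(lfc, guide_map, sequence_map) {
  gm <- guide_map[match(colnames(lfc), guide_map$sgrna), , drop = FALSE]
  gene_f <- factor(gm$gene, levels = unique(gm$gene))
  if (anyNA(lfc) && any(rowsum(1 - is.na(t(lfc)), gene_f) == 0))
    warning("gene(s) with all sgRNA LFCs masked in some replicate; scores are NA")
  # replicate x gene medians
  rep_scores <- matrix(NA_real_, nrow(lfc), nlevels(gene_f),
                       dimnames = list(rownames(lfc), levels(gene_f)))
  for (k in seq_len(nrow(lfc)))
    rep_scores[k, ] <- tapply(lfc[k, ], gene_f, stats::median, na.rm = TRUE)

  line_of <- sequence_map$cell_line[match(rownames(lfc), sequence_map$sequence_ID)]
  lines <- unique(line_of)
  values <- do.call(rbind, lapply(lines, function(cl) {
    apply(rep_scores[line_of == cl, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  }))
  rownames(values) <- lines
  gene_effect_matrix(values, "raw")
}

#' Mask suspected clonal outgrowths
#'
#' A clonal outgrowth is a single (replicate, sgRNA) readcount spike unrelated
#' to the intended perturbation (for instance a random fitness mutation in one
#' infected clone). An entry is masked when its log2 fold change versus pDNA
#' exceeds `lfc_threshold` AND exceeds the next-highest LFC among sgRNAs
#' targeting the same gene in that replicate by more than `gap_threshold`.
#' Entries for genes with a single sgRNA are never masked (the gap is
#' undefined). Detection runs on LFCs from batch-summed pDNA; masking is
#' applied to the raw counts so every downstream computation sees it.
#'
#' @param sd a [screen_data()] object.
#' @param lfc_threshold minimum LFC (log2) for a candidate outgrower.
#' @param gap_threshold minimum LFC lead (log2) over the gene's next-highest
#'   sgRNA in the same replicate.
#' @return a `screen_data` object with outgrower counts set `NA`, carrying a
#'   report data.frame (`sequence_ID`, `sgrna`, `gene`, `lfc`, `gap`) in
#'   attribute `"outgrowth_report"`.
#' @export
remove_clonal_outgrowths <- function(sd, lfc_threshold = 2, gap_threshold = 2) {
  stopifnot(inherits(sd, "screen_data"),
            lfc_threshold > 0, gap_threshold > 0)
  lfc <- compute_lfc(sd)
  gm <- sd$guide_map
  gene_of <- gm$gene[match(colnames(lfc), gm$sgrna)]
  gene_f <- factor(gene_of, levels = unique(gene_of))
  multi <- table(gene_f) > 1L

  hits <- list()
  for (k in seq_len(nrow(lfc))) {
    row <- lfc[k, ]
    cand <- which(!is.na(row) & row > lfc_threshold)
    for (j in cand) {
      g <- gene_f[j]
      if (!multi[[as.integer(g)]]) next  # single-sgRNA gene: gap undefined
      sib <- which(gene_f == g)
      sib <- sib[sib != j]
      nxt <- suppressWarnings(max(row[sib], na.rm = TRUE))
      if (!is.finite(nxt)) next
      gap <- row[j] - nxt
      if (gap > gap_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_ID = rownames(lfc)[k], sgrna = colnames(lfc)[j],
          gene = as.character(g), lfc = unname(row[j]), gap = unname(gap),
          stringsAsFactors = FALSE)
    }
  }
  report <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence_ID = character(), sgrna = character(), gene = character(),
               lfc = numeric(), gap = numeric(), stringsAsFactors = FALSE)

  counts <- sd$counts
  if (nrow(report)) {
    idx <- cbind(match(report$sequence_ID, rownames(counts)),
                 match(report$sgrna, colnames(counts)))
    counts[idx] <- NA_real_
  }
  out <- screen_data(counts, sd$sequence_map, sd$guide_map)
  attr(out, "outgrowth_report") <- report
  out
}
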