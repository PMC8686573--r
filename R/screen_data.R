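#' Assemble and validate a pooled CRISPR screen dataset
#'
#' Bundles the three tables that define a pooled knockout screen: the raw
#' readcount matrix (sequences x sgRNAs), the sequence map describing each
#' sequenced sample (cell line or pDNA, pDNA batch, days since infection), and
#' the guide map assigning each sgRNA to exactly one target gene.
#'
#' pDNA (plasmid library) sequencings are identified either by the reserved
#' `cell_line` value `"pDNA"` or by `days == 0`; both conventions are accepted.
#'
#' @param counts numeric matrix of raw readcounts, rows named by sequence ID,
#'   columns named by sgRNA. `NA` marks masked entries; negative values are
#'   rejected. Stored as doubles so masking survives arithmetic.
#' @param sequence_map data.frame with columns `sequence_ID`, `cell_line`,
#'   `pdna_batch`, `days`.
#' @param guide_map data.frame with columns `sgrna`, `gene`.
#' @return An object of class `screen_data`.
#' @examples
#' sim <- simulate_screen(screen_scenario(n_lines = 2, n_genes = 10, seed = 1))
#' sd <- sim$screen
#' dim(sd$counts)
#' @export
screen_data <- function(counts, sequence_map, guide_map) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  sequence_map <- as.data.frame(sequence_map, stringsAsFactors = FALSE)
  guide_map <- as.data.frame(guide_map, stringsAsFactors = FALSE)

  need_seq <- c("sequence_ID", "cell_line", "pdna_batch", "days")
  missing_cols <- setdiff(need_seq, names(sequence_map))
  if (length(missing_cols))
    stop("sequence_map is missing column(s): ", paste(missing_cols, collapse = ", "))
  need_gm <- c("sgrna", "gene")
  missing_cols <- setdiff(need_gm, names(guide_map))
  if (length(missing_cols))
    stop("guide_map is missing column(s): ", paste(missing_cols, collapse = ", "))

  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sequence IDs as rownames and sgRNAs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sequence IDs in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sgRNA labels in counts")
  if (any(counts < 0, na.rm = TRUE))
    stop("negative readcounts found; counts must be nonnegative")

  # each sgRNA maps to exactly one gene
  dup <- unique(guide_map$sgrna[duplicated(guide_map$sgrna)])
  if (length(dup)) {
    err <- structure(
      class = c("multi_target_guide_error", "error", "condition"),
      list(message = paste0(
             "sgRNA(s) mapped to more than one gene: ",
             paste(utils::head(dup, 5), collapse = ", "),
             if (length(dup) > 5) ", ..." else "",
             ". Multi-targeting sgRNAs are not modelled; remove them upstream."),
           call = sys.call(-1)))
    stop(err)
  }

  orphan <- setdiff(colnames(counts), guide_map$sgrna)
  if (length(orphan))
    stop("sgRNA(s) in counts absent from guide_map: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  unseen <- setdiff(rownames(counts), sequence_map$sequence_ID)
  if (length(unseen))
    stop("sequence_ID(s) in counts absent from sequence_map: ",
         paste(utils::head(unseen, 5), collapse = ", "))

  sequence_map <- sequence_map[match(rownames(counts), sequence_map$sequence_ID), ,
                               drop = FALSE]
  rownames(sequence_map) <- NULL
  guide_map <- guide_map[match(colnames(counts), guide_map$sgrna), , drop = FALSE]
  rownames(guide_map) <- NULL

  sequence_map$days <- as.numeric(sequence_map$days)
  if (any(is.na(sequence_map$days)) || any(sequence_map$days < 0))
    stop("sequence_map$days must be nonnegative numbers")

  is_pdna <- sequence_map$cell_line == "pDNA" | sequence_map$days == 0
  if (any(!is_pdna & sequence_map$days <= 0))
    stop("non-pDNA sequences must have days > 0: ",
         paste(sequence_map$sequence_ID[!is_pdna & sequence_map$days <= 0],
               collapse = ", "))

  # every batch used by a cell line must have at least one pDNA sequencing
  line_batches <- unique(sequence_map$pdna_batch[!is_pdna])
  pdna_batches <- unique(sequence_map$pdna_batch[is_pdna])
  bad <- setdiff(line_batches, pdna_batches)
  if (length(bad)) {
    err <- structure(
      class = c("missing_pdna_error", "error", "condition"),
      list(message = paste0("pDNA batch(es) without any pDNA sequencing: ",
                            paste(bad, collapse = ", ")),
           call = sys.call(-1)))
    stop(err)
  }
  lines <- unique(sequence_map$cell_line[!is_pdna])
  if (!length(lines))
    stop("screen contains no late-time-point (non-pDNA) sequences")

  structure(list(counts = counts,
                 sequence_map = sequence_map,
                 guide_map = guide_map),
            class = "screen_data")
}

#' @export
print.screen_data <- function(x, ...) {
  pd <- is_pdna_row(x$sequence_map)
  cat("Pooled CRISPR screen data\n")
  cat(sprintf("  %d sgRNAs targeting %d genes\n",
              ncol(x$counts), length(unique(x$guide_map$gene))))
  cat(sprintf("  %d late-time-point sequences over %d cell line(s), %d pDNA sequence(s) in %d batch(es)\n",
              sum(!pd), length(unique(x$sequence_map$cell_line[!pd])),
              sum(pd), length(unique(x$sequence_map$pdna_batch))))
  nmask <- sum(is.na(x$counts))
  if (nmask) cat(sprintf("  %d masked (NA) count entries\n", nmask))
  invisible(x)
}

# logical vector marking pDNA rows of a sequence map
is_pdna_row <- function(sequence_map) {
  sequence_map$cell_line == "pDNA" | sequence_map$days == 0
}

#' Subset a screen to selected days or cell lines
#'
#' Keeps the pDNA sequencings plus the late-time-point sequences matching the
#' filters, revalidating the result. Useful for comparing fits on subsets of
#' a timecourse.
#'
#' @param sd a [screen_data()] object.
#' @param days optional numeric vector of days to keep.
#' @param cell_lines optional character vector of cell lines to keep.
#' @return a `screen_data` object.
#' @export
filter_screen <- function(sd, days = NULL, cell_lines = NULL) {
  stopifnot(inherits(sd, "screen_data"))
  sm <- sd$sequence_map
  keep <- is_pdna_row(sm)
  late <- !keep
  if (!is.null(days)) late <- late & sm$days %in% days
  if (!is.null(cell_lines)) late <- late & sm$cell_line %in% cell_lines
  keep <- keep | late
  if (!any(late)) stop("filter removes every late-time-point sequence")
  screen_data(sd$counts[keep, , drop = FALSE], sm[keep, , drop = FALSE],
              sd$guide_map)
}

#' Read a screen dataset from delimited files
#'
#' Reads the three standard input tables and returns a validated
#' [screen_data()] bundle. Files are comma-separated with a header row; a
#' `.tsv` extension switches to tab separation. The counts file has sequence
#' IDs in its first column and one column per sgRNA.
#'
#' @param counts_path,sequence_map_path,guide_map_path file paths.
#' @return A validated `screen_data` object.
#' @export
read_screen_data <- function(counts_path, sequence_map_path, guide_map_path) {
  counts <- read_matrix_csv(counts_path)
  sequence_map <- read_table_file(sequence_map_path)
  guide_map <- read_table_file(guide_map_path)
  screen_data(counts, sequence_map, guide_map)
}

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a labelled numeric matrix from a delimited file
#'
#' First column holds row labels, remaining columns are numeric. Empty cells
#' become `NA`. Inverse of [write_matrix_csv()].
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- delim_for(path)
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (length(hdr) < 1L) stop("empty table in ", path)
  # header parsed separately: read.table misassigns columns on header-only
  # files and when labels happen to look numeric
  df <- tryCatch(
    utils::read.table(path, sep = sep, skip = 1L, header = FALSE,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df)) {
    return(matrix(numeric(), 0L, length(hdr) - 1L,
                  dimnames = list(NULL, hdr[-1L])))
  }
  if (ncol(df) != length(hdr))
    stop("malformed table in ", path, ": ", ncol(df),
         " data column(s) under ", length(hdr), " header field(s)")
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, hdr[-1L])
  m
}

#' Write a labelled numeric matrix to a delimited file
#'
#' Writes with a header row and row labels in the first column so that
#' `read_matrix_csv(write_matrix_csv(m, path))` round-trips exactly,
#' including `NA` positions. An empty matrix yields a header-only file.
#'
#' @param m numeric matrix with unique dimnames.
#' @param path destination (`.csv` or `.tsv`).
#' @param label name for the row-label column header.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, label = "row") {
  m <- as.matrix(m)
  if (nrow(m) && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    stop("matrix must have unique row labels to write: ", path)
  labels <- if (is.null(rownames(m))) character(nrow(m)) else rownames(m)
  df <- data.frame(labels, m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- label
  status <- try(utils::write.table(df, path, sep = delim_for(path), qmethod = "double",
                                   row.names = FALSE, col.names = TRUE, quote = FALSE,
                                   na = "NA"), silent = TRUE)
  if (inherits(status, "try-error"))
    stop("failed to write matrix to ", path, ": ", attr(status, "condition")$message)
  invisible(path)
}

#' Construct a gene-effect matrix
#'
#' A cell-line-by-gene matrix of fitness effects (fractional change in growth
#' rate on knockout) tagged with its normalization state.
#'
#' @param values numeric matrix, rows = cell lines, columns = genes.
#' @param normalization one of `"raw"`, `"globally_scaled"`, `"cn_corrected"`.
#' @return a `gene_effect` matrix (numeric matrix with attribute
#'   `normalization`).
#' @export
gene_effect_matrix <- function(values,
                               normalization = c("raw", "globally_scaled",
                                                 "cn_corrected")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene effect matrix needs cell line rownames and gene colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene effect matrix labels must be unique")
  structure(values, normalization = normalization, class = c("gene_effect", "matrix"))
}

#' @export
print.gene_effect <- function(x, ...) {
  cat(sprintf("Gene effect matrix: %d cell line(s) x %d gene(s) [%s]\n",
              nrow(x), ncol(x), attr(x, "normalization")))
  cat(sprintf("  range %.3f .. %.3f\n", min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}
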