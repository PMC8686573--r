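# Shared fixtures and oracles, all built in code.

# hand-built toy screen: one cell line with 3 replicate sequencings, one pDNA
# batch with 2 measurements, 8 sgRNAs over 3 genes
toy_screen <- function() {
  guides <- paste0("sg", 1:8)
  genes <- c("gA", "gA", "gA", "gB", "gB", "gB", "gC", "gC")
  counts <- rbind(
    pdna_1 = c(100, 120, 80, 100, 90, 110, 100, 100),
    pdna_2 = c(110, 100, 90, 100, 100, 100, 95, 105),
    rep_1  = c(90, 130, 70, 100, 85, 120, 100, 105),
    rep_2  = c(95, 125, 75, 105, 80, 115, 98, 103),
    rep_3  = c(85, 135, 65, 95, 90, 125, 102, 100))
  colnames(counts) <- guides
  sequence_map <- data.frame(
    sequence_ID = rownames(counts),
    cell_line = c("pDNA", "pDNA", "lineA", "lineA", "lineA"),
    pdna_batch = "b1",
    days = c(0, 0, 14, 14, 14),
    stringsAsFactors = FALSE)
  guide_map <- data.frame(sgrna = guides, gene = genes,
                          stringsAsFactors = FALSE)
  screen_data(counts, sequence_map, guide_map)
}

# independent oracle for the shifted NB2 cost via R's dnbinom log-pmf:
# lambda(N, mu) - lambda(N, N) = logpmf(N | N) - logpmf(N | mu)
nb_shift_oracle <- function(N, mu, alpha) {
  dnbinom(N, size = 1 / alpha, mu = N, log = TRUE) -
    dnbinom(N, size = 1 / alpha, mu = mu, log = TRUE)
}

# normalize fitted effects against the simulator's truth-derived control sets
norm_with_truth <- function(ge, cls) {
  ctl <- control_sets(names(cls)[cls == "essential"],
                      names(cls)[cls == "neutral"])
  unclass(normalize_global(ge, ctl))
}

# put the true gene-effect matrix on the same (0, -1) control scale
norm_truth_matrix <- function(r, cls) {
  mm <- function(g) median(apply(r[, g, drop = FALSE], 1L, median))
  m_non <- mm(names(cls)[cls == "neutral"])
  m_ess <- mm(names(cls)[cls == "essential"])
  (r - m_non) / (m_non - m_ess)
}
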