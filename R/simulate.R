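#' Define a synthetic pooled-screen scenario
#'
#' Captures every condition of a simulated CRISPR knockout screen: library
#' layout, measurement design, sequencing depth and noise, and the generative
#' truth (gene effects, guide and line efficacies, growth rates, initial
#' abundances, optional clonal outgrowths and copy-number bias).
#'
#' Default conditions emulate a typical mammalian-cell pooled screen:
#' unperturbed growth around 0.25/day (a 2-3 day doubling time), guide
#' efficacies Beta(9, 2), line efficacies uniform on (0.7, 1), lognormal pDNA
#' abundances (sdlog 0.5), a 3-day phenotype delay, and readouts at days 7
#' and 14. Gene effects follow a mixture: `neutral_fraction` genes with r = 0,
#' `essential_fraction` with r ~ Normal(-1, 0.2) shared across lines, and the
#' rest selectively essential in a random `selective_line_fraction` of lines.
#'
#' @param n_lines,n_genes,guides_per_gene library and panel size.
#' @param time_points days since infection of the late readouts.
#' @param replicates_per_timepoint sequenced replicates per line and day.
#' @param depth expected reads per sgRNA per sequencing.
#' @param alpha NB2 overdispersion of simulated counts.
#' @param n_pdna_measurements pDNA sequencings (one batch).
#' @param neutral_fraction,essential_fraction fractions of the gene mixture;
#'   the remainder is selectively essential.
#' @param essential_mean,essential_sd distribution of essential gene effects.
#' @param selective_line_fraction fraction of lines where a selective gene is
#'   essential.
#' @param pj_shape1,pj_shape2 Beta parameters of true guide efficacy.
#' @param p_j optional explicit guide efficacies (scalar or one per sgRNA),
#'   overriding the Beta draw.
#' @param p_c_range range of true line efficacy (drawn uniformly), or supply
#'   `p_c` directly.
#' @param p_c optional explicit per-line efficacies.
#' @param growth_rate_mean,growth_rate_sd per-day unperturbed growth rates.
#' @param d_g phenotype delay, days.
#' @param pdna_sdlog lognormal spread of initial sgRNA abundances.
#' @param outgrowth_rate fraction of (replicate, sgRNA) entries hit by a
#'   clonal outgrowth spike.
#' @param outgrowth_factor multiplicative count spike of an outgrowth.
#' @param cn_bias if `TRUE`, generate a copy-number matrix and add a smooth
#'   per-line-weighted bias surface to the effective gene effects.
#' @param off_target optional list `list(n_genes, r, p)`: plant an off-target
#'   artifact in `n_genes` randomly chosen neutral genes by giving their
#'   first sgRNA an additional two-population depletion with fitness effect
#'   `r` and knockout probability `p` in every line, mimicking a reagent
#'   cutting an unintended essential site.
#' @param exact if `TRUE`, emit exact expected counts instead of NB2 draws
#'   (a noise-free screen).
#' @param seed RNG seed; all output is reproducible from it.
#' @return a list of class `screen_scenario`.
#' @export
screen_scenario <- function(n_lines = 20, n_genes = 250, guides_per_gene = 4,
                            time_points = c(7, 14),
                            replicates_per_timepoint = 1,
                            depth = 500, alpha = 0.05,
                            n_pdna_measurements = 2,
                            neutral_fraction = 0.80,
                            essential_fraction = 0.15,
                            essential_mean = -1, essential_sd = 0.2,
                            selective_line_fraction = 0.2,
                            pj_shape1 = 9, pj_shape2 = 2, p_j = NULL,
                            p_c_range = c(0.7, 1), p_c = NULL,
                            growth_rate_mean = 0.25, growth_rate_sd = 0.025,
                            d_g = 3, pdna_sdlog = 0.5,
                            outgrowth_rate = 0, outgrowth_factor = 2^8,
                            cn_bias = FALSE, off_target = NULL,
                            exact = FALSE, seed = 0) {
  if (depth <= 0) stop("infeasible scenario: depth must be positive")
  if (n_lines < 1 || n_genes < 2 || guides_per_gene < 1)
    stop("infeasible scenario: need >= 1 line, >= 2 genes, >= 1 guide per gene")
  if (neutral_fraction + essential_fraction > 1)
    stop("gene mixture fractions exceed 1")
  sc <- as.list(environment())
  class(sc) <- "screen_scenario"
  sc
}

#' The smooth copy-number bias surface used by the simulator
#'
#' Encodes the empirically observed structure of the cutting-toxicity bias:
#' amplified nonessential genes are spuriously depleted (negative slope in
#' copy number), essential genes show the opposite, attenuated-knockout
#' trend, and a mild quadratic term makes the relationship non-monotone.
#'
#' @param cn copy number in log2(x+1) units.
#' @param m mean gene fitness effect.
#' @return bias values in gene-effect units.
#' @export
cn_bias_surface <- function(cn, m) {
  slope <- -0.4 + 0.55 * stats::plogis(-4 * (m + 0.5))
  (cn - 1) * slope + 0.1 * (cn - 1)^2
}

#' Simulate a pooled CRISPR knockout screen
#'
#' Generates readcounts under the exact two-population growth model: after
#' the phenotype delay, the knocked-out fraction `p_c p_j` of cells carrying
#' sgRNA j grows at `R_c (1 + r_cg)` while the rest keep growing at `R_c`, so
#' the expected relative abundance is
#' `nu0_j (1 + p_c p_j (exp(R_c r_cg (t - d_g)) - 1))`, row-normalized.
#' Counts are NB2 draws around `depth * n_guides * nu` (or exactly the
#' expectation with `exact = TRUE`). Optional clonal outgrowths multiply
#' individual entries by `outgrowth_factor`; optional copy-number bias adds
#' `w_c * cn_bias_surface(cn, mean_effect)` to the effective gene effects
#' driving the dynamics.
#'
#' @param scenario a [screen_scenario()].
#' @return list with `screen` (a [screen_data()]) and `truth` (gene effects,
#'   efficacies, growth rates, initial abundances, gene classes, outgrowth
#'   positions, and copy-number pieces when simulated).
#' @export
simulate_screen <- function(scenario) {
  stopifnot(inherits(scenario, "screen_scenario"))
  sc <- scenario
  set.seed(sc$seed)

  C <- sc$n_lines; G <- sc$n_genes; gp <- sc$guides_per_gene
  J <- G * gp
  genes <- sprintf("gene_%04d", seq_len(G))
  guides <- paste0(rep(genes, each = gp), "_sg", seq_len(gp))
  lines <- sprintf("line_%02d", seq_len(C))
  gidx <- rep(seq_len(G), each = gp)

  # gene mixture
  n_ess <- round(sc$essential_fraction * G)
  n_sel <- round((1 - sc$neutral_fraction - sc$essential_fraction) * G)
  classes <- rep("neutral", G)
  classes[sample.int(G, n_ess + n_sel)] <- c(rep("essential", n_ess),
                                             rep("selective", n_sel))
  r <- matrix(0, C, G, dimnames = list(lines, genes))
  ess_val <- stats::rnorm(G, sc$essential_mean, sc$essential_sd)
  for (g in which(classes == "essential")) r[, g] <- ess_val[g]
  for (g in which(classes == "selective")) {
    hit <- stats::runif(C) < sc$selective_line_fraction
    if (!any(hit)) hit[sample.int(C, 1L)] <- TRUE
    r[hit, g] <- ess_val[g]
  }

  p_j <- if (is.null(sc$p_j)) stats::rbeta(J, sc$pj_shape1, sc$pj_shape2)
         else rep_len(sc$p_j, J)
  names(p_j) <- guides
  p_c <- if (is.null(sc$p_c)) {
    stats::runif(C, sc$p_c_range[1], sc$p_c_range[2])
  } else rep_len(sc$p_c, C)
  names(p_c) <- lines
  R_c <- pmax(stats::rnorm(C, sc$growth_rate_mean, sc$growth_rate_sd), 0.01)
  names(R_c) <- lines

  nu0 <- stats::rlnorm(J, 0, sc$pdna_sdlog)
  nu0 <- nu0 / sum(nu0)
  names(nu0) <- guides

  truth <- list(r = r, p_j = p_j, p_c = p_c, R_c = R_c, nu0 = nu0,
                gene_class = stats::setNames(classes, genes),
                d_g = sc$d_g, alpha = sc$alpha, scenario = sc)

  r_eff <- r
  if (isTRUE(sc$cn_bias)) {
    x <- stats::rgamma(C * G, shape = 8, scale = 0.125)
    amp <- stats::runif(C * G) < 0.1
    x[amp] <- x[amp] * stats::runif(sum(amp), 2, 4)
    cn <- matrix(log2(x + 1), C, G, dimnames = list(lines, genes))
    w_c <- stats::setNames(stats::runif(C, 0.4, 1), lines)
    m_g <- colMeans(r)
    bias <- matrix(0, C, G, dimnames = list(lines, genes))
    for (ci in seq_len(C))
      bias[ci, ] <- w_c[ci] * cn_bias_surface(cn[ci, ], m_g)
    r_eff <- r + bias
    truth$cn <- cn
    truth$w_c <- w_c
    truth$cn_bias <- bias
  }

  off_idx <- integer()
  if (!is.null(sc$off_target)) {
    ot <- sc$off_target
    neutral <- which(classes == "neutral")
    if (length(neutral) < ot$n_genes)
      stop("not enough neutral genes to plant off-target artifacts")
    ot_genes <- sort(sample(neutral, ot$n_genes))
    off_idx <- match(ot_genes, gidx)       # each gene's first guide
    truth$off_target_genes <- genes[ot_genes]
    truth$off_target_guides <- guides[off_idx]
  }

  draw <- function(mu) {
    if (isTRUE(sc$exact)) mu
    else stats::rnbinom(length(mu), mu = mu, size = 1 / sc$alpha)
  }

  # pDNA sequencings (one batch)
  pdna <- do.call(rbind, lapply(seq_len(sc$n_pdna_measurements), function(i) {
    draw(sc$depth * J * nu0)
  }))
  rownames(pdna) <- paste0("pdna_", seq_len(sc$n_pdna_measurements))

  # late time points
  rep_rows <- list(); rep_meta <- list()
  for (ci in seq_len(C)) {
    for (t in sc$time_points) {
      dtp <- max(t - sc$d_g, 0)
      z <- nu0 * (1 + p_c[ci] * p_j * (exp(R_c[ci] * r_eff[ci, gidx] * dtp) - 1))
      if (length(off_idx))
        z[off_idx] <- z[off_idx] *
          (1 + sc$off_target$p * (exp(R_c[ci] * sc$off_target$r * dtp) - 1))
      nu <- z / sum(z)
      for (rep_i in seq_len(sc$replicates_per_timepoint)) {
        id <- sprintf("%s_d%02d_r%d", lines[ci], t, rep_i)
        rep_rows[[id]] <- draw(sc$depth * J * nu)
        rep_meta[[id]] <- data.frame(sequence_ID = id, cell_line = lines[ci],
                                     pdna_batch = "batch1", days = t,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  counts <- rbind(pdna, do.call(rbind, rep_rows))
  colnames(counts) <- guides

  # clonal outgrowth spikes on late-time-point entries
  outgrowths <- data.frame(sequence_ID = character(), sgrna = character(),
                           stringsAsFactors = FALSE)
  if (sc$outgrowth_rate > 0) {
    rep_ids <- names(rep_rows)
    n_entries <- length(rep_ids) * J
    hit <- which(stats::runif(n_entries) < sc$outgrowth_rate)
    if (length(hit)) {
      rowi <- ((hit - 1L) %% length(rep_ids)) + 1L
      coli <- ((hit - 1L) %/% length(rep_ids)) + 1L
      for (i in seq_along(hit)) {
        rid <- rep_ids[rowi[i]]
        counts[rid, coli[i]] <- max(counts[rid, coli[i]], 1) * sc$outgrowth_factor
      }
      outgrowths <- data.frame(sequence_ID = rep_ids[rowi],
                               sgrna = guides[coli],
                               stringsAsFactors = FALSE)
    }
  }
  truth$outgrowths <- outgrowths

  sequence_map <- rbind(
    data.frame(sequence_ID = rownames(pdna), cell_line = "pDNA",
               pdna_batch = "batch1", days = 0, stringsAsFactors = FALSE),
    do.call(rbind, rep_meta))
  guide_map <- data.frame(sgrna = guides, gene = genes[gidx],
                          stringsAsFactors = FALSE)
  list(screen = screen_data(counts, sequence_map, guide_map), truth = truth)
}

#' Registry of standard simulation scenarios
#'
#' * `recovery_small` — 3 lines x 80 genes, the smallest recovery setting.
#' * `recovery_standard` — 20 lines x 250 genes x 4 guides at depth 500.
#' * `timecourse` — one line read out at days 7, 10, 13, 16, 19, 22, 25.
#' * `cn_bias` — 60 lines x 200 genes with a planted copy-number bias
#'   surface and per-line weights.
#' * `outgrowth` — 25 lines with clonal outgrowth spikes at rate 2e-4.
#'
#' @param seed seed applied to every scenario.
#' @return named list of [screen_scenario()] objects.
#' @export
default_scenarios <- function(seed = 0) {
  list(
    recovery_small = screen_scenario(n_lines = 3, n_genes = 80, seed = seed),
    recovery_standard = screen_scenario(n_lines = 20, n_genes = 250,
                                        seed = seed),
    timecourse = screen_scenario(n_lines = 1, n_genes = 250,
                                 time_points = c(7, 10, 13, 16, 19, 22, 25),
                                 seed = seed),
    cn_bias = screen_scenario(n_lines = 60, n_genes = 200, cn_bias = TRUE,
                              seed = seed),
    outgrowth = screen_scenario(n_lines = 25, n_genes = 250,
                                outgrowth_rate = 2e-4, seed = seed)
  )
}
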