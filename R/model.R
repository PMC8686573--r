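#' Model hyperparameters and their defaults
#'
#' Collects every fixed constant of the population model and its fitting
#' schedule. All penalties use the convention `chi * mean(term)`.
#'
#' @param chi_rho weight of the squared pDNA-offset penalty.
#' @param chi_p weight of the guide-efficacy reciprocal penalty applied to the
#'   two most efficacious sgRNAs of each gene.
#' @param chi_R weight of the squared-log growth-rate penalty.
#' @param chi_r1 weight of the squared global-mean gene-effect penalty.
#' @param chi_h weight of the per-gene (Kronecker delta) term of the
#'   hierarchical kernel prior.
#' @param chi_k weight of the Gaussian cross-gene term of the kernel prior.
#' @param sigma kernel width in gene-rank units; the kernel support is
#'   truncated at `3 * sigma` ranks.
#' @param d_g delay in days between infection and onset of the knockout
#'   growth phenotype.
#' @param alpha NB2 overdispersion; a single global value or a named
#'   per-cell-line vector.
#' @param cell_efficacy_percentile quantile of sgRNAs (from the depleted end)
#'   whose late-time fold change anchors the cell-line efficacy estimate.
#' @param cell_efficacy_floor smallest admissible cell-line efficacy.
#' @param time_scale factor applied to days inside the growth exponent
#'   (0.1 = time measured in units of 10 days), for numerical conditioning.
#' @param cost_rescale_target value the core NB2 cost is rescaled to at the
#'   first epoch, so penalty weights act consistently across dataset sizes.
#' @param lr_initial,lr_max,burn_in_epochs learning-rate schedule: geometric
#'   ramp from `lr_initial` to `lr_max` over `burn_in_epochs` epochs.
#' @param gene_effect_only_epochs number of initial epochs during which only
#'   the gene-effect parameters are updated (the core cost is convex in them).
#' @param epochs total training epochs.
#' @param adam_beta1,adam_beta2,adam_eps first-order optimizer constants.
#' @return a list of class `screenpop_hyperparameters`.
#' @export
screen_hyperparameters <- function(chi_rho = 1.0, chi_p = 0.5, chi_R = 0.01,
                                   chi_r1 = 0.1, chi_h = 0.1, chi_k = 0.25,
                                   sigma = 5, d_g = 3, alpha = 0.05,
                                   cell_efficacy_percentile = 0.99,
                                   cell_efficacy_floor = 0.01,
                                   time_scale = 0.1,
                                   cost_rescale_target = 0.67,
                                   lr_initial = 1e-4, lr_max = 0.02,
                                   burn_in_epochs = 50,
                                   gene_effect_only_epochs = 100,
                                   epochs = 801,
                                   adam_beta1 = 0.9, adam_beta2 = 0.999,
                                   adam_eps = 1e-8) {
  hp <- list(chi_rho = chi_rho, chi_p = chi_p, chi_R = chi_R, chi_r1 = chi_r1,
             chi_h = chi_h, chi_k = chi_k, sigma = sigma, d_g = d_g,
             alpha = alpha,
             cell_efficacy_percentile = cell_efficacy_percentile,
             cell_efficacy_floor = cell_efficacy_floor,
             time_scale = time_scale,
             cost_rescale_target = cost_rescale_target,
             lr_initial = lr_initial, lr_max = lr_max,
             burn_in_epochs = burn_in_epochs,
             gene_effect_only_epochs = gene_effect_only_epochs,
             epochs = epochs, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
             adam_eps = adam_eps)
  scalars <- hp[setdiff(names(hp), "alpha")]
  if (any(unlist(scalars) <= 0) && !all(unlist(scalars) > 0))
    stop("all hyperparameters must be positive")
  if (any(hp$alpha <= 0)) stop("alpha must be positive")
  class(hp) <- "screenpop_hyperparameters"
  hp
}

#' Initial relative sgRNA abundance per pDNA batch
#'
#' For each batch the measured starting abundance of sgRNA j is the median,
#' over the batch's pDNA sequencings, of the sgRNA's relative abundance
#' (RPM / 1e6). The model's initial abundance multiplies this by
#' `exp(rho_bj)`, where the free offsets `rho` absorb systematic pDNA
#' measurement error and are re-centered to mean 0 over each gene's sgRNAs
#' within a batch before use.
#'
#' @param sd a [screen_data()] object (raw counts).
#' @param rho optional batch x sgRNA offset matrix; 0 when omitted.
#' @return batch x sgRNA matrix of initial relative abundances.
#' @export
initial_abundance <- function(sd, rho = NULL) {
  stopifnot(inherits(sd, "screen_data"))
  sm <- sd$sequence_map
  pd <- is_pdna_row(sm)
  batches <- unique(sm$pdna_batch[pd])
  rel <- normalize_rpm(sd$counts[pd, , drop = FALSE]) / 1e6
  m <- do.call(rbind, lapply(batches, function(b) {
    apply(rel[sm$pdna_batch[pd] == b, , drop = FALSE], 2L, stats::median,
          na.rm = TRUE)
  }))
  rownames(m) <- batches
  if (any(!is.finite(m) | m <= 0)) {
    bad <- colnames(m)[apply(!is.finite(m) | m <= 0, 2L, any)]
    stop("sgRNA(s) with no measurable pDNA abundance in some batch: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(rho)) return(m)
  rho <- center_rho(rho, sd$guide_map$gene[match(colnames(m), sd$guide_map$sgrna)])
  m * exp(rho)
}

# re-center rho to mean 0 over each gene's sgRNA set, per batch (row)
center_rho <- function(rho, gene_of_col) {
  gene_f <- factor(gene_of_col, levels = unique(gene_of_col))
  for (k in seq_len(nrow(rho))) {
    mu <- tapply(rho[k, ], gene_f, mean)
    rho[k, ] <- rho[k, ] - mu[as.integer(gene_f)]
  }
  rho
}

#' Predicted relative sgRNA abundance under the two-population model
#'
#' Each infected cell either carries a functional knockout (probability
#' `p_c * p_j`) and grows at rate `R_c * (1 + r_cg)` after the phenotype delay
#' `d_g`, or escaped knockout and keeps growing at `R_c`. Dividing out the
#' unperturbed growth, the unnormalized abundance is
#' `Z_cj(t) = nu0_cj * (1 + p_c p_j (exp(R_c r_cg (t - d_g)) - 1))` for
#' `t >= d_g` and `Z_cj(t) = nu0_cj` before the delay; the predicted read
#' proportion is `nu = Z / sum_j(Z)`. The exponent is evaluated as
#' `(R_c r_cg / time_scale) * (time_scale * (t - d_g))`, so predictions are
#' invariant to the conditioning constant `time_scale`.
#'
#' @param nu0 numeric vector of initial relative abundances (one per sgRNA).
#' @param days scalar or vector of measurement times (days since infection).
#' @param r_cg per-sgRNA gene effect (already expanded from genes to guides).
#' @param p_c cell-line knockout efficacy in (0, 1].
#' @param p_j per-sgRNA knockout efficacy in (0, 1].
#' @param R_c unperturbed growth rate of the line.
#' @param d_g phenotype delay, days.
#' @param time_scale conditioning constant (see above).
#' @param exponent_cap growth exponents are clipped at this bound with a
#'   warning; hitting it signals runaway parameters.
#' @return matrix `length(days)` x `length(nu0)` of predicted proportions
#'   `nu`, with attribute `"Z"` holding the unnormalized abundances.
#' @export
predicted_abundance <- function(nu0, days, r_cg, p_c = 1, p_j = 1, R_c = 1,
                                d_g = 3, time_scale = 0.1, exponent_cap = 50) {
  stopifnot(all(days >= 0), all(p_j > 0 & p_j <= 1), all(p_c > 0 & p_c <= 1),
            R_c > 0)
  dt <- time_scale * pmax(days - d_g, 0)
  a <- outer(dt, (R_c / time_scale) * r_cg)   # days x sgRNA exponents
  if (any(a > exponent_cap)) {
    warning("growth exponent clipped at ", exponent_cap,
            "; parameters may be running away")
    a <- pmin(a, exponent_cap)
  }
  q <- rep(p_c * p_j, each = length(days))
  Z <- matrix(nu0, nrow = length(days), ncol = length(nu0), byrow = TRUE) *
    (1 + q * (exp(a) - 1))
  nu <- Z / rowSums(Z)
  attr(nu, "Z") <- Z
  nu
}

#' Shifted NB2 negative log likelihood
#'
#' The NB2 negative binomial has variance `mu + alpha * mu^2`. Keeping only
#' the mu-dependent terms, the negative log likelihood of observing `N` counts
#' when `mu` are expected is
#' `lambda(N, mu) = (N + 1/alpha) ln(1 + alpha mu) - N ln(mu)`.
#' This function returns `lambda(N, mu) - lambda(N, N)`, which is zero when
#' the prediction equals the observation, so a perfect fit has zero cost.
#' For `N = 0` the `N ln(mu)` terms vanish.
#'
#' @param N observed counts (nonnegative; need not be integer).
#' @param mu expected counts (strictly positive).
#' @param alpha overdispersion (strictly positive); recycled against `N`.
#' @return nonnegative values, same shape as `N`.
#' @export
nb2_negative_log_likelihood <- function(N, mu, alpha) {
  if (any(mu <= 0, na.rm = TRUE)) stop("mu must be strictly positive")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (any(N < 0, na.rm = TRUE)) stop("N must be nonnegative")
  inv <- 1 / alpha
  nlog <- function(n, x) ifelse(n > 0, n * log(x), 0)
  (N + inv) * (log1p(alpha * mu) - log1p(alpha * N)) - nlog(N, mu) + nlog(N, N)
}

#' Core NB2 readcount cost of a set of predictions
#'
#' Sums the shifted NB2 term over every unmasked (sequence, sgRNA) entry with
#' `N = 1e6 * n` (observed reads per million) and `mu = 1e6 * nu` (predicted
#' proportion scaled to RPM), using the sequence's cell-line overdispersion.
#' Masked (`NA`) observations contribute 0. Because both sides are in RPM,
#' the cost is invariant to each replicate's sequencing depth.
#'
#' @param n observed proportions matrix (RPM / 1e6), sequences x sgRNAs.
#' @param nu predicted proportions matrix of the same shape.
#' @param alpha overdispersion per sequence row (vector recycled by row) or a
#'   scalar.
#' @return nonnegative scalar.
#' @export
core_cost <- function(n, nu, alpha) {
  stopifnot(identical(dim(n), dim(nu)))
  alpha <- rep_len(alpha, nrow(n))
  tot <- 0
  for (k in seq_len(nrow(n))) {
    ok <- !is.na(n[k, ])
    tot <- tot + sum(nb2_negative_log_likelihood(1e6 * n[k, ok], 1e6 * nu[k, ok],
                                                 alpha[k]))
  }
  tot
}

## ---- penalty terms -------------------------------------------------------
## All penalties are means over their index sets scaled by a chi weight, so
## their magnitudes are comparable across dataset sizes.

#' @rdname penalties
#' @export
penalty_rho <- function(rho, hp) hp$chi_rho * mean(rho^2)

#' Regularization penalties
#'
#' `penalty_rho`: squared pDNA offsets, `chi_rho * mean(rho^2)`.
#'
#' `penalty_guide_efficacy`: mean over genes of the summed reciprocal
#' efficacies of each gene's two currently most efficacious sgRNAs (ties
#' broken by column order), times `chi_p`. Minimizing it forces at least two
#' sgRNAs per gene toward efficacy 1, so a gene's fitness effect can never be
#' carried by a single (possibly off-target) guide.
#'
#' `penalty_growth_rate`: `chi_R * mean((ln R_c)^2)` — negligible while
#' growth rates sit near their constrained mean of 1, large if any line's
#' rate collapses toward 0.
#'
#' `penalty_gene_mean`: `chi_r1 * mean(r_cg)^2`, pinning the global mean gene
#' effect near 0.
#'
#' `penalty_kernel`: smoothed hierarchical prior
#' `mean_{c,g} sum_h kappa_gh (r_cg - rbar_h)^2` with
#' `kappa_gh = chi_h delta_gh + chi_k w_gh`, where `w_gh` is a Gaussian in the
#' rank distance of gene means (width `sigma`, support truncated at
#' `3 sigma`, normalized to sum 1 over each gene's support). The delta term
#' shrinks each line's effect toward the gene's mean across lines; the
#' Gaussian term couples genes with similar mean effects.
#'
#' @param rho batch x sgRNA offset matrix.
#' @param p_j per-sgRNA efficacies in (0, 1].
#' @param gene_of_guide gene label per sgRNA.
#' @param R_c per-line growth rates.
#' @param r gene effect matrix, cell lines x genes.
#' @param hp a [screen_hyperparameters()] list.
#' @param kernel optional precomputed kernel matrix from [kernel_matrix()].
#' @return scalar penalty values.
#' @name penalties
#' @export
penalty_guide_efficacy <- function(p_j, gene_of_guide, hp) {
  idx <- top2_guides(p_j, gene_of_guide)
  hp$chi_p * sum(1 / p_j[idx]) / length(unique(gene_of_guide))
}

# indices of each gene's two most efficacious guides (all of them for
# single-guide genes); ties broken by column order
top2_guides <- function(p_j, gene_of_guide) {
  gene_f <- factor(gene_of_guide, levels = unique(gene_of_guide))
  unlist(lapply(split(seq_along(p_j), gene_f), function(ix) {
    ix[order(-p_j[ix], ix)][seq_len(min(2L, length(ix)))]
  }), use.names = FALSE)
}

#' @rdname penalties
#' @export
penalty_growth_rate <- function(R_c, hp) hp$chi_R * mean(log(R_c)^2)

#' @rdname penalties
#' @export
penalty_gene_mean <- function(r, hp) hp$chi_r1 * mean(r)^2

#' Rank-distance kernel over genes
#'
#' Genes are ranked by their mean effect across cell lines (ties broken by
#' column order). The kernel combines a Kronecker delta (weight `chi_h`) with
#' a Gaussian in rank distance (weight `chi_k`, width `sigma`), truncated at
#' `3 sigma` ranks and with the Gaussian part normalized to sum 1 over each
#' gene's truncated support.
#'
#' @param gene_means vector of per-gene mean effects.
#' @param hp a [screen_hyperparameters()] list.
#' @return G x G kernel matrix (row g = kernel of gene g over genes h).
#' @export
kernel_matrix <- function(gene_means, hp) {
  G <- length(gene_means)
  rk <- rank(gene_means, ties.method = "first")
  d <- abs(outer(rk, rk, "-"))
  w <- exp(-d^2 / (2 * hp$sigma^2))
  w[d > 3 * hp$sigma] <- 0
  w <- w / rowSums(w)
  hp$chi_h * diag(G) + hp$chi_k * w
}

#' @rdname penalties
#' @export
penalty_kernel <- function(r, hp, kernel = NULL) {
  if (is.null(kernel)) kernel <- kernel_matrix(colMeans(r), hp)
  rbar <- colMeans(r)
  C <- nrow(r); G <- ncol(r)
  s2 <- colSums(r^2)                       # sum_c r_cg^2 per gene g
  # sum_{g,h} kappa_gh * sum_c (r_cg - rbar_h)^2, expanded in g/h marginals
  tot <- sum(rowSums(kernel) * s2) -
    2 * C * sum(rbar * (kernel %*% rbar)) +
    C * sum(kernel %*% rbar^2)
  tot / (C * G)
}

#' Combined training cost
#'
#' `C_T = f * C_core + C_rho + C_p + C_R + C_r1 + C_r2`, where `f` is the
#' rescaling factor fixed at the first training epoch so the core cost starts
#' at `cost_rescale_target`.
#'
#' @param n,nu observed and predicted proportion matrices.
#' @param alpha per-sequence overdispersion.
#' @param rho,p_j,R_c,r model parameters.
#' @param gene_of_guide gene label per sgRNA.
#' @param hp hyperparameters.
#' @param rescale core-cost rescaling factor.
#' @param kernel optional precomputed kernel matrix.
#' @return scalar total cost.
#' @export
total_cost <- function(n, nu, alpha, rho, p_j, R_c, r, gene_of_guide, hp,
                       rescale = 1, kernel = NULL) {
  rescale * core_cost(n, nu, alpha) +
    penalty_rho(rho, hp) +
    penalty_guide_efficacy(p_j, gene_of_guide, hp) +
    penalty_growth_rate(R_c, hp) +
    penalty_gene_mean(r, hp) +
    penalty_kernel(r, hp, kernel)
}

#' Estimate per-cell-line knockout efficacy from fold changes
#'
#' Under the two-population model, a fully efficacious sgRNA on a lethal gene
#' leaves only the escaped (non-knockout) fraction `1 - p_c` of cells at late
#' times, so the most-depleted fold changes asymptote at `log2(1 - p_c)`.
#' The estimator takes, per cell line, the mean LFC per sgRNA over the line's
#' last-time-point replicates, reads off the quantile `1 - percentile` (the
#' boundary of the most-depleted 1% by default), and inverts:
#' `p_c = clip(1 - 2^q, floor, 1)`.
#'
#' @param lfc matrix from [compute_lfc()].
#' @param sequence_map data.frame mapping `sequence_ID` to `cell_line`, `days`.
#' @param percentile depth into the depleted tail (default 0.99).
#' @param floor smallest admissible efficacy.
#' @return named vector of efficacies per cell line.
#' @export
estimate_cell_efficacy <- function(lfc, sequence_map, percentile = 0.99,
                                   floor = 0.01) {
  if (ncol(lfc) < 100)
    warning("fewer than 100 sgRNAs; the tail quantile is poorly resolved")
  sm <- sequence_map[match(rownames(lfc), sequence_map$sequence_ID), , drop = FALSE]
  lines <- unique(sm$cell_line)
  p_c <- vapply(lines, function(cl) {
    rows <- which(sm$cell_line == cl)
    rows <- rows[sm$days[rows] == max(sm$days[rows])]
    mean_lfc <- colMeans(lfc[rows, , drop = FALSE], na.rm = TRUE)
    q <- stats::quantile(mean_lfc, probs = 1 - percentile, na.rm = TRUE,
                         names = FALSE)
    min(max(1 - 2^q, floor), 1)
  }, numeric(1))
  names(p_c) <- lines
  p_c
}
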