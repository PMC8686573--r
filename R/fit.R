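#' Learning-rate schedule
#'
#' Geometric ramp from `lr_initial` at epoch 0 to `lr_max` at
#' `burn_in_epochs`, constant afterwards. The slow start prevents the initial
#' cost explosion a fixed large step causes with adaptive first-order
#' optimizers.
#'
#' @param epoch integer epoch (0-based).
#' @param hp a [screen_hyperparameters()] list.
#' @return scalar learning rate.
#' @export
learning_rate <- function(epoch, hp) {
  stopifnot(epoch >= 0)
  frac <- pmin(epoch / hp$burn_in_epochs, 1)
  hp$lr_initial * (hp$lr_max / hp$lr_initial)^frac
}

#' Initialize free model parameters
#'
#' Deterministic given `seed`: pDNA offsets `rho` start at 0; guide
#' efficacies at 1 minus a small uniform negative offset (all in (0.95, 1]);
#' growth rates at 1 plus Gaussian noise (sd 0.01), projected positive with
#' mean exactly 1; gene means and per-line deviations uniform on
#' [-1e-4, 0.5e-4].
#'
#' @param sd a [screen_data()] object.
#' @param hp hyperparameters.
#' @param seed integer RNG seed.
#' @return list with elements `rho` (batch x sgRNA), `p_j` (sgRNA),
#'   `R_c` (cell line), `gene_mean` (gene), `delta` (cell line x gene).
#' @export
initialize_parameters <- function(sd, hp = screen_hyperparameters(), seed = 0) {
  dims <- screen_dims(sd)
  set.seed(seed)
  rho <- matrix(0, dims$B, dims$J, dimnames = list(dims$batches, dims$guides))
  p_j <- 1 - stats::runif(dims$J, 0, 0.05)
  names(p_j) <- dims$guides
  R_c <- 1 + stats::rnorm(dims$C, 0, 0.01)
  R_c <- pmax(R_c, 1e-3)
  R_c <- R_c / mean(R_c)
  names(R_c) <- dims$lines
  gene_mean <- stats::runif(dims$G, -1e-4, 0.5e-4)
  names(gene_mean) <- dims$genes
  delta <- matrix(stats::runif(dims$C * dims$G, -1e-4, 0.5e-4), dims$C, dims$G,
                  dimnames = list(dims$lines, dims$genes))
  list(rho = rho, p_j = p_j, R_c = R_c, gene_mean = gene_mean, delta = delta)
}

# index structure shared by the fit: guides, genes, lines, batches,
# replicate-row maps
screen_dims <- function(sd) {
  sm <- sd$sequence_map
  pd <- is_pdna_row(sm)
  guides <- colnames(sd$counts)
  genes <- unique(sd$guide_map$gene)
  lines <- unique(sm$cell_line[!pd])
  batches <- unique(sm$pdna_batch[pd])
  list(guides = guides, genes = genes, lines = lines, batches = batches,
       J = length(guides), G = length(genes), C = length(lines),
       B = length(batches),
       gidx = match(sd$guide_map$gene, genes),
       rep_rows = which(!pd),
       cidx = match(sm$cell_line[!pd], lines),
       bidx = match(sm$pdna_batch[!pd], batches),
       days = sm$days[!pd])
}

#' Fit the population-dynamics model to a pooled CRISPR screen
#'
#' Estimates per-gene fitness effects (the fractional change in growth rate on
#' knockout), per-sgRNA and per-cell-line knockout efficacies, per-line
#' unperturbed growth rates, and pDNA abundance offsets by minimizing the
#' penalized NB2 readcount cost with a first-order adaptive (Adam-style)
#' optimizer. Training is staged: the core cost is rescaled at the first
#' epoch to `hp$cost_rescale_target`; only the gene-effect parameters move
#' during the first `hp$gene_effect_only_epochs` epochs (the core cost is
#' convex in them); the learning rate ramps geometrically over
#' `hp$burn_in_epochs`. After every epoch, constraints are re-imposed by
#' projection: guide efficacies clipped to (0, 1], growth rates positive with
#' per-fit mean 1, pDNA offsets centered per gene and batch.
#'
#' Cell-line efficacy `p_c` is estimated from the depleted tail of the late
#' time point fold changes before training and held fixed (see
#' [estimate_cell_efficacy()]).
#'
#' Reported gene effects are on the fitted scale: time measured in units of
#' `1 / hp$time_scale` days and mean growth rate 1. The model is scale
#' degenerate between `R_c` and `r_cg`, so only this convention (or a
#' control-based normalization, see [normalize_global()]) makes effects
#' comparable across fits.
#'
#' @param data a [screen_data()] object (mask outgrowths first with
#'   [remove_clonal_outgrowths()] if desired).
#' @param hp a [screen_hyperparameters()] list.
#' @param seed integer seed controlling parameter initialization.
#' @param p_c optional named per-line knockout efficacy overriding the
#'   internal estimate.
#' @param verbose print the cost every 100 epochs.
#' @return an object of class `screenpop`; see [coef.screenpop()],
#'   [summary.screenpop()], [predict.screenpop()].
#' @examples
#' sim <- simulate_screen(screen_scenario(n_lines = 2, n_genes = 20,
#'                                        depth = 300, seed = 7))
#' fit <- screenpop(sim$screen, hp = screen_hyperparameters(epochs = 51),
#'                  seed = 1)
#' dim(coef(fit))
#' @export
screenpop <- function(data, hp = screen_hyperparameters(), seed = 0,
                      p_c = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "screen_data"))
  dims <- screen_dims(data)
  alpha_line <- expand_alpha(hp$alpha, dims$lines)

  lfc <- compute_lfc(data)
  if (is.null(p_c)) {
    p_c <- suppressWarnings(
      estimate_cell_efficacy(lfc, data$sequence_map,
                             percentile = hp$cell_efficacy_percentile,
                             floor = hp$cell_efficacy_floor))
    p_c <- p_c[dims$lines]
  } else {
    if (is.null(names(p_c))) stop("p_c must be a named per-line vector")
    p_c <- p_c[dims$lines]
    if (anyNA(p_c)) stop("p_c is missing value(s) for some cell line")
  }

  m <- initial_abundance(data)[dims$batches, dims$guides, drop = FALSE]

  # observed proportions, masked entries carry weight 0
  rpm <- normalize_rpm(data$counts[dims$rep_rows, , drop = FALSE])
  n <- rpm / 1e6
  W <- 1 * !is.na(n)
  n[is.na(n)] <- 0
  Nmat <- 1e6 * n

  par <- initialize_parameters(data, hp, seed)
  st <- fit_loop(par, dims, m, n, Nmat, W, p_c, alpha_line, hp, verbose)

  r <- sweep(st$par$delta, 2L, st$par$gene_mean, "+")
  dimnames(r) <- list(dims$lines, dims$genes)

  structure(list(
    gene_effect = gene_effect_matrix(r, "raw"),
    guide_efficacy = st$par$p_j,
    cell_efficacy = p_c,
    growth_rate = st$par$R_c,
    rho = st$par$rho,
    alpha = alpha_line,
    gene_mean = st$par$gene_mean,
    cost_history = st$cost_history,
    rescale_factor = st$rescale,
    predicted = st$nu,
    observed = n,
    weights = W,
    nu0_base = m,
    row_totals = rowSums(data$counts[dims$rep_rows, , drop = FALSE],
                         na.rm = TRUE),
    dims = dims,
    guide_map = data$guide_map,
    sequence_map = data$sequence_map[dims$rep_rows, , drop = FALSE],
    hp = hp,
    seed = seed,
    call = match.call()
  ), class = "screenpop")
}

expand_alpha <- function(alpha, lines) {
  if (length(alpha) == 1L && is.null(names(alpha)))
    return(stats::setNames(rep(alpha, length(lines)), lines))
  out <- alpha[lines]
  if (anyNA(out)) stop("alpha is missing value(s) for some cell line")
  out
}

## ---- training loop -------------------------------------------------------

# forward pass + analytic gradients of the total cost. Returns cost pieces
# and gradients for every free parameter group.
sp_cost_grad <- function(par, dims, m, n, Nmat, W, p_c, alpha_line, hp,
                         rescale, lamN_sum, want_grad = TRUE,
                         exponent_cap = 50) {
  cidx <- dims$cidx; bidx <- dims$bidx; gidx <- dims$gidx
  sdt <- hp$time_scale * pmax(dims$days - hp$d_g, 0)
  arow <- alpha_line[cidx]
  invA <- 1 / arow

  r <- sweep(par$delta, 2L, par$gene_mean, "+")
  nu0B <- m * exp(par$rho)
  nu0K <- nu0B[bidx, , drop = FALSE]
  rK <- r[cidx, gidx, drop = FALSE]
  av <- par$R_c[cidx] * sdt
  a <- rK * av
  clipped <- a > exponent_cap
  if (any(clipped)) a[clipped] <- exponent_cap
  E <- exp(a)
  Em1 <- E - 1
  qK <- tcrossprod(p_c[cidx], par$p_j)
  Z <- nu0K * (1 + qK * Em1)
  S <- rowSums(Z)
  nu <- Z / S
  mu <- 1e6 * nu

  lam <- (Nmat + invA) * log1p(arow * mu) - Nmat * log(mu)
  core_raw <- sum(W * lam) - lamN_sum

  kern <- kernel_matrix(colMeans(r), hp)
  pen <- c(rho = penalty_rho(par$rho, hp),
           p = penalty_guide_efficacy(par$p_j, dims$gidx, hp),
           R = penalty_growth_rate(par$R_c, hp),
           r1 = penalty_gene_mean(r, hp),
           r2 = penalty_kernel(r, hp, kern))
  out <- list(core_raw = core_raw, penalties = pen,
              total = rescale * core_raw + sum(pen), nu = nu,
              clipped = any(clipped))
  if (!want_grad) return(out)

  C <- dims$C; G <- dims$G; B <- dims$B; J <- dims$J
  dmu <- W * ((Nmat + invA) * (arow / (1 + arow * mu)) - Nmat / mu)
  dnu <- (1e6 * rescale) * dmu
  H <- rowSums(dnu * nu)
  dZ <- (dnu - H) / S

  # rho: dZ/drho = Z (through nu0 = m exp(rho)); group rows by batch
  g_rho <- matrix(0, B, J)
  acc <- rowsum(dZ * Z, bidx)
  g_rho[as.integer(rownames(acc)), ] <- acc
  g_rho <- g_rho + (2 * hp$chi_rho / (B * J)) * par$rho

  # guide efficacy
  g_pj <- colSums(dZ * nu0K * Em1 * p_c[cidx])
  top2 <- top2_guides(par$p_j, dims$gidx)
  g_pj[top2] <- g_pj[top2] - hp$chi_p / (G * par$p_j[top2]^2)

  # growth rates and gene effects share the exponent derivative
  DA <- dZ * nu0K * qK * E
  DA[clipped] <- 0                       # exponent pinned at the cap
  v <- rowSums(DA * rK) * sdt
  g_R <- as.numeric(rowsum(v, cidx)) +
    (2 * hp$chi_R / C) * log(par$R_c) / par$R_c

  U <- DA * av
  Uc <- rowsum(U, cidx)                  # C x J
  g_r <- t(rowsum(t(Uc), gidx))          # C x G

  # mean penalty
  g_r <- g_r + (2 * hp$chi_r1 * mean(r)) / (C * G)
  # kernel penalty: direct term plus the dependence through the gene means
  rbar <- colMeans(r)
  rs <- rowSums(kern); cs <- colSums(kern)
  g_kern <- (2 / (C * G)) *
    (sweep(r, 2L, rs, "*") -
       matrix(as.numeric(kern %*% rbar), C, G, byrow = TRUE) -
       matrix(as.numeric(crossprod(kern, rbar)) - cs * rbar, C, G, byrow = TRUE))
  g_r <- g_r + g_kern

  out$grad <- list(rho = g_rho, p_j = g_pj, R_c = g_R,
                   gene_mean = colSums(g_r), delta = g_r)
  out
}

adam_new <- function(par) lapply(par, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(par, grad, state, lr, hp, t, groups) {
  for (nm in groups) {
    g <- grad[[nm]]
    state[[nm]]$m <- hp$adam_beta1 * state[[nm]]$m + (1 - hp$adam_beta1) * g
    state[[nm]]$v <- hp$adam_beta2 * state[[nm]]$v + (1 - hp$adam_beta2) * g^2
    mhat <- state[[nm]]$m / (1 - hp$adam_beta1^t)
    vhat <- state[[nm]]$v / (1 - hp$adam_beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + hp$adam_eps)
  }
  list(par = par, state = state)
}

project_parameters <- function(par, dims) {
  par$p_j <- pmin(pmax(par$p_j, 1e-6), 1)
  par$R_c <- pmax(par$R_c, 1e-3)
  par$R_c <- par$R_c / mean(par$R_c)
  par$rho <- center_rho(par$rho, dims$gidx)
  par
}

fit_loop <- function(par, dims, m, n, Nmat, W, p_c, alpha_line, hp, verbose) {
  # constant part of the shifted NB2 cost, lambda(N, N), over unmasked entries
  arow <- alpha_line[dims$cidx]
  invA <- 1 / arow
  lamN <- (Nmat + invA) * log1p(arow * Nmat) -
    ifelse(Nmat > 0, Nmat * log(Nmat), 0)
  lamN_sum <- sum(W * lamN)

  ev0 <- sp_cost_grad(par, dims, m, n, Nmat, W, p_c, alpha_line, hp,
                      rescale = 1, lamN_sum, want_grad = FALSE)
  rescale <- if (ev0$core_raw > 0) hp$cost_rescale_target / ev0$core_raw else 1

  state <- adam_new(par)
  cost_history <- numeric(hp$epochs)
  gene_groups <- c("gene_mean", "delta")
  all_groups <- c("rho", "p_j", "R_c", "gene_mean", "delta")
  warned_clip <- FALSE

  for (epoch in seq_len(hp$epochs) - 1L) {
    ev <- sp_cost_grad(par, dims, m, n, Nmat, W, p_c, alpha_line, hp,
                       rescale, lamN_sum)
    if (!is.finite(ev$total)) {
      stop("non-finite cost at epoch ", epoch,
           "; core = ", signif(ev$core_raw, 4),
           ", penalties = ", paste(signif(ev$penalties, 3), collapse = ", "))
    }
    if (ev$clipped && !warned_clip) {
      warning("growth exponent clipped during training; parameters may be ",
              "running away")
      warned_clip <- TRUE
    }
    cost_history[epoch + 1L] <- ev$total
    groups <- if (epoch < hp$gene_effect_only_epochs) gene_groups else all_groups
    upd <- adam_step(par, ev$grad, state, learning_rate(epoch, hp), hp,
                     t = epoch + 1L, groups = groups)
    par <- project_parameters(upd$par, dims)
    state <- upd$state
    if (verbose && epoch %% 100 == 0)
      cat(sprintf("epoch %4d  cost %.6f\n", epoch, ev$total))
  }

  half <- cost_history[seq(max(1L, hp$epochs - 49L), hp$epochs)]
  trend <- suppressWarnings(stats::cor(seq_along(half), half))
  rise <- (half[length(half)] - half[1L]) / max(abs(half[1L]), 1e-12)
  if (length(half) > 10 && !is.na(trend) && trend > 0.9 && rise > 1e-3)
    warning("cost is persistently increasing in the final epochs; ",
            "consider a smaller learning rate")

  ev <- sp_cost_grad(par, dims, m, n, Nmat, W, p_c, alpha_line, hp,
                     rescale, lamN_sum, want_grad = FALSE)
  nu <- ev$nu
  dimnames(nu) <- dimnames(n)
  list(par = par, cost_history = cost_history, rescale = rescale, nu = nu)
}
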