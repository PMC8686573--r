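#' Knot placement for the 2D copy-number spline
#'
#' Ten knots linearly spaced over the observed copy-number range (after
#' clipping CN values to their 0.1th-99.9th percentiles to stabilize the
#' boundary basis), and five knots in mean-gene-effect space spaced
#' pseudo-exponentially: effects are shifted so the 1st-percentile mean gene
#' effect maps to 1, knots placed geometrically in that shifted space, then
#' shifted back. This concentrates effect knots in the strongly negative
#' region where the copy-number effect changes fastest.
#'
#' @param cn_values numeric vector of copy-number values (log2(x+1) units).
#' @param gene_means numeric vector of per-gene mean fitness effects.
#' @param n_cn,n_effect knot counts per axis.
#' @return list with `knots_cn`, `knots_effect` (sorted), and the clipping
#'   range `cn_range`.
#' @export
place_knots <- function(cn_values, gene_means, n_cn = 10, n_effect = 5) {
  cn_values <- cn_values[is.finite(cn_values)]
  gene_means <- gene_means[is.finite(gene_means)]
  rng <- stats::quantile(cn_values, c(0.001, 0.999), names = FALSE)
  if (diff(rng) <= 0) stop("degenerate copy-number range; cannot place knots")
  knots_cn <- seq(rng[1], rng[2], length.out = n_cn)

  q01 <- stats::quantile(gene_means, 0.01, names = FALSE)
  shift <- 1 - q01                      # q01 maps to 1
  s <- gene_means + shift
  s_hi <- max(s)
  if (s_hi <= 1 || stats::sd(gene_means) == 0)
    stop("degenerate mean-effect axis: gene means span no usable range")
  knots_s <- exp(seq(log(1), log(s_hi), length.out = n_effect))
  knots_effect <- knots_s - shift
  list(knots_cn = knots_cn, knots_effect = sort(knots_effect), cn_range = rng)
}

# clamped cubic B-spline basis over a fixed knot sequence; values outside the
# knot range are clipped to it (constant extrapolation of the edge basis)
bspline_basis <- function(x, knots) {
  x <- pmin(pmax(x, knots[1]), knots[length(knots)])
  aug <- c(rep(knots[1], 3), knots, rep(knots[length(knots)], 3))
  splines::splineDesign(aug, x, ord = 4, outer.ok = TRUE)
}

#' Fit the 2D spline model of copy-number bias
#'
#' Models the copy-number-related component of a gene-effect matrix as
#' `y_cg = w_c * sum_k theta_k B_k(cn_cg, mbar_g)` where `B` is a
#' tensor-product cubic B-spline basis over (copy number, mean gene effect),
#' `theta` are shared coefficients and `w_c` in (0, 1] weights the strength
#' of the effect in each cell line. The cost
#' `sum_cg (r_cg - y_cg)^2 + X_w sum_c ln(w_c)^2` is minimized by
#' alternating exact least squares in `theta` with bounded one-dimensional
#' updates of each `w_c`, until the relative cost change is below `tol`.
#'
#' Two identifiability safeguards keep the surface from absorbing true gene
#' effects rather than copy-number bias. First, the spline is fit to per-gene
#' centered deviations `r_cg - mean_c(r_cg)`: the raw effects are dominated
#' by each gene's mean (its actual essentiality), which lives on the `m` axis
#' and would otherwise be soaked up wholesale by the surface, mean-centering
#' the corrected matrix. Second, the surface is anchored at normal ploidy —
#' the modelled bias is `S(cn, m) - S(1, m)`, zero at a diploid locus
#' (`cn = 1` in log2(x+1) units). Because the surface is shared across genes,
#' its extrapolation still recovers the per-gene mean component of a genuine
#' copy-number bias (genes amplified in most lines), so mean gene effects are
#' approximately, not exactly, preserved.
#'
#' @param ge gene-effect matrix (cell lines x genes); needs >= 3 lines so
#'   mean effects are estimable.
#' @param cn copy-number matrix in log2(x+1) units, aligned to `ge`; genes
#'   absent from `cn` are assumed diploid (value 1).
#' @param X_w weight of the log-squared penalty keeping `w_c` near 1.
#' @param tol relative cost-change convergence tolerance.
#' @param max_rounds cap on alternating rounds.
#' @return list of class `cn_spline_model`: `theta`, `knots`, `w_c`,
#'   `fitted` (the bias surface evaluations y_cg), `cost`.
#' @export
fit_cn_model <- function(ge, cn, X_w = 1e-3, tol = 1e-6, max_rounds = 100) {
  if (nrow(ge) < 3)
    stop("copy-number correction requires at least three cell lines ",
         "to identify mean gene effects")
  cn <- align_cn(cn, ge)
  gene_means <- colMeans(ge, na.rm = TRUE)
  knots <- place_knots(as.numeric(cn), gene_means)

  C <- nrow(ge); G <- ncol(ge)
  B1 <- bspline_basis(as.numeric(cn), knots$knots_cn)        # (C*G) x K1
  B1_ref <- bspline_basis(1, knots$knots_cn)                 # normal ploidy
  B2 <- bspline_basis(rep(gene_means, each = C), knots$knots_effect)
  K1 <- ncol(B1); K2 <- ncol(B2)
  # tensor product of the anchored CN basis, column-major over (k1, k2)
  B <- matrix(0, C * G, K1 * K2)
  for (k2 in seq_len(K2))
    B[, (k2 - 1L) * K1 + seq_len(K1)] <-
      (B1 - matrix(B1_ref, C * G, K1, byrow = TRUE)) * B2[, k2]

  # target: per-gene centered deviations (see identifiability note above)
  y <- as.numeric(sweep(unclass(ge), 2L, gene_means))
  ok <- is.finite(y)
  w <- rep(1, C)
  wv <- rep(w, G)

  # columns with no support (anchored away or empty knot span) are dropped
  live <- colSums(abs(B)) > 1e-10
  Blive <- B[, live, drop = FALSE]

  theta <- rep(0, ncol(B))
  cost <- Inf
  for (round in seq_len(max_rounds)) {
    # theta step: weighted least squares with rows scaled by w_c
    Xw <- Blive[ok, , drop = FALSE] * wv[ok]
    XtX <- crossprod(Xw)
    Xty <- crossprod(Xw, y[ok])
    # small scaled ridge: near-empty basis cells (knot spans with little
    # data) make XtX nearly singular, and unregularized null directions
    # explode; the ridge biases well-supported coefficients negligibly
    lam <- 1e-6 * mean(diag(XtX))
    theta_try <- try(solve(XtX + lam * diag(ncol(XtX)), Xty), silent = TRUE)
    if (inherits(theta_try, "try-error")) {
      warning("singular spline basis; increasing ridge")
      theta_try <- solve(XtX + 1e4 * lam * diag(ncol(XtX)), Xty)
    }
    theta <- rep(0, ncol(B))
    theta[live] <- as.numeric(theta_try)
    f <- matrix(Blive %*% theta[live], C, G)   # unweighted surface

    # w step: per-line bounded 1D minimization
    for (ci in seq_len(C)) {
      fc <- f[ci, ]; rc <- unclass(ge)[ci, ] - gene_means
      use <- is.finite(rc) & is.finite(fc)
      obj <- function(wc) sum((rc[use] - wc * fc[use])^2) + X_w * log(wc)^2
      w[ci] <- stats::optimize(obj, interval = c(1e-3, 1))$minimum
    }
    # snap to the boundary when the unconstrained optimum lies at or past 1
    w[w > 1 - 1e-6] <- 1
    wv <- rep(w, G)

    yhat <- f * w
    new_cost <- sum((y[ok] - as.numeric(yhat)[ok])^2) + X_w * sum(log(w)^2)
    if (is.finite(cost) && abs(cost - new_cost) <= tol * max(cost, 1e-12)) {
      cost <- new_cost
      break
    }
    cost <- new_cost
  }
  fitted <- f * w
  dimnames(fitted) <- dimnames(ge)
  structure(list(theta = theta, knots = knots, w_c = stats::setNames(w, rownames(ge)),
                 fitted = fitted, cost = cost, X_w = X_w),
            class = "cn_spline_model")
}

#' @export
print.cn_spline_model <- function(x, ...) {
  cat("2D copy-number spline model\n")
  cat(sprintf("  %d coefficients, cost %.4f\n", length(x$theta), x$cost))
  cat(sprintf("  per-line weights w_c: median %.2f (range %.2f..%.2f)\n",
              stats::median(x$w_c), min(x$w_c), max(x$w_c)))
  invisible(x)
}

# align a copy-number matrix to a gene-effect matrix; missing genes are
# assumed diploid: log2(1 + 1) = 1
align_cn <- function(cn, ge) {
  cn <- as.matrix(cn)
  if (any(cn < 0, na.rm = TRUE)) stop("copy number (log2(x+1)) must be >= 0")
  out <- matrix(1, nrow(ge), ncol(ge), dimnames = dimnames(ge))
  missing_lines <- setdiff(rownames(ge), rownames(cn))
  if (length(missing_lines))
    stop("copy-number matrix is missing cell line(s): ",
         paste(utils::head(missing_lines, 5), collapse = ", "))
  common_genes <- intersect(colnames(ge), colnames(cn))
  out[, common_genes] <- cn[rownames(ge), common_genes]
  out[is.na(out)] <- 1
  out
}

#' Remove copy-number bias from a gene-effect matrix
#'
#' Fits the 2D spline model of [fit_cn_model()] and returns the residuals
#' `r_cg - y_cg` as the bias-corrected gene effects. Mean gene effects are
#' approximately (not exactly) preserved. The correction is approximately
#' idempotent: re-correcting corrected output changes it very little.
#'
#' @inheritParams fit_cn_model
#' @return a `cn_corrected` [gene_effect_matrix()] with the fitted
#'   [fit_cn_model()] object in attribute `"cn_model"`.
#' @export
correct_copy_number <- function(ge, cn, X_w = 1e-3) {
  model <- fit_cn_model(ge, cn, X_w = X_w)
  out <- gene_effect_matrix(unclass(ge) - model$fitted, "cn_corrected")
  attr(out, "cn_model") <- model
  out
}
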