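#' @export
print.screenpop <- function(x, ...) {
  d <- x$dims
  cat("Population-dynamics model of a pooled CRISPR screen\n")
  cat(sprintf("  %d cell line(s), %d genes, %d sgRNAs, %d replicate sequence(s)\n",
              d$C, d$G, d$J, length(d$rep_rows)))
  cat(sprintf("  cost %.4f -> %.4f over %d epochs (seed %d)\n",
              x$cost_history[1], x$cost_history[length(x$cost_history)],
              length(x$cost_history), x$seed))
  cat(sprintf("  gene effects [%s]: median %.3f, 5%%..95%% = %.3f..%.3f\n",
              attr(x$gene_effect, "normalization"),
              stats::median(x$gene_effect, na.rm = TRUE),
              stats::quantile(x$gene_effect, 0.05, na.rm = TRUE),
              stats::quantile(x$gene_effect, 0.95, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a fitted screen model
#'
#' @param object a [screenpop()] fit.
#' @param ... unused.
#' @return a list of class `summary.screenpop` with per-line and per-guide
#'   summaries.
#' @export
summary.screenpop <- function(object, ...) {
  sm <- object$sequence_map
  lines <- object$dims$lines
  per_line <- data.frame(
    cell_line = lines,
    replicates = as.integer(table(factor(sm$cell_line, levels = lines))),
    cell_efficacy = unname(object$cell_efficacy[lines]),
    growth_rate = unname(object$growth_rate[lines]),
    alpha = unname(object$alpha[lines]),
    median_effect = apply(object$gene_effect, 1L, stats::median, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(per_line) <- NULL
  out <- list(per_line = per_line,
              guide_efficacy = summary(object$guide_efficacy),
              cost_initial = object$cost_history[1],
              cost_final = object$cost_history[length(object$cost_history)],
              epochs = length(object$cost_history))
  class(out) <- "summary.screenpop"
  out
}

#' @export
print.summary.screenpop <- function(x, ...) {
  cat(sprintf("Fit over %d epochs, cost %.4f -> %.4f\n",
              x$epochs, x$cost_initial, x$cost_final))
  cat("Guide efficacy:\n")
  print(x$guide_efficacy)
  cat("Per cell line:\n")
  print(x$per_line, digits = 3)
  invisible(x)
}

#' Gene-effect estimates of a fitted screen model
#'
#' @param object a [screenpop()] fit.
#' @param ... unused.
#' @return the cell-line x gene [gene_effect_matrix()].
#' @export
coef.screenpop <- function(object, ...) object$gene_effect

#' @export
fitted.screenpop <- function(object, ...) object$predicted

#' Residuals of a fitted screen model
#'
#' @param object a [screenpop()] fit.
#' @param type `"proportion"` for observed minus predicted read proportions,
#'   `"deviance"` for signed square roots of each entry's shifted NB2 cost.
#' @param ... unused.
#' @return matrix, replicate sequences x sgRNAs; masked entries are `NA`.
#' @export
residuals.screenpop <- function(object, type = c("proportion", "deviance"),
                                ...) {
  type <- match.arg(type)
  n <- object$observed
  nu <- object$predicted
  out <- if (type == "proportion") {
    n - nu
  } else {
    alpha <- object$alpha[object$dims$cidx]
    dev <- nb2_negative_log_likelihood(1e6 * n, 1e6 * nu, alpha)
    sign(n - nu) * sqrt(2 * pmax(dev, 0))
  }
  out[object$weights == 0] <- NA_real_
  dimnames(out) <- dimnames(n)
  out
}

#' Predicted sgRNA abundance trajectories
#'
#' Evaluates the fitted two-population model for one cell line over a grid of
#' days, returning the predicted relative abundance of every sgRNA.
#'
#' @param object a [screenpop()] fit.
#' @param cell_line which line to predict for (default: first).
#' @param days numeric vector of days since infection.
#' @param ... unused.
#' @return matrix `length(days)` x sgRNAs of predicted proportions.
#' @export
predict.screenpop <- function(object, cell_line = NULL, days = NULL, ...) {
  d <- object$dims
  if (is.null(cell_line)) cell_line <- d$lines[1L]
  ci <- match(cell_line, d$lines)
  if (is.na(ci)) stop("unknown cell line: ", cell_line)
  if (is.null(days)) {
    days <- sort(unique(d$days[d$cidx == ci]))
  }
  # batch of this line's replicates; nu0 = median pDNA abundance * exp(rho)
  bi <- unique(d$bidx[d$cidx == ci])[1L]
  nu0 <- object$nu0_base[bi, ] * exp(center_rho(object$rho, d$gidx)[bi, ])
  r_guide <- object$gene_effect[ci, d$gidx]
  out <- predicted_abundance(nu0, days, r_guide,
                             p_c = object$cell_efficacy[ci],
                             p_j = object$guide_efficacy,
                             R_c = object$growth_rate[ci],
                             d_g = object$hp$d_g,
                             time_scale = object$hp$time_scale)
  rownames(out) <- paste0("day_", days)
  colnames(out) <- d$guides
  out
}

#' Simulate readcounts from a fitted screen model
#'
#' Draws NB2 readcounts at the fitted expected proportions, using each
#' replicate's observed sequencing depth — a parametric-bootstrap companion
#' to [screenpop()].
#'
#' @param object a [screenpop()] fit.
#' @param nsim number of simulated count matrices.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` count matrices shaped like the replicate rows of
#'   the input counts.
#' @export
simulate.screenpop <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  # expected counts: observed total reads per row times predicted proportion
  totals <- object$row_totals
  if (is.null(totals)) totals <- rep(1e6, nrow(object$observed))
  alpha <- object$alpha[object$dims$cidx]
  lapply(seq_len(nsim), function(i) {
    mu <- object$predicted * totals
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(1 / alpha, ncol(mu))),
                  nrow(mu), ncol(mu))
    dimnames(cnt) <- dimnames(object$observed)
    cnt
  })
}

#' Diagnostic plots for a fitted screen model
#'
#' Left: training cost by epoch (log scale). Right: observed versus predicted
#' read proportions on log axes.
#'
#' @param x a [screenpop()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.screenpop <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$cost_history) - 1L, x$cost_history, type = "l",
                 log = "y", xlab = "epoch", ylab = "total cost",
                 main = "training cost", ...)
  ok <- x$weights > 0
  graphics::plot(pmax(x$predicted[ok], 1e-9), pmax(x$observed[ok], 1e-9),
                 log = "xy", pch = ".", xlab = "predicted proportion",
                 ylab = "observed proportion", main = "fit", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
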