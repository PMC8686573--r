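# shared builder: screens of C lines with a planted smooth CN bias
planted_cn_fixture <- function(C = 24, G = 150, w_star = NULL, noise = 0.03,
                               seed = 11) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(C)); genes <- sprintf("g%03d", seq_len(G))
  m_true <- c(rnorm(round(G * 0.2), -1, 0.2),
              rep(0, G - round(G * 0.2)))[sample(G)]
  r <- matrix(rep(m_true, each = C), C, G, dimnames = list(lines, genes))
  cn <- matrix(log2(rgamma(C * G, 8, scale = 0.125) + 1), C, G,
               dimnames = list(lines, genes))
  if (is.null(w_star)) w_star <- rep(1, C)
  bias <- r * 0
  for (ci in seq_len(C))
    bias[ci, ] <- w_star[ci] * cn_bias_surface(cn[ci, ], m_true)
  obs <- gene_effect_matrix(r + bias + matrix(rnorm(C * G, 0, noise), C, G),
                            "raw")
  names(m_true) <- genes
  list(obs = obs, cn = cn, r = r, bias = bias, w_star = w_star,
       m_true = m_true)
}

test_that("knots are linear in CN and pseudo-exponential in effect", {
  kn <- place_knots(seq(0, 2, length.out = 5000), rnorm(200, -0.5, 0.5))
  expect_length(kn$knots_cn, 10)
  expect_equal(kn$knots_cn, seq(min(kn$knots_cn), max(kn$knots_cn),
                                length.out = 10))
  expect_equal(kn$knots_cn[1], 0, tolerance = 0.01)
  expect_equal(kn$knots_cn[10], 2, tolerance = 0.01)

  # effect knots concentrate at the strongly negative end
  kn2 <- place_knots(runif(1000, 0, 2), runif(500, -2, 0.2))
  gaps <- diff(kn2$knots_effect)
  expect_true(all(diff(gaps) > 0))
  expect_lt(kn2$knots_effect[1], -1.8)

  expect_error(place_knots(runif(100), rep(-1, 50)), "degenerate")
})

test_that("copy-number correction needs at least three cell lines", {
  fx <- planted_cn_fixture(C = 6)
  expect_error(fit_cn_model(fx$obs[1:2, ], fx$cn[1:2, ]), "three cell lines")
})

test_that("a CN-independent matrix passes through nearly unchanged", {
  fx <- planted_cn_fixture(w_star = rep(0, 24) + 1e-9, noise = 0.05)
  corrected <- correct_copy_number(fx$obs, fx$cn)
  model <- attr(corrected, "cn_model")
  expect_lt(sd(model$fitted), 0.02)
  expect_lt(median(abs(unclass(corrected) - unclass(fx$obs))), 0.02)
  # sparse basis corners may wiggle slightly; never by a material amount
  expect_lt(max(abs(unclass(corrected) - unclass(fx$obs))), 0.25)
})

test_that("planted per-line weights and bias surface are recovered", {
  fx <- planted_cn_fixture(w_star = rep(c(0.5, 1), length.out = 24))
  model <- fit_cn_model(fx$obs, fx$cn)
  expect_lt(max(abs(model$w_c - fx$w_star)), 0.1)
  resid_var <- var(as.numeric(fx$bias - model$fitted))
  expect_lt(resid_var, 0.2 * var(as.numeric(fx$bias)))
  # the planted surface is non-monotone in CN and still captured (R^2)
  expect_gt(1 - resid_var / var(as.numeric(fx$bias)), 0.8)
})

test_that("a single biased line gets w near 1 and the rest stay small", {
  w_star <- c(1, rep(0, 23))
  fx <- planted_cn_fixture(w_star = pmax(w_star, 1e-9))
  model <- fit_cn_model(fx$obs, fx$cn)
  expect_gt(model$w_c[1], 0.9)
  expect_lt(max(model$w_c[-1]), 0.35)
})

test_that("residuals are orthogonal to the weighted spline fit", {
  fx <- planted_cn_fixture(w_star = runif(24, 0.5, 1))
  model <- fit_cn_model(fx$obs, fx$cn)
  resid <- unclass(fx$obs) - model$fitted
  resid_c <- sweep(resid, 2L, colMeans(resid))
  # projection of centered residuals on the fitted surface is ~ 0
  expect_lt(abs(sum(resid_c * model$fitted)) /
              max(sum(model$fitted^2), 1e-12), 0.02)
})

test_that("correction shrinks planted CN correlations for both gene kinds", {
  fx <- planted_cn_fixture(w_star = runif(40, 0.6, 1), C = 40, noise = 0.02,
                           seed = 3)
  corrected <- correct_copy_number(fx$obs, fx$cn)
  per_gene_cor <- function(m, genes) {
    sapply(genes, function(g) abs(cor(m[, g], fx$cn[, g])))
  }
  ess <- names(which(fx$m_true < -0.5))
  neu <- names(which(fx$m_true == 0))
  # planted: strong correlation in both classes; corrected: shrunk
  expect_gt(median(per_gene_cor(unclass(fx$obs), neu)), 0.5)
  expect_gt(median(per_gene_cor(unclass(fx$obs), ess)), 0.3)
  expect_lt(median(per_gene_cor(unclass(corrected), neu)), 0.2)
  expect_lt(median(per_gene_cor(unclass(corrected), ess)), 0.2)
  expect_identical(attr(corrected, "normalization"), "cn_corrected")
})

test_that("correction is idempotent within one percent of variance", {
  fx <- planted_cn_fixture(w_star = runif(24, 0.5, 1), seed = 8)
  once <- correct_copy_number(fx$obs, fx$cn)
  twice <- correct_copy_number(gene_effect_matrix(unclass(once), "raw"),
                               fx$cn)
  rel <- var(as.numeric(unclass(twice) - unclass(once))) /
    var(as.numeric(unclass(once)))
  expect_lt(rel, 0.01)
})

test_that("genes missing from the CN matrix are treated as diploid", {
  fx <- planted_cn_fixture()
  cn_partial <- fx$cn[, 1:100]
  corrected <- correct_copy_number(fx$obs, cn_partial)
  expect_equal(dim(corrected), dim(fx$obs))
  # diploid-imputed genes sit at the surface anchor: zero bias removed
  model <- attr(corrected, "cn_model")
  expect_equal(max(abs(model$fitted[, 101:150])), 0, tolerance = 1e-9)
})
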