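make_ge <- function(C = 6, G = 300, seed = 1) {
  set.seed(seed)
  gene_effect_matrix(
    matrix(rnorm(C * G, -0.2, 0.6), C, G,
           dimnames = list(sprintf("L%d", 1:C), sprintf("g%03d", 1:G))))
}

test_that("global normalization pins the control medians at (0, -1) exactly", {
  ge <- make_ge()
  ctl <- control_sets(colnames(ge)[1:40], colnames(ge)[41:120])
  out <- normalize_global(ge, ctl)
  mm <- function(g) median(apply(out[, g, drop = FALSE], 1, median))
  expect_equal(mm(ctl$nonessential_genes), 0, tolerance = 1e-12)
  expect_equal(mm(ctl$essential_genes), -1, tolerance = 1e-12)
  expect_identical(attr(out, "normalization"), "globally_scaled")

  # a matrix already in normalized form is a fixed point
  again <- normalize_global(out, ctl)
  expect_equal(unclass(again), unclass(out), ignore_attr = TRUE)

  # the affine solve on a shifted fixture: medians (1, 0) -> shift 1, scale 1
  ge2 <- gene_effect_matrix(unclass(out) + 1, "raw")
  out2 <- normalize_global(ge2, ctl)
  expect_equal(unclass(out2), unclass(out), ignore_attr = TRUE)
  expect_equal(attr(out2, "shift"), 1)   # medians were at (1, 0)
  expect_equal(attr(out2, "scale"), 1)

  flat <- gene_effect_matrix(matrix(0.5, 3, 10,
                                    dimnames = list(letters[1:3],
                                                    paste0("g", 1:10))))
  expect_error(normalize_global(flat, control_sets(paste0("g", 1:2),
                                                   paste0("g", 3:4))),
               "undefined")
})

test_that("control lists must be disjoint and present", {
  expect_error(control_sets(c("a", "b"), c("b", "c")), "overlap")
  ge <- make_ge()
  expect_error(normalize_global(ge, control_sets("nope1", "nope2")),
               "control gene")
})

test_that("NNMD matches its definition and the hand-computed fixture", {
  expect_equal(nnmd(c(-3, -3, -3), c(0, 1, -1)), -3)
  x <- rnorm(100)
  expect_equal(nnmd(x, x), 0)
  # translation invariance
  expect_equal(nnmd(x - 5, c(x, 2) - 5), nnmd(x, c(x, 2)))
  expect_error(nnmd(1:3, rep(2, 5)), "MAD")
})

test_that("rank metrics survive affine maps; NNMD reacts to nonlinear ones", {
  ge <- make_ge(seed = 3)
  ess <- colnames(ge)[1:30]
  set.seed(4)
  expr <- matrix(runif(length(ge)), nrow(ge), ncol(ge),
                 dimnames = dimnames(ge))
  expr[, 200:300] <- 0        # unexpressed everywhere
  ctl <- control_sets(ess, colnames(ge)[31:60], expression = expr)

  ge_aff <- gene_effect_matrix(unclass(ge) * 3.7 - 2, "raw")
  fp1 <- unexpressed_false_positive_rate(ge, ctl)
  fp2 <- unexpressed_false_positive_rate(ge_aff, ctl)
  expect_equal(fp1$pooled, fp2$pooled)
  m1 <- essential_recall_metrics(ge, ctl)
  m2 <- essential_recall_metrics(ge_aff, ctl)
  expect_equal(m1$pr_auc, m2$pr_auc)

  n1 <- nnmd(ge[, ess], ge[, 200:300])
  n_aff <- nnmd(ge_aff[, ess], ge_aff[, 200:300])
  expect_equal(n1, n_aff)
  cube <- gene_effect_matrix(sign(unclass(ge)) * abs(unclass(ge))^3, "raw")
  expect_false(isTRUE(all.equal(n1, nnmd(cube[, ess], cube[, 200:300]))))
})

test_that("the unexpressed false-positive rate behaves at its extremes", {
  C <- 4; G <- 200
  scores <- matrix(rnorm(C * G), C, G,
                   dimnames = list(paste0("L", 1:C), paste0("g", 1:G)))
  expr <- matrix(1, C, G, dimnames = dimnames(scores))
  unexp <- paste0("g", 1:20)   # fewer than 15% of genes
  expr[, unexp] <- 0

  # unexpressed genes pushed to the top of the distribution: rate 0
  ge <- scores; ge[, unexp] <- abs(ge[, unexp]) + 5
  out <- unexpressed_false_positive_rate(gene_effect_matrix(ge),
                                         control_sets("x", "y", expr))
  expect_equal(out$pooled, 0)

  # forced most-depleted: rate 1
  ge2 <- scores; ge2[, unexp] <- -abs(ge2[, unexp]) - 5
  out2 <- unexpressed_false_positive_rate(gene_effect_matrix(ge2),
                                          control_sets("x", "y", expr))
  expect_equal(out2$pooled, 1)

  # permutation null: rate matches the depleted fraction within 2 s.e.
  set.seed(9)
  C <- 10; G <- 500
  ge3 <- matrix(rnorm(C * G), C, G,
                dimnames = list(paste0("L", 1:C), paste0("g", 1:G)))
  expr3 <- matrix(ifelse(runif(C * G) < 0.5, 0, 1), C, G,
                  dimnames = dimnames(ge3))
  out3 <- unexpressed_false_positive_rate(gene_effect_matrix(ge3),
                                          control_sets("x", "y", expr3))
  n_unexp <- sum(expr3 == 0)
  se <- sqrt(0.15 * 0.85 / n_unexp)
  expect_lt(abs(out3$pooled - 0.15), 2 * se + 1 / (0.15 * G))

  # a line with no unexpressed genes is NA and excluded from the pool
  expr4 <- expr; expr4["L1", ] <- 1
  out4 <- unexpressed_false_positive_rate(gene_effect_matrix(ge2),
                                          control_sets("x", "y", expr4))
  expect_true(is.na(out4$per_line["L1"]))
  expect_equal(out4$pooled, 1)
})

test_that("precision-recall handles separation, noise, and ties", {
  pr <- pr_curve(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(pr$auc, 1)

  # random scores give AUC near the prevalence of positives
  set.seed(6)
  auc <- mean(replicate(40, {
    pr_curve(runif(200), rep(c(TRUE, FALSE), c(40, 160)))$auc
  }))
  expect_lt(abs(auc - 0.2), 0.05)

  # all-equal scores collapse to one threshold at precision = prevalence
  pr_tie <- pr_curve(rep(1, 10), rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(pr_tie$precision, 0.3)
  expect_equal(pr_tie$recall, 1)
  expect_error(pr_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("per-line essential recall metrics hit their boundary cases", {
  C <- 3; G <- 100
  ge <- matrix(0.1, C, G, dimnames = list(paste0("L", 1:C), paste0("g", 1:G)))
  ess <- paste0("g", 1:20)
  unexp <- paste0("g", 51:100)
  ge[, ess] <- -2                       # perfectly separated
  expr <- matrix(1, C, G, dimnames = dimnames(ge))
  expr[, unexp] <- 0
  ctl <- control_sets(ess, paste0("g", 21:40), expr)
  m <- essential_recall_metrics(gene_effect_matrix(ge), ctl)
  expect_equal(m$pr_auc, rep(1, C))
  expect_equal(m$recall_at_90_precision, rep(1, C))

  # equal scores everywhere: degenerate curve, recall at 90% precision is 0
  ge2 <- ge; ge2[, ] <- 0.5
  m2 <- essential_recall_metrics(gene_effect_matrix(ge2), ctl)
  expect_equal(m2$recall_at_90_precision, rep(0, C))

  # a line with no unexpressed genes yields NA with a warning
  expr3 <- expr; expr3["L1", ] <- 1
  ctl3 <- control_sets(ess, paste0("g", 21:40), expr3)
  expect_warning(m3 <- essential_recall_metrics(gene_effect_matrix(ge), ctl3),
                 "lacks a control class")
  expect_true(is.na(m3$pr_auc[1]))
})
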