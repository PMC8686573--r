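test_that("shifted NB2 cost matches the independent log-pmf oracle", {
  expect_equal(nb2_negative_log_likelihood(100, 100, 0.3), 0)
  expect_equal(nb2_negative_log_likelihood(0, 1e-12, 1), 0, tolerance = 1e-9)

  set.seed(101)
  N <- sample(0:5000, 1000, replace = TRUE)
  mu <- runif(1000, 0.5, 5000)
  alpha <- runif(1000, 0.001, 0.5)
  ours <- nb2_negative_log_likelihood(N, mu, alpha)
  expect_lt(max(abs(ours - nb_shift_oracle(N, mu, alpha))), 1e-8)
  expect_true(all(ours >= 0))

  # alpha -> 0 limit is the Poisson deviance N ln(N/mu) - (N - mu)
  N <- 120; mu <- 80
  dev <- N * log(N / mu) - (N - mu)
  expect_equal(nb2_negative_log_likelihood(N, mu, 1e-8), dev,
               tolerance = 1e-4)
  expect_error(nb2_negative_log_likelihood(10, -1, 0.1), "mu")
})

test_that("initial abundance is the median pDNA share, with centered offsets", {
  sd <- toy_screen()
  nu0 <- initial_abundance(sd)
  rel <- normalize_rpm(sd$counts[1:2, ]) / 1e6
  expect_equal(unname(nu0["b1", ]), unname(apply(rel, 2, median)))

  # a constant per-gene offset is centered away; a balanced one survives
  gene_of <- sd$guide_map$gene
  rho <- matrix(0, 1, 8, dimnames = list("b1", colnames(sd$counts)))
  rho[1, gene_of == "gA"] <- 0.3
  expect_equal(initial_abundance(sd, rho), nu0)
  rho[1, gene_of == "gC"] <- c(0.2, -0.2)
  shifted <- initial_abundance(sd, rho)
  expect_equal(unname(shifted[1, 7:8]), unname(nu0[1, 7:8] * exp(c(0.2, -0.2))))

  # an sgRNA invisible in all pDNA measurements cannot seed the dynamics
  sd$counts[1:2, 3] <- 0
  expect_error(initial_abundance(sd), "pDNA abundance")
})

test_that("predicted abundance solves the two-population mixture exactly", {
  # before the delay, predictions are the normalized initial abundance
  nu <- predicted_abundance(c(0.2, 0.8), days = c(0, 2), r_cg = c(-5, 0),
                            d_g = 3)
  expect_equal(unname(nu[1, ]), c(0.2, 0.8))
  expect_equal(unname(nu[2, ]), c(0.2, 0.8))

  # no fitness effect means no change at any time
  nu <- predicted_abundance(c(0.3, 0.7), days = c(5, 30), r_cg = c(0, 0))
  expect_equal(unname(nu[2, ]), c(0.3, 0.7))

  # closed form: equal start, r = (-1, 0), p = 1, R = 1, no delay
  t <- seq(0, 30, by = 0.25)
  nu <- predicted_abundance(c(0.5, 0.5), t, c(-1, 0), p_c = 1, p_j = 1,
                            R_c = 1, d_g = 0)
  expect_lt(max(abs(nu[, 1] - exp(-t) / (1 + exp(-t)))), 1e-10)
  expect_lt(max(abs(rowSums(nu) - 1)), 1e-10)

  # predictions do not depend on the conditioning constant
  for (ts in c(0.05, 0.2, 1)) {
    alt <- predicted_abundance(c(0.5, 0.5), t, c(-1, 0), p_c = 1, p_j = 1,
                               R_c = 1, d_g = 0, time_scale = ts)
    expect_lt(max(abs(alt - nu)), 1e-8)
  }
  expect_warning(predicted_abundance(c(0.5, 0.5), 30, c(5, 0), d_g = 0),
                 "clipped")
})

test_that("core cost is zero at a perfect fit and depth-invariant", {
  n <- rbind(r1 = c(0.3, 0.7), r2 = c(0.6, 0.4))
  expect_equal(core_cost(n, n, 0.05), 0)

  # term-by-term oracle on a printed fixture
  nu <- rbind(r1 = c(0.4, 0.6), r2 = c(0.5, 0.5))
  oracle <- sum(nb_shift_oracle(c(300000, 700000), c(400000, 600000), 0.05)) +
    sum(nb_shift_oracle(c(600000, 400000), c(500000, 500000), 0.02))
  expect_equal(core_cost(n, nu, c(0.05, 0.02)), oracle, tolerance = 1e-8)

  # NaN entries contribute nothing
  n_na <- n; n_na[1, 2] <- NA
  expect_equal(core_cost(n_na, nu, 0.05),
               core_cost(n, nu, 0.05) -
                 nb2_negative_log_likelihood(7e5, 6e5, 0.05))
})

test_that("core cost falls monotonically toward the observations", {
  set.seed(4)
  n <- matrix(runif(20, 0.01, 1), 2); n <- n / rowSums(n)
  nu <- matrix(runif(20, 0.01, 1), 2); nu <- nu / rowSums(nu)
  costs <- sapply(seq(0, 1, by = 0.1), function(a) {
    core_cost(n, nu + a * (n - nu), 0.05)
  })
  expect_true(all(diff(costs) < 0))
})

test_that("penalties reproduce their defining identities", {
  hp <- screen_hyperparameters()
  expect_equal(penalty_rho(matrix(0, 2, 6), hp), 0)
  expect_equal(penalty_growth_rate(c(1, 1, 1), hp), 0)

  # a 4-guide gene with all efficacies 1 contributes 2 before weighting
  p_j <- rep(1, 4)
  expect_equal(penalty_guide_efficacy(p_j, rep("g1", 4), hp), hp$chi_p * 2)
  # pushing the top two toward 1 lowers the penalty
  expect_lt(penalty_guide_efficacy(c(0.95, 0.95, 0.5, 0.5), rep("g1", 4), hp),
            penalty_guide_efficacy(c(0.90, 0.90, 0.5, 0.5), rep("g1", 4), hp))

  expect_equal(penalty_gene_mean(matrix(c(1, -1, 2, -2), 2), hp), 0)
  expect_gt(penalty_gene_mean(matrix(1, 2, 2), hp), 0)

  # all lines equal per gene: only the Gaussian cross-gene term remains,
  # and the delta (per-gene) term vanishes
  r_flat <- matrix(rep(c(-1, 0, 1), each = 2), 2)
  hp0 <- screen_hyperparameters(chi_k = 1e-12)
  expect_lt(penalty_kernel(r_flat, hp0), 1e-10)
})

test_that("the rank kernel matches a direct truncated-Gaussian computation", {
  hp <- screen_hyperparameters(sigma = 5)
  set.seed(2)
  G <- 40
  r <- matrix(rnorm(3 * G, -0.2, 0.5), 3, G)
  gene_means <- colMeans(r)    # the penalty ranks genes by current means
  K <- kernel_matrix(gene_means, hp)
  rk <- rank(gene_means, ties.method = "first")
  K_direct <- matrix(0, G, G)
  for (g in 1:G) {
    w <- numeric(G)
    for (h in 1:G) {
      d <- abs(rk[g] - rk[h])
      if (d <= 3 * hp$sigma) w[h] <- exp(-d^2 / (2 * hp$sigma^2))
    }
    K_direct[g, ] <- hp$chi_k * w / sum(w)
  }
  diag(K_direct) <- diag(K_direct) + hp$chi_h
  expect_equal(K, K_direct, tolerance = 1e-12)

  # penalty value against a brute-force triple loop
  rbar <- gene_means
  direct <- 0
  for (c in 1:3) for (g in 1:G) for (h in 1:G) {
    direct <- direct + K[g, h] * (r[c, g] - rbar[h])^2
  }
  expect_equal(penalty_kernel(r, hp), direct / (3 * G), tolerance = 1e-10)
})

test_that("total cost is the sum of its parts", {
  set.seed(5)
  n <- matrix(runif(12, 0.01, 1), 2); n <- n / rowSums(n)
  nu <- matrix(runif(12, 0.01, 1), 2); nu <- nu / rowSums(nu)
  hp <- screen_hyperparameters()
  rho <- matrix(rnorm(6, 0, 0.1), 1)
  p_j <- runif(6, 0.5, 1)
  R_c <- c(0.9, 1.1)
  r <- matrix(rnorm(6, -0.3, 0.4), 2)
  gog <- rep(c("g1", "g2", "g3"), each = 2)
  total <- total_cost(n, nu, 0.05, rho, p_j, R_c, r, gog, hp, rescale = 0.4)
  parts <- 0.4 * core_cost(n, nu, 0.05) + penalty_rho(rho, hp) +
    penalty_guide_efficacy(p_j, gog, hp) + penalty_growth_rate(R_c, hp) +
    penalty_gene_mean(r, hp) + penalty_kernel(r, hp)
  expect_equal(total, parts)
})

test_that("analytic gradients match finite differences on a small problem", {
  sim <- simulate_screen(screen_scenario(n_lines = 2, n_genes = 4,
                                         guides_per_gene = 2, depth = 300,
                                         seed = 11))
  sd <- sim$screen
  dims <- screenpop:::screen_dims(sd)
  hp <- screen_hyperparameters()
  m <- initial_abundance(sd)[dims$batches, dims$guides, drop = FALSE]
  n <- normalize_rpm(sd$counts[dims$rep_rows, , drop = FALSE]) / 1e6
  W <- 1 * !is.na(n); n[is.na(n)] <- 0; Nmat <- 1e6 * n
  p_c <- c(0.8, 0.9); names(p_c) <- dims$lines
  al <- screenpop:::expand_alpha(hp$alpha, dims$lines)
  set.seed(42)
  par <- initialize_parameters(sd, hp, seed = 5)
  par$rho <- matrix(rnorm(length(par$rho), 0, 0.1), nrow(par$rho))
  par$p_j <- runif(dims$J, 0.4, 0.99)
  par$R_c <- c(0.9, 1.1)
  par$gene_mean <- rnorm(dims$G, -0.3, 0.5)
  par$delta <- matrix(rnorm(dims$C * dims$G, 0, 0.3), dims$C)
  arow <- al[dims$cidx]
  lamN <- (Nmat + 1 / arow) * log1p(arow * Nmat) -
    ifelse(Nmat > 0, Nmat * log(Nmat), 0)
  lamN_sum <- sum(W * lamN)
  f <- function(p) screenpop:::sp_cost_grad(p, dims, m, n, Nmat, W, p_c, al,
                                            hp, 0.37, lamN_sum,
                                            want_grad = FALSE)$total
  ev <- screenpop:::sp_cost_grad(par, dims, m, n, Nmat, W, p_c, al, hp, 0.37,
                                 lamN_sum)
  h <- 1e-6
  for (nm in names(ev$grad)) {
    g_num <- par[[nm]] * 0
    for (i in seq_along(par[[nm]])) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + h; up <- f(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h; down <- f(p2)
      g_num[i] <- (up - down) / (2 * h)
    }
    expect_lt(max(abs(ev$grad[[nm]] - g_num) / (abs(g_num) + 1e-6)), 1e-3)
  }
})

test_that("cell efficacy inverts the depleted-tail fold change", {
  sm <- data.frame(sequence_ID = c("r1", "r2"), cell_line = "L",
                   days = c(14, 14))
  # complete dropout of the depleted tail implies full efficacy
  lfc <- matrix(rep(c(-30, 0), c(5, 195)), 2, 200, byrow = TRUE,
                dimnames = list(c("r1", "r2"), NULL))
  expect_gte(unname(estimate_cell_efficacy(lfc, sm)["L"]), 0.999)
  # no depletion anywhere floors the estimate
  lfc0 <- matrix(abs(rnorm(400, 0.2, 0.05)), 2, 200,
                 dimnames = list(c("r1", "r2"), NULL))
  expect_equal(unname(estimate_cell_efficacy(lfc0, sm)["L"]), 0.01)
  expect_warning(estimate_cell_efficacy(lfc0[, 1:50], sm), "100 sgRNAs")
})

test_that("cell efficacy is recovered within 0.1 on simulated screens", {
  # a 21-day readout saturates the strong essentials the estimator relies on
  sc <- screen_scenario(n_lines = 3, n_genes = 150, p_c = c(0.6, 0.8, 1.0),
                        time_points = c(7, 21), seed = 13)
  sim <- simulate_screen(sc)
  lfc <- compute_lfc(sim$screen)
  est <- estimate_cell_efficacy(lfc, sim$screen$sequence_map)
  expect_lt(max(abs(est[names(sim$truth$p_c)] - sim$truth$p_c)), 0.1)
})
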