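test_that("binned ACF is 1 for a perfectly linear bin series and 0 for degenerate ones", {
  # one CpG per 100-bp bin, linearly increasing signal
  cpgs <- make_cpgs(c(50, 150, 250, 350, 450), meth_diff = 1:5)
  acf <- estimate_acf(cpgs, bin_size = 100, max_lag = 2, source = "meth_diff")
  expect_equal(acf$rho[1], 1)       # lag 0 by definition
  expect_equal(acf$rho[2], 1, tolerance = 1e-12)

  const <- make_cpgs(c(50, 150, 250, 350), meth_diff = 7)
  expect_warning(
    acf0 <- estimate_acf(const, bin_size = 100, max_lag = 2,
                         source = "meth_diff"),
    "undefined"
  )
  expect_equal(acf0$rho[2:3], c(0, 0))
  expect_error(estimate_acf(make_cpgs(1)[0, ]), "no CpGs")
})

test_that("ACF of independent bin values is near zero", {
  set.seed(21)
  n <- 10000
  cpgs <- make_cpgs(seq(50, by = 100, length.out = n), pvalue = runif(n))
  acf <- estimate_acf(cpgs, bin_size = 100, max_lag = 5)
  expect_true(all(abs(acf$rho[-1]) < 0.05))
})

test_that("region correlation matrix maps pair distances to binned lags", {
  acf <- structure(list(bin_size = 100L, max_lag = 10L,
                        rho = c(1, 0.4, 0.2, rep(0.05, 8)),
                        n_pairs = rep(100L, 11), source = "pvalue"),
                   class = "acf_estimate")
  expect_equal(region_correlation_matrix(500, acf), matrix(1, 1, 1))
  m <- region_correlation_matrix(c(100, 150), acf)   # 50 bp -> lag 1
  expect_equal(m[1, 2], 0.4)
  expect_equal(diag(m), c(1, 1))
  far <- region_correlation_matrix(c(100, 5100), acf)  # beyond max lag
  expect_equal(far[1, 2], 0)
  # PSD repair: matrix stays symmetric with non-negative spectrum
  acf_neg <- acf
  acf_neg$rho <- c(1, -0.9, 0.8, rep(0, 8))
  mm <- region_correlation_matrix(c(100, 200, 300), acf_neg)
  expect_true(isSymmetric(mm))
  expect_gte(min(eigen(mm, symmetric = TRUE)$values), -1e-10)
})

test_that("Stouffer-Liptak reproduces algebraic special cases", {
  # single p-value: identity
  expect_equal(stouffer_liptak(0.03, matrix(1)), 0.03, tolerance = 1e-12)
  # two independent p = 0.05
  expect_equal(stouffer_liptak(c(0.05, 0.05), diag(2)),
               pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(stouffer_liptak(c(0.05, 0.05), diag(2)) - 0.0100), 1e-4)
  # full dependence: no gain over a single test
  expect_equal(stouffer_liptak(rep(0.05, 3), matrix(1, 3, 3)), 0.05,
               tolerance = 1e-12)
})

test_that("Stouffer-Liptak is invariant under simultaneous permutation and rejects bad input", {
  set.seed(5)
  k <- 6
  p <- runif(k)
  a <- matrix(runif(k * k, -0.1, 0.3), k, k)
  corr <- (a + t(a)) / 2; diag(corr) <- 1
  perm <- sample.int(k)
  expect_equal(stouffer_liptak(p, corr),
               stouffer_liptak(p[perm], corr[perm, perm]), tolerance = 1e-12)
  expect_error(stouffer_liptak(c(0.1, 0.2), matrix(1)), "matrix")
  asym <- diag(2); asym[1, 2] <- 0.5
  expect_error(stouffer_liptak(c(0.1, 0.2), asym), "symmetric")
  expect_error(stouffer_liptak(c(0.1, 0.2),
                               matrix(c(1, -1.5, -1.5, 1), 2)), "degenerate")
  expect_error(stouffer_liptak(c(0.1, 1.2), diag(2)), "\\[0, 1\\]")
})

test_that("BH q-values match the literal step-up definition", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("the dependence adjustment restores null calibration that identity combination loses", {
  # 2000 regions of 8 CpGs, one CpG per 100-bp bin, latent AR(1) z shared
  # through the bins: member p-values are positively correlated
  set.seed(31)
  rho <- 0.6
  n_reg <- 2000L
  k <- 8L
  bins_per_block <- 108L   # 8 occupied bins + 100-bin gap between regions
  nb <- n_reg * bins_per_block
  b <- as.numeric(stats::filter(rnorm(nb, sd = sqrt(1 - rho^2)), rho,
                                method = "recursive", init = rnorm(1)))
  block0 <- rep(seq_len(n_reg) - 1L, each = k)
  offset <- rep(seq_len(k) - 1L, n_reg)
  bin_idx <- block0 * bins_per_block + offset
  pos <- bin_idx * 100L + 50L
  z <- b[bin_idx + 1L]
  cpgs <- make_cpgs(pos, pvalue = pnorm(z, lower.tail = FALSE))
  # regions are 8 bins wide, so lags beyond 7 have no pairs (rho = 0, warns)
  acf <- suppressWarnings(estimate_acf(cpgs, bin_size = 100, max_lag = 10))
  expect_equal(acf$rho[2], rho, tolerance = 0.1)

  reg <- segment_regions(cpgs, 700)
  expect_equal(nrow(reg), n_reg)
  p_adj <- p_id <- numeric(n_reg)
  for (i in seq_len(n_reg)) {
    rows <- reg$first_row[i]:reg$last_row[i]
    sigma <- region_correlation_matrix(cpgs$pos[rows], acf)
    p_adj[i] <- stouffer_liptak(cpgs$pvalue[rows], sigma)
    p_id[i] <- stouffer_liptak(cpgs$pvalue[rows])
  }
  expect_gt(mean(p_id < 0.05), 0.07)           # ignoring correlation inflates
  expect_gte(mean(p_adj < 0.05), 0.03)         # adjustment restores level
  expect_lte(mean(p_adj < 0.05), 0.07)
})

test_that("region p-value combination honours the member-selection mode", {
  cpgs <- make_cpgs(c(100, 150, 200), meth_diff = c(40, 40, 5),
                    pvalue = c(0.001, 0.002, 0.9),
                    qvalue = c(0.001, 0.002, 0.9))
  acf <- suppressWarnings(estimate_acf(cpgs, bin_size = 100, max_lag = 3))
  reg <- count_dmcs(segment_regions(cpgs, 100), cpgs)
  all_mode <- combine_region_pvalues(reg, cpgs, acf, combine = "all")
  dmc_mode <- combine_region_pvalues(reg, cpgs, acf, combine = "dmc-only")
  expect_true(all_mode$p_combined != dmc_mode$p_combined)
  # dmc-only drops the null member, so the combination is stronger
  expect_lt(dmc_mode$p_combined, all_mode$p_combined)
  expect_true(all(all_mode$q_value >= 0 & all_mode$q_value <= 1))
})
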