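test_that("exact p-values match exhaustive enumeration (Poisson limit)", {
  worst <- 0
  for (y_a in 0:15) for (y_b in 0:15) {
    p <- atcmarkers:::nb_exact_pvalue(y_a, y_b, 2, 2, 0)
    worst <- max(worst, abs(p - oracle_binom_p(y_a, y_b, 2, 2)))
  }
  for (y_a in 0:12) for (y_b in 0:12) {
    p <- atcmarkers:::nb_exact_pvalue(y_a, y_b, 3, 5, 0)
    worst <- max(worst, abs(p - oracle_binom_p(y_a, y_b, 3, 5)))
  }
  expect_lt(worst, 1e-10)
})

test_that("exact p-values match enumeration under overdispersion", {
  worst <- 0
  for (y_a in 0:10) for (y_b in 0:10) {
    p <- atcmarkers:::nb_exact_pvalue(y_a, y_b, 4, 3, 0.3)
    worst <- max(worst, abs(p - oracle_nb_p(y_a, y_b, 4, 3, 0.3)))
  }
  expect_lt(worst, 1e-10)
})

test_that("exact-test conventions: no evidence and windowed large totals", {
  # both groups all-zero -> p = 1
  expect_equal(atcmarkers:::nb_exact_pvalue(0, 0, 5, 5, 0.1), 1)
  # windowed computation (large totals) agrees with the full enumeration
  p_win <- atcmarkers:::nb_exact_pvalue(30000, 31000, 5, 5, 0.01)
  t_tot <- 61000
  lw <- stats::dnbinom(0:t_tot, size = 5 / 0.01, mu = t_tot / 2, log = TRUE) +
    stats::dnbinom(t_tot:0, size = 5 / 0.01, mu = t_tot / 2, log = TRUE)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  p_full <- min(1, sum(w[w <= w[30001] * (1 + 1e-8)]))
  expect_equal(p_win, p_full, tolerance = 1e-10)
})

test_that("type-I error is near nominal under the null", {
  set.seed(12)
  mu <- exp(stats::rnorm(10000, 3, 1))
  cnt <- sapply(1:8, function(s) stats::rnbinom(10000, mu = mu, size = 1 / 0.1))
  dimnames(cnt) <- list(sprintf("g%05d", 1:10000), sprintf("s%d", 1:8))
  grp <- factor(rep(c("A", "B"), each = 4))
  de <- nb_exact_test(cnt, grp, 0.1, tmm_norm_factors(cnt))
  rate <- mean(de$p_value < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("dispersion estimation recovers the truth and flags degeneracy", {
  set.seed(11)
  grp <- factor(rep(c("A", "B"), c(10, 18)))
  mu <- exp(stats::rnorm(2000, 4, 1.2))
  cnt <- sapply(seq_len(28), function(s) stats::rnbinom(2000, mu = mu, size = 5))
  dimnames(cnt) <- list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:28))
  est <- estimate_common_dispersion(cnt, grp)
  expect_lt(abs(est$phi / 0.2 - 1), 0.2)

  # Poisson data pins the estimate to (near) zero
  cntp <- sapply(seq_len(28), function(s) stats::rpois(2000, mu))
  dimnames(cntp) <- dimnames(cnt)
  expect_lt(estimate_common_dispersion(cntp, grp)$phi, 0.005)

  # constant counts within groups: no overdispersion evidence
  cntc <- matrix(rep(c(5L, 9L), c(10, 18)), nrow = 30, ncol = 28, byrow = TRUE)
  dimnames(cntc) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:28))
  expect_lt(estimate_common_dispersion(cntc, grp)$phi, 0.005)

  expect_error(estimate_common_dispersion(cnt[, 1, drop = FALSE], grp[1]),
               "single sample")
})

test_that("exact-test interface validates inputs and reports fold changes", {
  m <- toy_counts(n_genes = 20, n_samples = 6, seed = 2)
  grp <- factor(rep(c("A", "B"), each = 3))
  expect_error(nb_exact_test(m, factor(rep("A", 6)), 0.1), "two levels")
  expect_error(nb_exact_test(m, grp, -0.1), "non-negative")
  de <- nb_exact_test(m, grp, 0.1)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_true(all(is.finite(de$log2_fc)))
  expect_identical(attr(de, "comparison"), "B vs A")
})

test_that("BH adjustment matches step-up arithmetic and is order-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- stats::runif(100)
  perm <- sample(100)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
})

test_that("PCA embedding separates simulated classes and orders variance", {
  sim <- default_sim()
  scr <- default_screen()
  fpm <- compute_fpm(sim$counts, scr$factors)
  emb <- pca_embed(fpm, n_components = 3)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_lte(sum(emb$explained_variance), 1 + 1e-12)
  atc <- sim$samples$class == "ATC"
  # ATC carries 20 strongly induced genes: PC1 separates it from the rest
  d_between <- abs(mean(emb$coords[atc, 1]) - mean(emb$coords[!atc, 1]))
  d_within <- max(stats::sd(emb$coords[atc, 1]), stats::sd(emb$coords[!atc, 1]))
  expect_gt(d_between, d_within)
  # identical samples coincide
  m <- cbind(a = c(10, 5, 1), b = c(10, 5, 1), c = c(1, 5, 10))
  e2 <- pca_embed(m, 2, pseudocount = 1)
  expect_equal(e2$coords["a", ], e2$coords["b", ])
  expect_error(pca_embed(m, 5), "n_components")
})
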