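test_that("simulation is deterministic and respects the configuration", {
  cfg <- sim_config(n_genes = 200, n_spiked_markers = 5, n_decoy_markers = 4,
                    seed = 1)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)

  expect_identical(dim(a$counts), c(209L, 28L))
  expect_true(all(a$counts >= 0))
  expect_identical(storage.mode(a$counts), "integer")
  expect_identical(a$samples$class,
                   rep(c("ATC", "PTC", "FTC", "NT"), c(10, 6, 6, 6)))
  expect_identical(sort(unique(a$truth$role)),
                   c("background", "decoy_expressed", "decoy_high_rsd",
                     "spiked_marker"))
  expect_identical(sum(a$truth$role == "spiked_marker"), 5L)
  expect_false(anyDuplicated(a$truth$gene_id) > 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_samples_per_class = c(ATC = 0L)), "positive")
  expect_error(sim_config(n_samples_per_class = c(XYZ = 5L)), "class labels")
  expect_error(sim_config(spike_fold_change = 40), "exceed 50")
  expect_error(sim_config(spike_noatc_mean_fpm = 1.5), "below 1")
  expect_error(sim_config(spike_rsd_target = 0.7), "0, 0.5")
  expect_error(sim_config(libsize_range = c(2, 1)), "increasing")
})

test_that("spiked markers satisfy the screen thresholds empirically", {
  # construction-fidelity check on a second generator seed
  sim <- simulate_counts(sim_config(seed = 7))
  fpm <- compute_fpm(sim$counts)
  noatc <- sim$samples$sample_id[sim$samples$class != "ATC"]
  atc <- sim$samples$sample_id[sim$samples$class == "ATC"]
  spiked <- sim$truth$gene_id[sim$truth$role == "spiked_marker"]
  m_no <- rowMeans(fpm[spiked, noatc])
  m_atc <- rowMeans(fpm[spiked, atc])
  expect_true(all(m_no < 1))
  expect_true(all(m_atc > 50 * pmax(m_no, 0.05)))
})

test_that("per-class empirical means converge to configured means", {
  cfg <- sim_config(n_genes = 50, baseline_logmean_sigma = 0.5,
                    n_samples_per_class = c(ATC = 400L),
                    libsize_range = c(1, 1),
                    n_spiked_markers = 0L, n_decoy_markers = 0L, seed = 3)
  sim <- simulate_counts(cfg)
  # truth table stores expected FPM; with 400 samples and unit size factors
  # the empirical mean FPM must sit close to it (biological CV ~ sqrt(phi))
  fpm <- sweep(sim$counts, 2, colSums(sim$counts), "/") * 1e6
  emp <- rowMeans(fpm)
  truth <- sim$truth$true_noatc_mean_fpm
  hi <- truth > 50
  expect_gt(sum(hi), 10)
  expect_true(all(abs(emp[hi] / truth[hi] - 1) < 0.15))
})

test_that("a global-null simulation yields an FDR-level significant fraction", {
  cfg <- sim_config(n_genes = 3000, n_spiked_markers = 0L,
                    n_decoy_markers = 0L, seed = 5)
  sim <- simulate_counts(cfg)
  grp <- factor(ifelse(sim$samples$class == "ATC", "ATC", "noATC"),
                levels = c("noATC", "ATC"))
  f <- tmm_norm_factors(sim$counts)
  disp <- estimate_common_dispersion(sim$counts, grp, f)
  de <- nb_exact_test(sim$counts, grp, disp, f)
  expect_lt(mean(de$fdr <= 0.05), 0.01)
  expect_lt(mean(de$p_value < 0.05), 0.08)
})

test_that("IHC cohort simulation is deterministic, valid, and calibrated", {
  pr <- data.frame(tumor_class = c("ATC", "PTC"), marker = "IGF2BP1",
                   rate = c(0.75, 0))
  cfg <- ihc_cohort_config(n_per_class = c(ATC = 4000L, PTC = 50L),
                           positivity_rate = pr, seed = 2)
  rec <- simulate_ihc_cohort(cfg)
  expect_identical(rec, simulate_ihc_cohort(cfg))
  pct <- as.matrix(rec[, paste0("pct_intensity_", 0:3)])
  expect_true(all(abs(rowSums(pct) - 100) < 1e-9))
  h <- histoscore(pct)
  # class with rate 0 is all-negative
  expect_true(all(h[rec$tumor_class == "PTC"] == 0))
  # empirical positivity within 3 binomial SEs of the configured rate
  emp <- mean(call_positive(h[rec$tumor_class == "ATC"]))
  expect_lt(abs(emp - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
})

test_that("IHC configs with invalid rates are rejected", {
  bad <- data.frame(tumor_class = "ATC", marker = "X", rate = 1.2)
  expect_error(ihc_cohort_config(positivity_rate = bad), "\\[0, 1\\]")
})

test_that("gene-set generation is seeded and size-checked", {
  genes <- sprintf("g%03d", 1:100)
  s1 <- make_gene_sets(genes, n_sets = 5, set_size_range = c(5, 20), seed = 9)
  s2 <- make_gene_sets(genes, n_sets = 5, set_size_range = c(5, 20), seed = 9)
  expect_identical(s1, s2)
  expect_error(make_gene_sets(genes, set_size_range = c(50, 200)),
               "exceed")
  # GMT round trip, byte-identical under a fixed seed
  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  write_gmt(s1, f1); write_gmt(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gmt(f1)
  expect_identical(lapply(back, sort), lapply(s1, sort))
})
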