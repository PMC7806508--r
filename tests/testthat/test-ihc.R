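test_that("Histoscore arithmetic and validation", {
  expect_equal(histoscore(c(0, 0, 0, 100)), 300)
  expect_equal(histoscore(c(100, 0, 0, 0)), 0)
  expect_equal(histoscore(c(40, 10, 20, 30)), 140)
  m <- rbind(c(50, 50, 0, 0), c(0, 0, 50, 50))
  expect_equal(histoscore(m), c(50, 250))
  expect_error(histoscore(c(40, 10, 20, 20)), "sum to 100")
  expect_error(histoscore(c(-10, 60, 30, 20)), "non-negative")
})

test_that("Histoscore classes use the printed bin boundaries", {
  expect_identical(as.character(classify_histoscore(c(0, 1, 100, 101, 200, 201, 300))),
                   c("absent", "low", "low", "intermediate", "intermediate",
                     "strong", "strong"))
  expect_error(classify_histoscore(301), "\\[0, 300\\]")
})

test_that("positivity rule is any detectable staining, but configurable", {
  expect_false(call_positive(0))
  expect_true(call_positive(15))
  expect_false(call_positive(15, threshold = 101))
})

test_that("pooled contingency tables reproduce the cohort count arithmetic", {
  counts <- thyroid_cohort_counts()
  igf <- build_contingency(counts, "IGF2BP1")
  expect_identical(c(igf$tp, igf$fn, igf$fp, igf$tn), c(27L, 9L, 1L, 204L))
  mage <- build_contingency(counts, "MAGEA3")
  expect_identical(c(mage$tp, mage$fn, mage$fp, mage$tn), c(18L, 18L, 0L, 205L))
  myc <- build_contingency(counts, "MYC")
  expect_identical(c(myc$tp, myc$fn, myc$fp, myc$tn), c(26L, 10L, 16L, 189L))
  expect_error(build_contingency(counts, "NOPE"), "not present")
})

test_that("contingency building from records matches the positivity rule", {
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:4), cohort = "x",
    tumor_class = c("ATC", "ATC", "PTC", "NT"), marker = "M",
    pct_intensity_0 = c(0, 100, 90, 0),
    pct_intensity_1 = c(50, 0, 10, 0),
    pct_intensity_2 = c(50, 0, 0, 0),
    pct_intensity_3 = c(0, 0, 0, 100))
  tab <- build_contingency(rec, "M")  # NT excluded by default
  expect_identical(c(tab$tp, tab$fn, tab$fp, tab$tn), c(1L, 1L, 1L, 0L))
  tab2 <- build_contingency(rec, "M", threshold = 101)
  expect_identical(c(tab2$tp, tab2$fn, tab2$fp, tab2$tn), c(1L, 1L, 0L, 1L))
})

test_that("DOR point estimates and CIs follow the log method with Haldane", {
  d <- dor_with_ci(list(tp = 27, fn = 9, fp = 1, tn = 204))
  expect_equal(d$dor, 612)
  expect_equal(d$ci_lower, 74.6, tolerance = 0.005)
  expect_equal(d$ci_upper, 5021, tolerance = 0.005)
  expect_false(d$correction_applied)

  d2 <- dor_with_ci(list(tp = 18, fn = 18, fp = 0, tn = 205))
  expect_true(d2$correction_applied)
  expect_equal(d2$dor, 411)
  expect_equal(d2$ci_lower, 23.8, tolerance = 0.005)

  expect_equal(dor_with_ci(list(tp = 10, fn = 10, fp = 10, tn = 10))$dor, 1)
  # invariance under positive scaling when no correction triggers
  a <- dor_with_ci(list(tp = 6, fn = 3, fp = 2, tn = 9))$dor
  b <- dor_with_ci(list(tp = 60, fn = 30, fp = 20, tn = 90))$dor
  expect_equal(a, b)
  # correction triggers iff a cell is zero
  expect_true(dor_with_ci(list(tp = 5, fn = 0, fp = 2, tn = 9))$correction_applied)
  expect_false(dor_with_ci(list(tp = 5, fn = 1, fp = 2, tn = 9))$correction_applied)
})

test_that("DOR equals the sensitivity/specificity odds identity", {
  tab <- list(tp = 26, fn = 10, fp = 16, tn = 189)
  ss <- sens_spec_with_ci(tab)
  se <- ss$sensitivity$estimate; sp <- ss$specificity$estimate
  expect_equal(dor_with_ci(tab)$dor, (se / (1 - se)) / ((1 - sp) / sp))
})

test_that("sensitivity and specificity with Wilson intervals", {
  tab <- list(tp = 27, fn = 9, fp = 1, tn = 204)
  ss <- sens_spec_with_ci(tab)
  expect_equal(ss$sensitivity$estimate, 0.75)
  expect_equal(ss$specificity$estimate, 204 / 205)
  expect_true(ss$sensitivity$ci_lower <= 0.75 &
              0.75 <= ss$sensitivity$ci_upper)
  perfect <- sens_spec_with_ci(list(tp = 5, fn = 0, fp = 0, tn = 7))
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$specificity$estimate, 1)
})

test_that("predictive values at sample prevalence equal column proportions", {
  tab <- list(tp = 26, fn = 10, fp = 16, tn = 189)
  pn <- ppv_npv_with_ci(tab)
  expect_equal(pn$ppv$estimate, 26 / 42)
  expect_equal(pn$npv$estimate, 189 / 199)
  expect_equal(pn$prevalence, 36 / 241)
  expect_equal(pn$ppv$ci_lower, 0.493, tolerance = 0.002)
  expect_equal(pn$ppv$ci_upper, 0.731, tolerance = 0.002)
  # CI brackets the point estimate for every metric
  expect_true(pn$ppv$ci_lower <= pn$ppv$estimate &
              pn$ppv$estimate <= pn$ppv$ci_upper)
  expect_true(pn$npv$ci_lower <= pn$npv$estimate &
              pn$npv$estimate <= pn$npv$ci_upper)
  perfect <- ppv_npv_with_ci(list(tp = 5, fn = 0, fp = 0, tn = 7))
  expect_equal(perfect$ppv$estimate, 1)
  expect_equal(perfect$npv$estimate, 1)
  expect_true(perfect$correction_applied)
  # boundary tables keep the bracket property: interval contains the point
  bnd <- ppv_npv_with_ci(list(tp = 18, fn = 18, fp = 0, tn = 205))
  expect_true(bnd$ppv$ci_lower <= bnd$ppv$estimate &
              bnd$ppv$estimate <= bnd$ppv$ci_upper)
})

test_that("the diagnostic report orders the three markers as published", {
  rep <- diagnostic_report(thyroid_cohort_counts(),
                           markers = c("IGF2BP1", "MAGEA3", "MYC"))
  expect_identical(rep$marker[order(-rep$dor)], c("IGF2BP1", "MAGEA3", "MYC"))
  expect_equal(rep$dor, c(612, 411, 30.7125))
  expect_identical(rep$haldane_corrected, c(FALSE, TRUE, FALSE))
  expect_identical(nrow(diagnostic_report(thyroid_cohort_counts(),
                                          markers = character(0))), 0L)
})

test_that("simulated cohorts at published rates approximate published metrics", {
  # positivity rates follow the pooled cohort frequencies; with cohort sizes
  # scaled 20x, sampling error on DOR shrinks enough to compare magnitudes
  counts <- thyroid_cohort_counts()
  igf <- counts[counts$marker == "IGF2BP1" & counts$tumor_class != "NT", ]
  agg <- stats::aggregate(cbind(n_total, n_positive) ~ tumor_class, igf, sum)
  pr <- data.frame(tumor_class = agg$tumor_class, marker = "IGF2BP1",
                   rate = agg$n_positive / agg$n_total)
  cfg <- ihc_cohort_config(
    n_per_class = stats::setNames(agg$n_total * 20L, agg$tumor_class),
    positivity_rate = pr, seed = 31)
  rec <- simulate_ihc_cohort(cfg)
  rep <- diagnostic_report(rec, markers = "IGF2BP1")
  expect_equal(rep$sensitivity, 0.75, tolerance = 0.1)
  expect_equal(rep$specificity, 204 / 205, tolerance = 0.02)
  expect_gt(rep$dor, 100)
})
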