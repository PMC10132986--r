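test_that("context classification follows the motif and precedence rules", {
  muts <- data.frame(
    context = c("ACG", "TCA", "TCG", "ACA", "CpG>T", "APOBEC", "nonsense"),
    ref = c("C", "C", "C", "C", NA, NA, NA),
    alt = c("T", "G", "T", "A", NA, NA, NA))
  expect_equal(classify_context(muts),
               c("CpG>T", "APOBEC", "CpG>T", "other", "CpG>T", "APOBEC", "other"))
  # APOBEC requires the TpCpW motif and C>T/C>G
  m2 <- data.frame(context = c("TCC", "TCT", "GCA"), ref = "C",
                   alt = c("G", "T", "T"))
  expect_equal(classify_context(m2), c("other", "APOBEC", "other"))
})

test_that("clock burden counts are exposure-corrected", {
  ann <- data.frame(clonal = TRUE, context = "CpG>T", ref = "C", alt = "T",
                    map_multiplicity = 1L, total_cn = 2L)[rep(1, 12), ]
  expect_equal(count_clock_mutations(ann, 30), 0.4)
  # no CpG>T mutations
  ann2 <- transform(ann, context = "ACA", alt = "A")
  expect_equal(count_clock_mutations(ann2, 30), 0)
  # same counts at multiplicity 2 on a doubled genome: burden unchanged
  ann3 <- transform(ann, map_multiplicity = 2L, total_cn = 4L)
  expect_equal(count_clock_mutations(ann3, 30), 0.4)
  expect_error(count_clock_mutations(ann, 0), "covered_cpg_mb")
})

test_that("the aging-rate fit is exact on noiseless data and robust to outliers", {
  ages <- seq(40, 80, length.out = 50)
  fit <- fit_aging_rate(0.37 * ages, ages)
  expect_equal(fit$rate, 0.37, tolerance = 1e-12)
  expect_equal(sum(fit$retained), 46)   # 5% trimmed from each tail (floor(2.5) = 2)

  set.seed(19)
  cc <- simulate_clock_cohort(400, rate = 0.37, hypermutated_fraction = 0.05)
  trimmed <- fit_aging_rate(cc$burden, cc$age)$rate
  untrimmed <- sum(cc$age * cc$burden) / sum(cc$age^2)
  expect_equal(trimmed, 0.37, tolerance = 0.05 / 0.37)
  expect_gt(untrimmed, trimmed + 0.05)
  expect_warning(fit_aging_rate(0.37 * ages[1:5], ages[1:5]), "20")
})

test_that("years before diagnosis transform is exact, monotone and truncated", {
  expect_equal(pi_to_years(1, burden = 20, rate = 0.4, age = 70), 0)
  expect_equal(pi_to_years(0.5, burden = 20, rate = 0.4, age = 70), 25)
  expect_equal(pi_to_years(0, burden = 20, rate = 0.4, age = 40), 40)  # age cap
  pis <- seq(0, 1, by = 0.05)
  yrs <- pi_to_years(pis, 20, 0.4, 80)
  expect_true(all(diff(yrs) <= 0))
  d <- time_segment_gain(5, 15, 1, 1, 3)
  ydist <- pi_to_years(d, 20, 0.4, 60)
  expect_true(all(ydist$years >= 0 & ydist$years <= 60))
  expect_equal(sum(ydist$prob), 1, tolerance = 1e-9)
  expect_error(pi_to_years(d, 0, 0.4, 60), "burden")
  expect_error(pi_to_years(d, 20, 0, 60), "rate")
})

test_that("conversion model behaves at parameter limits", {
  set.seed(29)
  # lambda = 0 truth: almost no conversions, fitted rate near 0
  ev0 <- simulate_conversion_events(200, conversion_rate = 0, immune_fraction = 0.35)
  expect_true(all(ev0$class == "WGD"))
  f0 <- suppressWarnings(fit_wgd_wgt_conversion(ev0$tau, ev0$class))
  expect_lt(f0$lambda * (1 - f0$f), 0.01)
  # f = 0, fast conversion, all events old: essentially all WGT, f-hat near 0
  ev1 <- simulate_conversion_events(200, conversion_rate = 1, immune_fraction = 0,
                                    origin_window = c(30, 40))
  fit1 <- suppressWarnings(fit_wgd_wgt_conversion(ev1$tau, ev1$class))
  expect_gt(mean(ev1$class == "WGT"), 0.95)
  expect_lt(fit1$f, 0.05)
})

test_that("P(WGT | tau) is increasing in tau and bounded by 1 - f", {
  lambda <- 0.11; f <- 0.35
  tau <- seq(0, 60, by = 1)
  p <- (1 - f) * (1 - exp(-lambda * tau))
  expect_true(all(diff(p) > 0))
  expect_true(all(p <= 1 - f))
})

test_that("conversion parameters are recovered inside profile CIs", {
  set.seed(37)
  hits <- replicate(20, {
    ev <- simulate_conversion_events(103)
    fit <- fit_wgd_wgt_conversion(ev$tau, ev$class)
    c(fit$lambda_ci[1] <= 0.11 && 0.11 <= fit$lambda_ci[2],
      fit$f_ci[1] <= 0.35 && 0.35 <= fit$f_ci[2])
  })
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})
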