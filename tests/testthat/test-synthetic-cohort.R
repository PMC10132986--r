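test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_tumors = 0), "n_tumors")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
  expect_error(sim_config(purity_range = c(0, 0.9)), "purity_range")
  bad_menu <- default_event_menu()
  bad_menu$prevalence[1] <- 1.5
  expect_error(sim_config(event_menu = bad_menu), "event_menu")
  expect_error(sim_config(wgd_params = list(origin_window = c(5, 35),
                                            conversion_rate = -1,
                                            immune_fraction = 0.3)),
               "wgd_params")
})

test_that("the same seed reproduces a byte-identical cohort bundle", {
  cfg <- sim_config(n_tumors = 3, seed = 99)
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1)
  expect_length(grep("mutations", files), 3)
  expect_length(grep("segments", files), 3)
  expect_true("metadata.tsv" %in% files)
  expect_true("truth.json" %in% files)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pure diploid clonal mutations have expected VAF one half", {
  menu <- default_event_menu()[0, ]   # no copy events at all
  cfg <- sim_config(n_tumors = 1, seed = 3, purity_range = c(1, 1),
                    event_menu = menu, coverage_mean = 200)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$T0001$mutations$expected_vaf == 0.5))
  # observed mean VAF within 3 standard errors of 0.5
  v <- coh$mutations$alt_count / (coh$mutations$alt_count + coh$mutations$ref_count)
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.5), 3 * se)
})

test_that("whole-genome doubling stratifies multiplicity by event time", {
  menu <- data.frame(name = "wgd", class = "wgd", locus = "genome",
                     prevalence = 1, t_lo = 0.5, t_hi = 0.5,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(n_tumors = 1, seed = 17, event_menu = menu,
                    wgd_params = list(origin_window = c(20, 20),
                                      conversion_rate = 0, immune_fraction = 1),
                    age_range = c(40, 40))
  coh <- simulate_cohort(cfg)
  tr <- coh$truth$T0001
  t_wgd <- tr$events$t_true[tr$events$name == "wgd"]
  expect_equal(t_wgd, 0.5)   # 20 years before diagnosis at age 40
  pre <- tr$mutations$true_t < t_wgd
  expect_true(all(tr$mutations$true_multiplicity[pre] == 2))
  expect_true(all(tr$mutations$true_multiplicity[!pre] == 1))
  expect_true(all(coh$segments$major_cn == 2 & coh$segments$minor_cn == 2))
})

test_that("event prevalence matches configuration within binomial error", {
  cfg <- sim_config(n_tumors = 150, seed = 21)
  coh <- simulate_cohort(cfg)
  menu <- cfg$event_menu
  for (i in seq_len(nrow(menu))) {
    carried <- mean(vapply(coh$truth, function(tr)
      menu$name[i] %in% tr$events$name, logical(1)))
    ci <- stats::binom.test(round(carried * 150), 150)$conf.int
    expect_true(menu$prevalence[i] >= ci[1] - 0.02 &&
                  menu$prevalence[i] <= ci[2] + 0.02,
                label = sprintf("prevalence of %s (conf %.2f-%.2f vs %.2f)",
                                menu$name[i], ci[1], ci[2], menu$prevalence[i]))
  }
})

test_that("simulated clonal CpG>T accrual recovers the configured clock rate", {
  set.seed(77)
  cc <- simulate_clock_cohort(1000, rate = 0.37)
  fit <- fit_aging_rate(cc$burden, cc$age)
  expect_equal(fit$rate, 0.37, tolerance = 0.02 / 0.37)
})

test_that("subclonal mutations are generated at the configured CCF", {
  cfg <- sim_config(n_tumors = 4, seed = 8, subclone_prevalence = 1,
                    subclone_ccf = 0.4, subclone_mut_fraction = 0.5)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth$T0001$mutations
  expect_gt(sum(tr$true_ccf == 0.4), 0)
  expect_true(all(tr$true_ccf %in% c(0.4, 1)))
})
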