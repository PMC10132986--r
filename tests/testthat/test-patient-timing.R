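test_that("gain timing responds to the multiplicity stratification", {
  early <- time_segment_gain(0, 20, d = 1, u = 0, C = 2)
  late <- time_segment_gain(20, 0, d = 1, u = 0, C = 2)
  expect_lt(early$mean, 0.15)
  expect_gt(late$mean, 0.85)
  expect_equal(sum(early$prob), 1, tolerance = 1e-9)
  # no information: uniform, flagged
  u <- time_segment_gain(0, 0, 1, 0, 2)
  expect_equal(u$mean, 0.5)
  expect_true("unpowered" %in% u$flags)
  expect_error(time_segment_gain(1, 1, 1, 1, 2), "C must exceed")
})

test_that("gain-time posterior mean matches the phi-space quadrature oracle", {
  cases <- expand.grid(n_hi = c(0, 1, 5, 15, 30), n_1 = c(0, 1, 5, 15, 30),
                       cfg = 1:3)
  cases <- cases[cases$n_hi + cases$n_1 > 0, ]
  cfgs <- list(c(1, 0, 2), c(1, 1, 3), c(2, 0, 4))
  for (i in seq_len(nrow(cases))) {
    k <- cfgs[[cases$cfg[i]]]
    impl <- time_segment_gain(cases$n_hi[i], cases$n_1[i], k[1], k[2], k[3])$mean
    orac <- gain_mean_oracle(cases$n_hi[i], cases$n_1[i], k[1], k[2], k[3])
    expect_equal(impl, orac, tolerance = 0.01,
                 label = sprintf("mean at n_hi=%d n_1=%d cfg=%d (impl %.4f oracle %.4f)",
                                 cases$n_hi[i], cases$n_1[i], cases$cfg[i], impl, orac))
  }
})

test_that("whole-genome timing pools arms and narrows with information", {
  one <- time_wgd(data.frame(n_hi = 6, n_1 = 14, d = 2, u = 0, C = 4))
  single <- time_segment_gain(6, 14, 2, 0, 4)
  expect_equal(one$mean, single$mean, tolerance = 1e-6)
  expect_equal(one$prob, single$prob, tolerance = 1e-9)

  two <- time_wgd(data.frame(n_hi = c(6, 6), n_1 = c(14, 14),
                             d = 2, u = 0, C = 4))
  width1 <- diff(one$ci)
  width2 <- diff(two$ci)
  expect_lt(width2, width1)

  # contradictory arms: broad posterior flagged in QC
  disc <- time_wgd(data.frame(n_hi = c(20, 0), n_1 = c(0, 20),
                              d = 2, u = 0, C = 4))
  expect_true("discordant_arms" %in% disc$flags)

  expect_true("no_doubled_arms" %in%
                time_wgd(data.frame(n_hi = numeric(), n_1 = numeric(),
                                    d = numeric(), u = numeric(),
                                    C = numeric()))$flags)
})

test_that("driver SNV timing respects copy-context constraints", {
  gain <- time_segment_gain(2, 30, d = 2, u = 0, C = 4)  # early gain
  expect_lt(gain$mean, 0.35)
  high <- annotate_mutation(150, 100, 1.0, 2L, 2L)        # multiplicity 2
  expect_equal(high$map_multiplicity, 2L)
  d_pre <- time_snv_driver(high, gain)
  # pre-gain constraint: essentially all mass below the gain's upper CI
  cdf <- cumsum(d_pre$prob)
  expect_gt(cdf[ceiling(gain$ci[2] * 100)], 0.95)

  low <- annotate_mutation(63, 187, 1.0, 1L, 3L)          # multiplicity 1 on 3:1
  d_post <- time_snv_driver(low, gain, u = 0)
  expect_gt(d_post$mean, gain$mean)

  sub <- annotate_mutation(10, 190, 1.0, 1L, 1L)          # subclonal
  d_sub <- time_snv_driver(sub, gain)
  expect_equal(d_sub$mean, 1)
  expect_equal(d_sub$prob[100], 1)

  clon <- annotate_mutation(100, 100, 1.0, 1L, 1L)        # no copy context
  expect_equal(time_snv_driver(clon, NULL)$mean, 0.5)
})

test_that("pi distributions normalize and delta(pi - 1) is exact", {
  for (d in list(pi_uniform(), pi_delta_one(),
                 time_segment_gain(3, 7, 1, 1, 3),
                 time_wgd(data.frame(n_hi = 2, n_1 = 5, d = 2, u = 0, C = 4)))) {
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(d$prob >= 0))
  }
  expect_identical(pi_sample(pi_delta_one(), 5), rep(1, 5))
})

test_that("assembled timing respects pre-gain constraints in every joint sample", {
  # one tumor: WGD with a known-early driver at multiplicity 2
  set.seed(12)
  n <- 120
  purity <- 0.9
  m_true <- c(rep(2L, 30), rep(1L, 90))
  v <- expected_vaf(m_true, 1, purity, 4)
  depth <- stats::rpois(n, 150) + 50L
  alt <- stats::rbinom(n, depth, v)
  muts <- rbind(
    mut_rows(n, arm = "5p", alt = alt, ref = depth - alt),
    mut_rows(1, arm = "5q", alt = 160L, ref = 90L, gene = "TP53",
             pos = 1234L))
  segs <- seg_genome(2L, 2L)
  ann <- annotate_mutations(muts, segs, purity)
  tt <- assemble_patient_timing(ann, segs, n_samples = 300)
  expect_true(all(c("wgd", "TP53") %in% tt$event))
  samples <- attr(tt, "event_samples")
  expect_true(all(samples[, "TP53"] <= samples[, "wgd"]))
  expect_lt(tt$pi_mean[tt$event == "TP53"], tt$pi_mean[tt$event == "wgd"])
})

test_that("a tumor without clonal mutations yields an empty, diagnosed result", {
  muts <- mut_rows(5, alt = 2L, ref = 198L)  # all subclonal
  segs <- seg_genome()
  ann <- annotate_mutations(muts, segs, 1.0)
  tt <- assemble_patient_timing(ann, segs)
  expect_equal(nrow(tt), 0)
  expect_match(attr(tt, "diagnostic"), "clonal")
})

test_that("posterior-mean pi ranks events like their true molecular times", {
  cfg <- sim_config(n_tumors = 12, seed = 41)
  coh <- simulate_cohort(cfg)
  taus <- c()
  for (k in seq_len(12)) {
    id <- coh$metadata$tumor_id[k]
    segs <- coh$segments[coh$segments$tumor_id == id, ]
    ann <- annotate_mutations(coh$mutations[coh$mutations$tumor_id == id, ],
                              segs, coh$metadata$purity[k])
    set.seed(500 + k)
    tt <- assemble_patient_timing(ann, segs, n_samples = 300)
    keep <- tt$class %in% c("arm_gain", "wgd")
    cmp <- merge(tt[keep, c("event", "pi_mean")],
                 coh$truth[[id]]$events[, c("name", "t_true")],
                 by.x = "event", by.y = "name")
    if (nrow(cmp) >= 2)
      taus <- c(taus, stats::cor(cmp$pi_mean, cmp$t_true, method = "kendall"))
  }
  expect_gte(mean(taus), 0.5)
})

test_that("HPV integration sites are timed and the earliest is representative", {
  set.seed(23)
  purity <- 0.9
  # early gain on 3q: mostly multiplicity-2 clonal mutations absent
  n <- 80
  m_true <- c(rep(2L, 8), rep(1L, 72))
  v <- expected_vaf(m_true, 1, purity, 3)
  depth <- stats::rpois(n, 150) + 50L
  alt <- stats::rbinom(n, depth, v)
  muts <- mut_rows(n, arm = "3q", alt = alt, ref = depth - alt)
  segs <- seg_genome(1L, 1L, override = list(`3q` = c(2L, 1L)))
  ann <- annotate_mutations(muts, segs, purity)
  support <- data.frame(
    site_id = c("s1", "s2"), chrom_arm = "3q", pos = c(100L, 200L),
    alt_count = c(180L, 60L), ref_count = c(95L, 190L))  # mult-2-like, mult-1-like
  res <- time_hpv_integration(support, ann, segs, purity)
  expect_equal(nrow(res), 2)
  expect_lt(res$pi_mean[res$site_id == "s1"], res$pi_mean[res$site_id == "s2"])
  expect_true(res$representative[which.min(res$pi_mean)])
  # no covered sites -> untimed
  none <- time_hpv_integration(
    data.frame(site_id = "x", chrom_arm = "3q", pos = 1L,
               alt_count = 0L, ref_count = 0L), ann, segs, purity)
  expect_equal(nrow(none), 0)
})
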