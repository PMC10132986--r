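test_that("MATH reproduces hand computations and the normal consistency limit", {
  expect_equal(math_score(c(0.3, 0.3, 0.3, 0.3)), 0)
  expect_equal(math_score(c(0.2, 0.4, 0.6)), 74.13)
  set.seed(14)
  x <- stats::rnorm(50000, 0.5, 0.1)
  expect_equal(math_score(x), 20, tolerance = 0.05)
  expect_warning(m0 <- math_score(c(0, 0, 0.1)), "undefined")
  expect_true(is.na(m0))
  expect_error(math_score(0.4), "at least 2")
})

test_that("MATH is invariant under multiplicative rescaling of MAFs", {
  set.seed(15)
  x <- stats::runif(200, 0.05, 0.6)
  for (s in c(0.25, 0.5, 1.5)) expect_equal(math_score(x), math_score(s * x))
})

test_that("ploidy classification follows the printed cascade", {
  # fractions of genome at total copy 2/3/4 set by construction
  frac_segs <- function(f2, f3, f4) {
    states <- list(c(1L, 1L), c(2L, 1L), c(2L, 2L), c(1L, 0L))
    lens <- c(f2, f3, f4, 1 - f2 - f3 - f4) * 1e8
    do.call(rbind, lapply(seq_along(states), function(i)
      data.frame(tumor_id = "T1", chrom_arm = "1p",
                 start = 0L, end = as.integer(lens[i]),
                 major_cn = states[[i]][1], minor_cn = states[[i]][2])))
  }
  expect_equal(ploidy_fractions(frac_segs(0.80, 0.10, 0.05))$class, "diploid")
  expect_equal(ploidy_fractions(frac_segs(0.30, 0.50, 0.20))$class, "triploid")
  expect_equal(ploidy_fractions(frac_segs(0.40, 0.20, 0.40))$class, "tetraploid")
  expect_error(ploidy_fractions(frac_segs(0, 0, 0)[0, ]), "segments")
})

test_that("aneuploidy classes partition all copy profiles", {
  set.seed(16)
  for (i in 1:25) {
    f2 <- stats::runif(1); f3 <- stats::runif(1, 0, 1 - f2)
    f4 <- stats::runif(1, 0, 1 - f2 - f3)
    segs <- data.frame(tumor_id = "T1", chrom_arm = "1p", start = 0L,
                       end = as.integer(c(f2, f3, f4, 1 - f2 - f3 - f4) * 1e8 + 1),
                       major_cn = c(1L, 2L, 2L, 5L), minor_cn = c(1L, 1L, 2L, 0L))
    expect_true(ploidy_fractions(segs)$class %in%
                  c("diploid", "triploid", "tetraploid"))
  }
})

test_that("whole-genome event calls follow the arm-count disjunction", {
  arms <- chrom_arms()$arm
  # 22 of 39 arms amplified (2:1) -> event (at least half)
  s1 <- seg_genome(1L, 1L,
                   override = stats::setNames(rep(list(c(2L, 1L)), 22), arms[1:22]))
  w1 <- call_whole_genome_event(s1)
  expect_true(w1$called)
  expect_equal(w1$wge_call, "WGT")   # mostly triploid profile
  # 4 arms amplified on both alleles, 5 amplified total -> event
  s2 <- seg_genome(1L, 1L, override = c(
    stats::setNames(rep(list(c(2L, 2L)), 4), arms[1:4]),
    stats::setNames(list(c(2L, 1L)), arms[5])))
  w2 <- call_whole_genome_event(s2)
  expect_true(w2$called)
  expect_true(w2$qc_flag)            # genome still mostly diploid
  expect_equal(w2$wge_call, "none")
  # 3 both-allele and 6 total of 39: below both thresholds
  s3 <- seg_genome(1L, 1L, override = c(
    stats::setNames(rep(list(c(2L, 2L)), 3), arms[1:3]),
    stats::setNames(rep(list(c(2L, 1L)), 3), arms[4:6])))
  expect_false(call_whole_genome_event(s3)$called)
  # fully doubled genome: WGD
  expect_equal(call_whole_genome_event(seg_genome(2L, 2L))$wge_call, "WGD")
})

test_that("FGA measures deviation from the class baseline", {
  expect_equal(compute_fga(seg_genome(1L, 1L), wge = FALSE), 0)
  # 10 equal segments, 3 at 2:1
  segs <- data.frame(tumor_id = "T1", chrom_arm = "1p",
                     start = as.integer(0:9 * 1e7), end = as.integer(1:10 * 1e7),
                     major_cn = c(rep(2L, 3), rep(1L, 7)),
                     minor_cn = 1L)
  expect_equal(compute_fga(segs, wge = FALSE), 0.3)
  # fully doubled genome with the event called: baseline shifts to 2
  expect_equal(compute_fga(seg_genome(2L, 2L), wge = TRUE), 0)
  expect_gt(compute_fga(seg_genome(2L, 2L), wge = FALSE), 0.99)
  # real-valued allelic copies respect the 0.2 threshold
  segs$major_cn <- c(rep(1.15, 3), rep(1.25, 7))
  expect_equal(compute_fga(segs, wge = FALSE), 0.7)
})

test_that("early-WGD tumors show higher post-WGD than pre-WGD MATH", {
  menu <- data.frame(name = "wgd", class = "wgd", locus = "genome",
                     prevalence = 1, t_lo = 0, t_hi = 1)
  cfg <- sim_config(n_tumors = 6, seed = 33, event_menu = menu,
                    wgd_params = list(origin_window = c(25, 35),
                                      conversion_rate = 0,
                                      immune_fraction = 1),
                    age_range = c(55, 75))
  coh <- simulate_cohort(cfg)
  diffs <- c()
  for (k in 1:6) {
    id <- coh$metadata$tumor_id[k]
    segs <- coh$segments[coh$segments$tumor_id == id, ]
    ann <- annotate_mutations(coh$mutations[coh$mutations$tumor_id == id, ],
                              segs, coh$metadata$purity[k])
    pp <- math_pre_post_wgd(ann, segs)
    if (!is.na(pp$math_pre) && !is.na(pp$math_post))
      diffs <- c(diffs, pp$math_post - pp$math_pre)
  }
  expect_gt(mean(diffs >= 0), 0.5)
  # no whole-genome event: decomposition absent
  segs0 <- seg_genome(1L, 1L)
  ann0 <- annotate_mutations(mut_rows(30, alt = 40L, ref = 60L), segs0, 0.8)
  expect_true(is.na(math_pre_post_wgd(ann0, segs0)$math_pre))
})

test_that("tumors with whole-genome events have higher MATH than diploid tumors", {
  cfg <- sim_config(n_tumors = 25, seed = 34)
  coh <- simulate_cohort(cfg)
  prof <- do.call(rbind, lapply(seq_len(25), function(k) {
    id <- coh$metadata$tumor_id[k]
    segs <- coh$segments[coh$segments$tumor_id == id, ]
    ann <- annotate_mutations(coh$mutations[coh$mutations$tumor_id == id, ],
                              segs, coh$metadata$purity[k])
    heterogeneity_profile(ann, segs)
  }))
  wge <- prof$wge_call != "none"
  expect_gt(sum(wge), 2)
  expect_gt(stats::median(prof$math[wge]), stats::median(prof$math[!wge]))
})

test_that("paired-sample profiles merge by averaging with QC on discordance", {
  p1 <- data.frame(math = 30, fga = 0.2, frac_diploid = 0.9, frac_triploid = 0.05,
                   frac_tetraploid = 0.02, aneuploidy_class = "diploid",
                   wge_call = "none", math_pre = NA_real_, math_post = NA_real_,
                   qc_flag = FALSE)
  p2 <- transform(p1, math = 40, fga = 0.3)
  m <- merge_paired_samples(rbind(p1, p2))
  expect_equal(m$math, 35)
  expect_equal(m$fga, 0.25)
  expect_false(m$qc_flag)
  identical2 <- merge_paired_samples(rbind(p1, p1))
  expect_equal(identical2$math, p1$math)
  p3 <- transform(p2, aneuploidy_class = "tetraploid", wge_call = "WGD")
  expect_true(merge_paired_samples(rbind(p1, p3))$qc_flag)
})
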