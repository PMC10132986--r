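# shared fixture builders; everything is generated in code

# diploid one-arm segment table
seg1 <- function(arm = "1p", major = 1L, minor = 1L, tumor_id = "T1") {
  data.frame(tumor_id = tumor_id, chrom_arm = arm, start = 0L,
             end = as.integer(arm_length_mb_t(arm) * 1e6),
             major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
}

arm_length_mb_t <- function(arm) {
  a <- chrom_arms()
  a$length_mb[match(arm, a$arm)]
}

# whole-genome segment table at a given copy state, with overrides per arm
seg_genome <- function(major = 1L, minor = 1L, override = list()) {
  a <- chrom_arms()
  s <- data.frame(tumor_id = "T1", chrom_arm = a$arm, start = 0L,
                  end = as.integer(a$length_mb * 1e6),
                  major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
  for (arm in names(override)) {
    s$major_cn[s$chrom_arm == arm] <- override[[arm]][1]
    s$minor_cn[s$chrom_arm == arm] <- override[[arm]][2]
  }
  s
}

# mutation table with fixed read counts on one arm
mut_rows <- function(n, arm = "1p", alt = 50L, ref = 50L, context = "ACA",
                     gene = "", pos = NULL) {
  data.frame(tumor_id = "T1", chrom_arm = arm,
             pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
             ref = "C", alt = "A", alt_count = alt, ref_count = ref,
             context = context, gene = gene, stringsAsFactors = FALSE)
}

# independent oracle for the gain-time posterior mean: quadrature in phi space
# over the truncated Beta pushforward (never touches the package's t grid)
gain_mean_oracle <- function(n_hi, n_1, d, u, C) {
  phimax <- d / (d + u)
  tfun <- function(phi) phi * C / (d - phi * (d + u - C))
  # integrate on the log scale for numerical stability at large counts
  lf <- function(p) n_hi * log(p) + n_1 * log1p(-p)
  peak <- stats::optimize(lf, c(1e-9, phimax - 1e-9), maximum = TRUE)$objective
  num <- stats::integrate(function(p) tfun(p) * exp(lf(p) - peak), 0, phimax,
                          rel.tol = 1e-9)$value
  den <- stats::integrate(function(p) exp(lf(p) - peak), 0, phimax,
                          rel.tol = 1e-9)$value
  num / den
}

# small cohort of synthetic per-tumor pi posteriors drawn around per-event
# cohort means (used for league/comparison tests without the full pipeline)
beta_pi <- function(m, conc = 80, nbins = 100L) {
  mids <- (seq_len(nbins) - 0.5) / nbins
  pi_dist(stats::dbeta(mids, m * conc, (1 - m) * conc))
}

synthetic_pi_cohort <- function(n, mus, sd_between = 0.12, conc = 80,
                                prevalence = 1) {
  lapply(seq_len(n), function(i) {
    carry <- stats::runif(length(mus)) < prevalence
    tt <- pmin(pmax(stats::rnorm(length(mus), mus, sd_between), 0.02), 0.98)
    out <- lapply(which(carry), function(k) beta_pi(tt[k], conc))
    names(out) <- names(mus)[carry]
    out
  })
}
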