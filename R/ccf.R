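#' Expected variant allele fraction under purity dilution
#'
#' For a mutation present at multiplicity `m` in a fraction `ccf` of cancer
#' cells, in a sample of purity `p` where the local total copy number is `N`,
#' the expected fraction of variant reads is
#' \deqn{VAF = \frac{m \cdot ccf \cdot p}{2(1-p) + p N}.}
#' Contaminating normal cells contribute two reference copies each.
#'
#' @param multiplicity Integer number of mutated copies per cancer cell
#'   (1 to `local_total_cn`).
#' @param ccf Cancer cell fraction in `[0, 1]`.
#' @param purity Sample purity in `(0, 1]`.
#' @param local_total_cn Total (major + minor) copy number at the locus.
#' @return Expected VAF in `[0, 1]`.
#' @examples
#' expected_vaf(1, 1, 1, 2)      # 0.5: pure diploid clonal het
#' expected_vaf(2, 1, 0.6, 4)    # 0.375: doubled mutation in a tetraploid region
#' @export
expected_vaf <- function(multiplicity, ccf, purity, local_total_cn) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(ccf < 0) || any(ccf > 1)) stop("ccf must be in [0, 1]")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  if (any(multiplicity > local_total_cn))
    stop("multiplicity exceeds local total copy number")
  multiplicity * ccf * purity / (2 * (1 - purity) + purity * local_total_cn)
}

#' Annotate one mutation with multiplicity and CCF posteriors
#'
#' Evaluates the binomial likelihood of the observed alt count over a grid of
#' (multiplicity, CCF) states: multiplicity 1..major copy number, CCF on
#' `ccf_grid_n` uniform points in `[0, 1]`. The prior is flat over
#' multiplicity and spike-and-slab over CCF: mass `clonal_prior_weight` on
#' CCF = 1 (most somatic mutations in a bulk sample are clonal) and the rest
#' uniform over the grid. Without the clonal spike the state (m = 1,
#' CCF = 1) is not identifiable from (m = 2, CCF ~ 0.5) on gained segments —
#' both give the same expected VAF — and clonality calls degrade.
#' Marginal posteriors for multiplicity and CCF are returned along
#' with the MAP multiplicity and a clonality call: clonal iff the posterior
#' probability that CCF >= `clonal_ccf` is at least 0.5 (ties are called
#' clonal). Sites with depth below `min_depth` are flagged unpowered and are
#' excluded from timing downstream (but still contribute to MATH, which uses
#' raw allele fractions).
#'
#' @param alt_count,ref_count Variant and reference read counts.
#' @param purity Sample purity in `(0, 1]`.
#' @param major_cn,minor_cn Allelic copy number of the covering segment.
#' @param clonal_ccf CCF threshold defining clonality (default 0.85).
#' @param min_depth Depth below which the site is unpowered (default 10).
#' @param ccf_grid_n Number of CCF grid points (default 101).
#' @param clonal_prior_weight Prior mass placed on CCF = 1 (default 0.5).
#' @return A list of class `mut_annotation`: `multiplicity_posterior`,
#'   `ccf_posterior` (with attribute `"grid"`), `map_multiplicity`, `ccf_map`,
#'   `ccf_mean`, `p_clonal`, `clonal`, `unpowered`.
#' @export
annotate_mutation <- function(alt_count, ref_count, purity, major_cn, minor_cn,
                              clonal_ccf = 0.85, min_depth = 10L,
                              ccf_grid_n = 101L, clonal_prior_weight = 0.5) {
  depth <- alt_count + ref_count
  if (depth <= 0) {
    out <- list(multiplicity_posterior = NULL, ccf_posterior = NULL,
                map_multiplicity = NA_integer_, ccf_map = NA_real_,
                ccf_mean = NA_real_, p_clonal = NA_real_, clonal = NA,
                unpowered = TRUE)
    class(out) <- "mut_annotation"
    return(out)
  }
  total_cn <- major_cn + minor_cn
  m_max <- max(major_cn, 1L)
  ccf <- seq(0, 1, length.out = ccf_grid_n)
  prior_c <- ccf_prior(ccf, clonal_prior_weight)
  lik <- matrix(0, nrow = m_max, ncol = ccf_grid_n)
  for (m in seq_len(m_max)) {
    v <- expected_vaf(m, ccf, purity, max(total_cn, m))
    lik[m, ] <- stats::dbinom(alt_count, depth, v) * prior_c
  }
  if (sum(lik) == 0) lik[] <- 1  # numerically impossible data: fall back to flat
  post <- lik / sum(lik)
  m_post <- rowSums(post)
  c_post <- colSums(post)
  p_clonal <- sum(c_post[ccf >= clonal_ccf - 1e-12])
  out <- list(
    multiplicity_posterior = m_post,
    ccf_posterior = structure(c_post, grid = ccf),
    map_multiplicity = which.max(m_post),
    ccf_map = ccf[which.max(c_post)],
    ccf_mean = sum(c_post * ccf),
    p_clonal = p_clonal,
    clonal = p_clonal >= 0.5,
    unpowered = depth < min_depth
  )
  class(out) <- "mut_annotation"
  out
}

#' Clonality call from an annotation
#'
#' Deterministic gate used before timing: an annotated mutation is clonal iff
#' its posterior mass at CCF >= the clonality threshold is at least 0.5 (the
#' boundary case of exactly 0.5 is called clonal).
#'
#' @param annotation A `mut_annotation` from [annotate_mutation()].
#' @return Logical.
#' @export
classify_clonal <- function(annotation) {
  stopifnot(inherits(annotation, "mut_annotation"))
  isTRUE(annotation$p_clonal >= 0.5)
}

#' Annotate a mutation table
#'
#' Vectorized version of [annotate_mutation()] for a full per-tumor mutation
#' table. Each mutation is matched to its covering copy-number segment by arm
#' and position, then annotated in groups sharing the same copy-number state.
#'
#' @param muts Mutation data.frame with columns `chrom_arm`, `pos`,
#'   `alt_count`, `ref_count` (other columns are carried through).
#' @param segments Segment data.frame with columns `chrom_arm`, `start`,
#'   `end`, `major_cn`, `minor_cn`.
#' @param purity Sample purity.
#' @inheritParams annotate_mutation
#' @return `muts` with added columns `major_cn`, `minor_cn`, `total_cn`,
#'   `depth`, `vaf`, `map_multiplicity`, `ccf_mean`, `ccf_map`, `p_clonal`,
#'   `clonal`, `unpowered`, `p_detect`.
#' @export
annotate_mutations <- function(muts, segments, purity, clonal_ccf = 0.85,
                               min_depth = 10L, ccf_grid_n = 101L,
                               clonal_prior_weight = 0.5) {
  n <- nrow(muts)
  muts$major_cn <- NA_integer_
  muts$minor_cn <- NA_integer_
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    hit <- muts$chrom_arm == s$chrom_arm & muts$pos >= s$start & muts$pos < s$end
    muts$major_cn[hit] <- s$major_cn
    muts$minor_cn[hit] <- s$minor_cn
  }
  if (anyNA(muts$major_cn))
    warning(sum(is.na(muts$major_cn)), " mutations outside any segment; assuming 1:1")
  muts$major_cn[is.na(muts$major_cn)] <- 1L
  muts$minor_cn[is.na(muts$minor_cn)] <- 1L
  muts$total_cn <- muts$major_cn + muts$minor_cn
  muts$depth <- muts$alt_count + muts$ref_count
  muts$vaf <- ifelse(muts$depth > 0, muts$alt_count / muts$depth, NA_real_)

  ccf <- seq(0, 1, length.out = ccf_grid_n)
  prior_c <- ccf_prior(ccf, clonal_prior_weight)
  muts$map_multiplicity <- NA_integer_
  muts$ccf_mean <- NA_real_
  muts$ccf_map <- NA_real_
  muts$p_clonal <- NA_real_

  grp <- paste(muts$major_cn, muts$total_cn)
  for (g in unique(grp)) {
    idx <- which(grp == g & muts$depth > 0)
    if (!length(idx)) next
    m_max <- max(muts$major_cn[idx][1], 1L)
    C <- muts$total_cn[idx][1]
    # likelihood cube: mutations x ccf-grid, one slice per multiplicity
    post_m <- matrix(0, length(idx), m_max)
    post_c <- matrix(0, length(idx), ccf_grid_n)
    for (m in seq_len(m_max)) {
      v <- expected_vaf(m, ccf, purity, max(C, m))
      L <- stats::dbinom(matrix(muts$alt_count[idx], length(idx), ccf_grid_n),
                         matrix(muts$depth[idx], length(idx), ccf_grid_n),
                         matrix(v, length(idx), ccf_grid_n, byrow = TRUE)) *
        matrix(prior_c, length(idx), ccf_grid_n, byrow = TRUE)
      post_m[, m] <- rowSums(L)
      post_c <- post_c + L
    }
    tot <- rowSums(post_m)
    bad <- tot == 0
    if (any(bad)) { post_m[bad, ] <- 1; post_c[bad, ] <- 1; tot[bad] <- m_max }
    muts$map_multiplicity[idx] <- max.col(post_m, ties.method = "first")
    csum <- rowSums(post_c)
    muts$ccf_mean[idx] <- as.vector(post_c %*% ccf) / csum
    muts$ccf_map[idx] <- ccf[max.col(post_c, ties.method = "first")]
    muts$p_clonal[idx] <- rowSums(post_c[, ccf >= clonal_ccf - 1e-12, drop = FALSE]) / csum
  }
  muts$clonal <- muts$p_clonal >= 0.5
  muts$unpowered <- muts$depth < min_depth
  # power to detect: chance of >= 3 alt reads for a clonal multiplicity-1
  # mutation at this depth and copy state; used to weight timing counts
  v1 <- expected_vaf(1, 1, purity, pmax(muts$total_cn, 1))
  muts$p_detect <- 1 - stats::pbinom(2, muts$depth, v1)
  muts
}

# spike-and-slab prior over the CCF grid: mass w on ccf = 1, rest uniform
ccf_prior <- function(ccf, w) {
  p <- rep((1 - w) / length(ccf), length(ccf))
  p[length(ccf)] <- p[length(ccf)] + w
  p
}
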