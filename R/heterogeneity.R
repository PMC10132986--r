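#' MATH score of mutant allele fractions
#'
#' Mutant-allele tumor heterogeneity: the median-normalized width of the
#' distribution of raw mutant allele fractions,
#' \deqn{\mathrm{MATH} = 100 \times 1.4826 \times
#'   \mathrm{median}(|MAF - \mathrm{median}(MAF)|) / \mathrm{median}(MAF),}
#' where 1.4826 scales the median absolute deviation of a normal distribution
#' to its standard deviation.
#'
#' @param maf Numeric vector of mutant allele fractions (>= 2 values).
#' @return MATH value (dimensionless); `NA` with a warning when the median
#'   MAF is 0.
#' @examples
#' math_score(c(0.2, 0.4, 0.6))  # 74.13
#' @export
math_score <- function(maf) {
  maf <- maf[!is.na(maf)]
  if (length(maf) < 2) stop("MATH needs at least 2 mutations")
  med <- stats::median(maf)
  if (med == 0) {
    warning("median MAF is 0: MATH undefined")
    return(NA_real_)
  }
  100 * stats::mad(maf, constant = 1.4826) / med
}

seg_total_cn <- function(segments) segments$major_cn + segments$minor_cn

#' Genome fractions by ploidy state and aneuploidy class
#'
#' Length-weighted fractions of the genome at total copy number 2, 3 and 4,
#' and the aneuploidy class: diploid when the diploid fraction exceeds 0.65;
#' otherwise triploid when the triploid fraction exceeds 0.35; otherwise
#' tetraploid.
#'
#' @param segments Segment data.frame with `start`, `end`, `major_cn`,
#'   `minor_cn`.
#' @return List: `fractions` (named diploid/triploid/tetraploid) and `class`.
#' @export
ploidy_fractions <- function(segments) {
  len <- segments$end - segments$start
  if (!nrow(segments) || sum(len) <= 0) stop("segments must cover > 0 Mb")
  tot <- seg_total_cn(segments)
  fr <- c(diploid = sum(len[tot == 2]), triploid = sum(len[tot == 3]),
          tetraploid = sum(len[tot == 4])) / sum(len)
  cls <- if (fr["diploid"] > 0.65) "diploid"
         else if (fr["triploid"] > 0.35) "triploid"
         else "tetraploid"
  list(fractions = fr, class = cls)
}

#' Call a whole-genome event (WGD or WGT)
#'
#' A whole-genome event is called when at least half of the chromosome arms
#' are amplified (arm total copy above the baseline of 2 over at least half
#' the arm length) or at least four arms are amplified on both alleles (both
#' allelic copies >= 2 over at least half the arm length). A called event is
#' labeled WGT when the tumor's aneuploidy class is triploid and WGD when
#' tetraploid; an event call in a diploid-class tumor is retained but labeled
#' `"none"` with a QC flag.
#'
#' @param segments Segment data.frame.
#' @return List: `called` (logical), `wge_call` (`"none"`, `"WGD"`, `"WGT"`),
#'   `class` (aneuploidy class), `n_amplified`, `n_both_amplified`, `qc_flag`.
#' @export
call_whole_genome_event <- function(segments) {
  arm_tab <- call_arm_events(segments)
  n_arms <- nrow(chrom_arms())
  n_amp <- sum(arm_tab$frac_gain >= 0.5)
  n_both <- sum(arm_tab$frac_both_amp >= 0.5)
  called <- n_amp >= n_arms / 2 || n_both >= 4
  cls <- ploidy_fractions(segments)$class
  wge <- if (!called) "none"
         else if (cls == "triploid") "WGT"
         else if (cls == "tetraploid") "WGD"
         else "none"
  list(called = called, wge_call = wge, class = cls,
       n_amplified = n_amp, n_both_amplified = n_both,
       qc_flag = called && cls == "diploid")
}

#' Fraction of the genome altered
#'
#' Length-weighted fraction of the genome whose allelic copy number deviates
#' by more than 0.2 from the baseline for either allele: one copy per allele
#' without a whole-genome event, two copies per allele with one. Real-valued
#' (purity-corrected) allelic copies are used as given; integer copies work
#' identically.
#'
#' @param segments Segment data.frame (allelic copies may be non-integer).
#' @param wge Logical: has the tumor had a whole-genome event?
#' @return FGA in `[0, 1]`.
#' @export
compute_fga <- function(segments, wge = FALSE) {
  len <- segments$end - segments$start
  if (sum(len) <= 0) return(0)
  b <- if (wge) 2 else 1
  dev <- abs(segments$major_cn - b) > 0.2 | abs(segments$minor_cn - b) > 0.2
  sum(len[dev]) / sum(len)
}

#' MATH before and after a whole-genome event
#'
#' Splits a tumor's clonal mutations into those timed before the whole-genome
#' event (multiplicity above one on doubled regions) and the remainder, and
#' computes MATH on the raw allele fractions of each set. Either value is
#' `NA` when its set has fewer than `min_muts` mutations.
#'
#' @param ann Annotated mutation table.
#' @param segments Segment table (used to find doubled regions).
#' @param depth_floor Minimum depth for a mutation to enter MATH (default 20).
#' @param min_muts Minimum set size (default 10).
#' @return List `math_pre`, `math_post`.
#' @export
math_pre_post_wgd <- function(ann, segments, depth_floor = 20L, min_muts = 10L) {
  wge <- call_whole_genome_event(segments)
  if (!wge$called) return(list(math_pre = NA_real_, math_post = NA_real_))
  arm_tab <- call_arm_events(segments)
  doubled <- arm_tab$chrom_arm[arm_tab$frac_both_amp >= 0.5 |
                                 (arm_tab$major_cn == 2 & arm_tab$minor_cn == 0)]
  ok <- !is.na(ann$clonal) & ann$clonal & ann$depth >= depth_floor
  pre <- ok & ann$chrom_arm %in% doubled & ann$map_multiplicity >= 2
  post <- ok & !pre
  list(
    math_pre = if (sum(pre) >= min_muts) math_score(ann$vaf[pre]) else NA_real_,
    math_post = if (sum(post) >= min_muts) math_score(ann$vaf[post]) else NA_real_
  )
}

#' Heterogeneity profile of one tumor sample
#'
#' Computes MATH (raw allele fractions at depth >= `depth_floor`), ploidy
#' fractions and aneuploidy class, the whole-genome event call, FGA against
#' the class-appropriate baseline, and (when a whole-genome event is called)
#' the pre/post-event MATH decomposition.
#'
#' @param ann Annotated mutation table ([annotate_mutations()]).
#' @param segments Segment table.
#' @param depth_floor Depth floor for MATH (default 20).
#' @return A one-row data.frame of class `het_profile`: `math`, `fga`,
#'   `frac_diploid`, `frac_triploid`, `frac_tetraploid`, `aneuploidy_class`,
#'   `wge_call`, `math_pre`, `math_post`, `qc_flag`.
#' @export
heterogeneity_profile <- function(ann, segments, depth_floor = 20L) {
  pf <- ploidy_fractions(segments)
  wge <- call_whole_genome_event(segments)
  mafs <- ann$vaf[!is.na(ann$vaf) & ann$depth >= depth_floor]
  pp <- math_pre_post_wgd(ann, segments, depth_floor = depth_floor)
  out <- data.frame(
    math = if (length(mafs) >= 2) math_score(mafs) else NA_real_,
    fga = compute_fga(segments, wge = wge$called),
    frac_diploid = unname(pf$fractions["diploid"]),
    frac_triploid = unname(pf$fractions["triploid"]),
    frac_tetraploid = unname(pf$fractions["tetraploid"]),
    aneuploidy_class = pf$class,
    wge_call = wge$wge_call,
    math_pre = pp$math_pre,
    math_post = pp$math_post,
    qc_flag = wge$qc_flag,
    stringsAsFactors = FALSE)
  class(out) <- c("het_profile", "data.frame")
  out
}

#' Merge heterogeneity profiles of paired samples from one tumor
#'
#' MATH values of separately sequenced samples of the same tumor are
#' averaged; FGA is averaged by the same convention. Aneuploidy classes and
#' whole-genome-event calls must agree, otherwise the merged profile is
#' QC-flagged (majority call retained).
#'
#' @param profiles A list of `het_profile` rows (>= 2) or a data.frame of
#'   stacked profiles.
#' @return A single merged `het_profile` row.
#' @export
merge_paired_samples <- function(profiles) {
  if (is.data.frame(profiles)) p <- profiles else p <- do.call(rbind, profiles)
  stopifnot(nrow(p) >= 2)
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  discord <- length(unique(p$aneuploidy_class)) > 1 || length(unique(p$wge_call)) > 1
  out <- p[1, , drop = FALSE]
  for (col in c("math", "fga", "frac_diploid", "frac_triploid", "frac_tetraploid",
                "math_pre", "math_post"))
    out[[col]] <- mean(p[[col]])
  out$aneuploidy_class <- modal(p$aneuploidy_class)
  out$wge_call <- modal(p$wge_call)
  out$qc_flag <- any(p$qc_flag) || discord
  rownames(out) <- NULL
  out
}
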