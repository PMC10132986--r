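#' Autosomal chromosome-arm table
#'
#' The analysis works at the resolution of chromosome arms: the 39 autosomal
#' arms that carry appreciable euchromatin (the short arms of the acrocentric
#' chromosomes 13, 14, 15, 21 and 22 are excluded). Lengths are approximate
#' megabases and are used only as relative weights (mutation placement,
#' length-weighted genome fractions); coordinates elsewhere in the package are
#' arm-relative, 0-based half-open.
#'
#' @return A data.frame with columns `arm` (e.g. `"9p"`), `chrom`, and
#'   `length_mb`.
#' @examples
#' arms <- chrom_arms()
#' nrow(arms)          # 39
#' sum(arms$length_mb) # ~2,800 Mb of non-acrocentric autosome
#' @export
chrom_arms <- function() {
  p <- c(123, 93, 91, 50, 49, 61, 60, 45, 43, 40, 53, 36,
         NA, NA, NA, 36, 25, 19, 26, 28, NA, NA)
  q <- c(125, 149, 107, 140, 133, 110, 99, 100, 95, 94, 82, 97,
         98, 89, 82, 54, 58, 62, 33, 36, 34, 37)
  out <- data.frame(
    arm = c(paste0(1:22, "p"), paste0(1:22, "q")),
    chrom = rep(1:22, 2L),
    length_mb = c(p, q),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$length_mb), , drop = FALSE]
  out <- out[order(out$chrom, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

arm_length_mb <- function(arm) {
  arms <- chrom_arms()
  idx <- match(arm, arms$arm)
  if (anyNA(idx)) stop("unknown chromosome arm: ", paste(arm[is.na(idx)], collapse = ", "))
  arms$length_mb[idx]
}
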