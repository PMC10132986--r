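#' Discretized posterior over molecular time
#'
#' A `pi_dist` is the package's representation of a posterior probability
#' distribution over molecular time on `[0, 1]`: a histogram with `nbins`
#' equal-width bins, normalized to sum to one. Molecular time 0 corresponds to
#' the first clonal event of a tumor and 1 to the last; subclonal events are
#' represented as a point mass at 1 (`pi_delta_one()`).
#'
#' @param prob Non-negative vector of bin masses (will be normalized).
#' @param mean Optional pre-computed posterior mean; defaults to the histogram
#'   mean over bin midpoints.
#' @param flags Character vector of QC flags (e.g. `"unpowered"`).
#' @return An object of class `pi_dist` with elements `prob`, `mids`, `mean`,
#'   `ci` (75\% equal-tailed credible interval) and `flags`.
#' @export
pi_dist <- function(prob, mean = NULL, flags = character()) {
  if (any(prob < 0) || all(prob == 0)) stop("pi_dist needs non-negative mass summing > 0")
  prob <- prob / sum(prob)
  n <- length(prob)
  mids <- (seq_len(n) - 0.5) / n
  if (is.null(mean)) mean <- sum(prob * mids)
  obj <- list(prob = prob, mids = mids, mean = mean,
              ci = hist_quantile(prob, c(0.125, 0.875)), flags = flags)
  class(obj) <- "pi_dist"
  obj
}

#' @export
print.pi_dist <- function(x, ...) {
  cat(sprintf("pi posterior: mean %.3f, 75%% CI [%.3f, %.3f], %d bins%s\n",
              x$mean, x$ci[1], x$ci[2], length(x$prob),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Uniform and degenerate molecular-time posteriors
#'
#' `pi_uniform()` is the posterior assigned to clonal events that cannot be
#' timed; `pi_delta_one()` is the point mass at 1 assigned to subclonal events
#' and to the last clonal event.
#'
#' @param nbins Number of histogram bins.
#' @param flags QC flags to attach.
#' @return A [pi_dist].
#' @export
pi_uniform <- function(nbins = 100L, flags = "untimed") {
  pi_dist(rep(1 / nbins, nbins), mean = 0.5, flags = flags)
}

#' @rdname pi_uniform
#' @export
pi_delta_one <- function(nbins = 100L) {
  p <- numeric(nbins)
  p[nbins] <- 1
  d <- pi_dist(p, mean = 1, flags = "delta_one")
  d$ci <- c(1, 1)
  d
}

is_delta_one <- function(d) "delta_one" %in% d$flags

# equal-tailed quantiles of a binned distribution, linear within bins
hist_quantile <- function(prob, q) {
  n <- length(prob)
  cdf <- cumsum(prob)
  vapply(q, function(p) {
    j <- which(cdf >= p - 1e-12)[1]
    lo <- if (j > 1) cdf[j - 1] else 0
    within <- if (prob[j] > 0) (p - lo) / prob[j] else 0.5
    (j - 1 + within) / n
  }, numeric(1))
}

#' Draw samples from a molecular-time posterior
#'
#' Samples a bin with the histogram probabilities and a uniform position
#' within it; a point mass at 1 returns exactly 1. Uses the current RNG
#' state (seed management is the caller's responsibility).
#'
#' @param d A [pi_dist].
#' @param n Number of draws.
#' @return Numeric vector in `[0, 1]`.
#' @export
pi_sample <- function(d, n = 1L) {
  if (is_delta_one(d)) return(rep(1, n))
  nb <- length(d$prob)
  j <- sample.int(nb, n, replace = TRUE, prob = d$prob)
  (j - 1 + stats::runif(n)) / nb
}

# bin a vector of values in [0,1] into a pi_dist; exact-1 values go to the
# last bin
bin_pi <- function(x, nbins = 100L, flags = character()) {
  x <- pmin(pmax(x, 0), 1)
  j <- pmin(floor(x * nbins) + 1L, nbins)
  pi_dist(tabulate(j, nbins), mean = mean(x), flags = flags)
}
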