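#' Classify a mutation's trinucleotide context
#'
#' Rule-based classification into the clock-like aging channel (C>T at CpG,
#' the dominant component of signature SBS1), the APOBEC channel (C>T or C>G
#' at TpCpW, W in \{A, T\}; signatures SBS2/SBS13), and everything else. A
#' site matching both motifs (TCG with C>T) is assigned to CpG>T: the clock
#' count is kept conservative and such sites are excluded from
#' APOBEC-sensitive analyses. Pre-classified labels (`"CpG>T"`, `"APOBEC"`,
#' `"other"`) pass through unchanged.
#'
#' @param muts Data.frame with columns `context` (trinucleotide around a
#'   mutated C, or a pre-classified label), `ref`, `alt`.
#' @return Character vector: `"CpG>T"`, `"APOBEC"` or `"other"`.
#' @export
classify_context <- function(muts) {
  ctx <- toupper(as.character(muts$context))
  out <- rep("other", length(ctx))
  out[ctx == "CPG>T"] <- "CpG>T"
  out[ctx == "APOBEC"] <- "APOBEC"
  tri <- grepl("^[ACGT]{3}$", ctx)
  if (any(tri)) {
    ref <- toupper(as.character(muts$ref[tri]))
    alt <- toupper(as.character(muts$alt[tri]))
    t3 <- substr(ctx[tri], 3, 3)
    t1 <- substr(ctx[tri], 1, 1)
    is_cpg <- ref == "C" & alt == "T" & t3 == "G"
    is_apo <- ref == "C" & alt %in% c("T", "G") & t1 == "T" & t3 %in% c("A", "T")
    lab <- rep("other", sum(tri))
    lab[is_apo] <- "APOBEC"
    lab[is_cpg] <- "CpG>T"   # precedence over APOBEC
    out[tri] <- lab
  }
  out
}

#' Clonal CpG>T burden per megabase at risk
#'
#' Counts clonal CpG>T mutations corrected for copy number and multiplicity:
#' each mutation contributes `2 * multiplicity / total_cn`, i.e. one count
#' when it arose on a diploid complement of at-risk sites and proportionally
#' less when it arose after the at-risk exposure had been amplified. The sum
#' is divided by the megabases of CpG sites covered.
#'
#' @param ann Annotated mutation table ([annotate_mutations()]) with a
#'   `context` column.
#' @param covered_cpg_mb Megabases of CpG sites at risk (> 0).
#' @return Burden in clonal CpG>T mutations per Mb.
#' @export
count_clock_mutations <- function(ann, covered_cpg_mb) {
  if (covered_cpg_mb <= 0) stop("covered_cpg_mb must be > 0")
  i <- !is.na(ann$clonal) & ann$clonal & classify_context(ann) == "CpG>T"
  sum(2 * ann$map_multiplicity[i] / pmax(ann$total_cn[i], 1)) / covered_cpg_mb
}

#' Fit the cohort CpG>T clock rate
#'
#' Robust zero-intercept regression of clonal CpG>T burden per Mb on age at
#' diagnosis: each tumor's slope is `burden / age`; the top and bottom 5\% of
#' per-tumor slopes are removed; the rate is the zero-intercept least-squares
#' slope on the retained tumors. The interquartile range of retained slopes
#' is reported alongside.
#'
#' @param burdens Per-tumor clonal CpG>T burden per Mb
#'   ([count_clock_mutations()]).
#' @param ages Ages at diagnosis (years).
#' @param trim Fraction trimmed from each tail of the per-tumor slopes
#'   (default 0.05).
#' @return List of class `aging_rate_fit`: `rate` (CpG>T per Mb at risk per
#'   year), `slopes`, `retained`, `iqr`, `trim`.
#' @export
fit_aging_rate <- function(burdens, ages, trim = 0.05) {
  stopifnot(length(burdens) == length(ages), all(ages > 0))
  slopes <- burdens / ages
  n <- length(slopes)
  if (n < 20) {
    warning("fewer than 20 tumors: clock rate fitted without trimming")
    retained <- rep(TRUE, n)
  } else {
    k <- floor(trim * n)
    ord <- order(slopes)
    drop <- c(utils::head(ord, k), utils::tail(ord, k))
    retained <- !(seq_len(n) %in% drop)
  }
  rate <- sum(ages[retained] * burdens[retained]) / sum(ages[retained]^2)
  out <- list(rate = rate, slopes = slopes, retained = retained,
              iqr = unname(stats::quantile(slopes[retained], c(0.25, 0.75))),
              trim = trim)
  class(out) <- "aging_rate_fit"
  out
}

#' @export
print.aging_rate_fit <- function(x, ...) {
  cat(sprintf("CpG>T clock: %.3f mutations/Mb/year (IQR of per-tumor slopes %.3f-%.3f, n = %d retained of %d)\n",
              x$rate, x$iqr[1], x$iqr[2], sum(x$retained), length(x$slopes)))
  invisible(x)
}

#' Convert a molecular-time posterior to years before diagnosis
#'
#' With a clock rate `rate` (CpG>T/Mb/year) and a tumor whose clonal CpG>T
#' burden at diagnosis is `burden`, an event at molecular time pi occurred
#' `burden * (1 - pi) / rate` years before diagnosis, truncated to
#' `[0, age]`. The transformation is applied bin-wise to the pi posterior
#' (computed on the CpG>T-only pi scale).
#'
#' @param pi A [pi_dist] for the event (CpG>T-only scale) or a single pi value.
#' @param burden Tumor clonal CpG>T burden per Mb at diagnosis.
#' @param rate Cohort (or per-tumor) clock rate, > 0.
#' @param age Age at diagnosis (years); upper truncation bound.
#' @return For a `pi_dist` input, a data.frame `years`, `prob` (descending
#'   years) with attributes `mean` and `ci`; for a scalar, the years value.
#' @export
pi_to_years <- function(pi, burden, rate, age) {
  if (rate <= 0) stop("rate must be > 0")
  if (burden <= 0) stop("tumor has no clock burden; event cannot be real-timed")
  f <- function(p) pmin(pmax(burden * (1 - p) / rate, 0), age)
  if (is.numeric(pi)) return(f(pi))
  stopifnot(inherits(pi, "pi_dist"))
  years <- f(pi$mids)
  out <- data.frame(years = years, prob = pi$prob)
  attr(out, "mean") <- sum(out$years * out$prob)
  attr(out, "ci") <- sort(f(pi$ci))
  out
}

#' Fit the WGD-to-WGT conversion model
#'
#' Whole-genome doubled (tetraploid) tumors convert to a triploid profile
#' (WGT) at a fixed annual rate, except for a fraction that never converts:
#' for an event originating `tau` years before diagnosis,
#' \deqn{P(\mathrm{WGT} \mid \tau) = (1 - f)(1 - e^{-\lambda \tau}).}
#' The two parameters are fitted by maximum likelihood on the observed
#' (years-before-diagnosis, class) pairs; 95\% confidence intervals come from
#' the profile likelihood.
#'
#' @param tau Years before diagnosis of each whole-genome event.
#' @param class Character vector, `"WGD"` (unconverted) or `"WGT"`
#'   (converted), parallel to `tau`.
#' @return List of class `conversion_fit`: `lambda` (per year), `f` (immune
#'   fraction), `loglik`, `lambda_ci`, `f_ci`.
#' @export
fit_wgd_wgt_conversion <- function(tau, class) {
  stopifnot(length(tau) == length(class), all(class %in% c("WGD", "WGT")))
  if (length(tau) < 10) warning("fewer than 10 whole-genome events: fit is fragile")
  y <- class == "WGT"
  if (all(y) || !any(y)) warning("all events are one class: boundary fit")
  nll <- function(par) {
    lambda <- par[1]; f <- par[2]
    p <- (1 - f) * (1 - exp(-lambda * tau))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(y, log(p), log1p(-p)))
  }
  fit <- stats::optim(c(0.1, 0.3), nll, method = "L-BFGS-B",
                      lower = c(1e-6, 0), upper = c(5, 0.999))
  ll <- -fit$value
  # profile-likelihood 95% CIs (chi-square_1 cutoff 3.84/2)
  prof <- function(k, grid) {
    ok <- vapply(grid, function(v) {
      g <- function(w) { par <- numeric(2); par[k] <- v; par[-k] <- w; nll(par) }
      o <- stats::optimize(g, if (k == 1) c(0, 0.999) else c(1e-6, 5))
      -o$objective >= ll - 1.92
    }, logical(1))
    range(c(fit$par[k], grid[ok]))  # always contains the MLE
  }
  lg <- seq(1e-4, max(1, 3 * fit$par[1]), length.out = 200)
  fg <- seq(0, 0.999, length.out = 200)
  out <- list(lambda = fit$par[1], f = fit$par[2], loglik = ll,
              lambda_ci = prof(1, lg), f_ci = prof(2, fg),
              n = length(tau))
  class(out) <- "conversion_fit"
  out
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf("WGD->WGT conversion: %.1f%%/year (95%% CI %.1f-%.1f), immune fraction %.0f%% (95%% CI %.0f-%.0f), n = %d\n",
              100 * x$lambda, 100 * x$lambda_ci[1], 100 * x$lambda_ci[2],
              100 * x$f, 100 * x$f_ci[1], 100 * x$f_ci[2], x$n))
  invisible(x)
}
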