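#' Cohort-level consensus ordering of events (league model)
#'
#' Combines per-tumor molecular-time posteriors of shared events into a
#' cohort-level relative-timing distribution. Each iteration subsamples
#' tumors without replacement (each tumor included independently with
#' probability `resample_fraction`, giving the stated average), draws one pi
#' value per event from each included tumor carrying it, averages them per
#' event, and rescales the per-event scores so the earliest event of the
#' iteration sits at 0 and the latest at 1. Iterations with fewer than two
#' events present are discarded. The union of per-iteration scores is the
#' final relative-timing trace; its median is the mRT point estimate.
#'
#' Draws are organised per entity (one RNG stream pass per event across
#' tumors), so the result is invariant to the input order of events and
#' tumors under the same seed.
#'
#' @param cohort A named list: one element per tumor, each a named list of
#'   [pi_dist] objects keyed by event name (tumors omit events they do not
#'   carry). Typically built from [assemble_patient_timing()] results.
#' @param events Character vector of event names to rank (default: all events
#'   seen in the cohort).
#' @param n_iterations Number of resampling iterations (default 200).
#' @param resample_fraction Mean inclusion fraction per iteration (default
#'   0.63).
#' @param seed Optional integer seed for the resampling.
#' @return List of class `cohort_timing`: `traces` (named list of per-event
#'   score vectors), `mrt` (named medians), `ci` (75\% interval of each
#'   trace), `prevalence`, `n_tumors`, `n_iterations`.
#' @export
league_aggregate <- function(cohort, events = NULL, n_iterations = 200L,
                             resample_fraction = 0.63, seed = NULL) {
  if (!length(cohort)) stop("empty cohort")
  if (!is.null(seed)) set.seed(seed)
  all_events <- sort(unique(unlist(lapply(cohort, names))))
  if (is.null(events)) events <- all_events
  events <- sort(intersect(events, all_events))
  if (length(events) < 2) stop("need at least two shared events to anchor the scale")
  n_t <- length(cohort)
  tumor_ids <- if (is.null(names(cohort))) as.character(seq_len(n_t)) else names(cohort)

  incl <- matrix(NA, n_t, n_iterations, dimnames = list(tumor_ids, NULL))
  for (ti in order(tumor_ids))
    incl[ti, ] <- stats::runif(n_iterations) < resample_fraction
  # per-event draw matrices, tumors x iterations (per-entity streams in
  # sorted-id order: the draws for an entity do not depend on input order)
  draws <- lapply(events, function(e) {
    m <- matrix(NA_real_, n_t, n_iterations)
    for (ti in order(tumor_ids)) {
      d <- cohort[[ti]][[e]]
      if (!is.null(d)) m[ti, ] <- pi_sample(d, n_iterations)
    }
    m
  })
  names(draws) <- events

  scores <- matrix(NA_real_, length(events), n_iterations,
                   dimnames = list(events, NULL))
  for (k in seq_along(events)) {
    m <- draws[[k]]
    carrier <- !is.na(m[, 1])
    use <- incl & carrier
    cnt <- colSums(use)
    sm <- colSums(ifelse(use, m, 0))
    scores[k, ] <- ifelse(cnt > 0, sm / cnt, NA_real_)
  }
  # per-iteration rescale to [0, 1] over the events present
  keep <- logical(n_iterations)
  for (j in seq_len(n_iterations)) {
    s <- scores[, j]
    ok <- !is.na(s)
    if (sum(ok) < 2 || diff(range(s[ok])) == 0) next
    scores[ok, j] <- (s[ok] - min(s[ok])) / (max(s[ok]) - min(s[ok]))
    keep[j] <- TRUE
  }
  scores <- scores[, keep, drop = FALSE]
  traces <- lapply(events, function(e) {
    v <- scores[e, ]
    v[!is.na(v)]
  })
  names(traces) <- events
  prev <- vapply(events, function(e)
    mean(vapply(cohort, function(tu) !is.null(tu[[e]]), logical(1))), numeric(1))
  out <- list(
    traces = traces,
    mrt = vapply(traces, stats::median, numeric(1)),
    ci = t(vapply(traces, stats::quantile, numeric(2), probs = c(0.125, 0.875))),
    prevalence = prev,
    n_tumors = n_t,
    n_iterations = n_iterations)
  class(out) <- "cohort_timing"
  out
}

#' @export
print.cohort_timing <- function(x, ...) {
  ord <- order(x$mrt)
  cat(sprintf("Cohort relative timing (%d tumors, %d iterations):\n",
              x$n_tumors, x$n_iterations))
  for (e in names(x$mrt)[ord])
    cat(sprintf("  %-20s mRT %.2f  [%.2f, %.2f]  prevalence %.0f%%\n",
                e, x$mrt[e], x$ci[e, 1], x$ci[e, 2], 100 * x$prevalence[e]))
  invisible(x)
}

#' Compare event timing between two cohorts
#'
#' Runs paired league-model iterations in each cohort and, per iteration,
#' takes the difference of the rescaled relative-timing scores for each
#' shared event. The one-way p value is the proportion of difference-trace
#' samples greater than zero (exact zeros counted half); the two-way p value is
#' `1 - 2 * |0.5 - p_one_way|`; q values are Benjamini-Hochberg across the
#' compared events.
#'
#' @param cohort_a,cohort_b Cohorts as in [league_aggregate()].
#' @param events Events to compare (default: all shared).
#' @param min_cases Minimum carriers required in each cohort (default 3).
#' @inheritParams league_aggregate
#' @return Data.frame of class `timing_comparison`: `event`, `delta_median`
#'   (cohort A minus cohort B), `p_one_way`, `p_two_way`, `q`, carrier counts;
#'   the per-event difference traces are in `attr(, "delta_traces")`. Zero
#'   rows (with a diagnostic attribute) when no event passes the floor.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, events = NULL, min_cases = 3L,
                            n_iterations = 200L, resample_fraction = 0.63,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  carriers <- function(cohort, e)
    sum(vapply(cohort, function(tu) !is.null(tu[[e]]), logical(1)))
  shared <- intersect(unique(unlist(lapply(cohort_a, names))),
                      unique(unlist(lapply(cohort_b, names))))
  if (!is.null(events)) shared <- intersect(shared, events)
  shared <- shared[vapply(shared, function(e)
    carriers(cohort_a, e) >= min_cases && carriers(cohort_b, e) >= min_cases,
    logical(1))]
  out0 <- structure(
    data.frame(event = character(), delta_median = numeric(),
               p_one_way = numeric(), p_two_way = numeric(), q = numeric()),
    class = c("timing_comparison", "data.frame"))
  if (length(shared) < 1) {
    attr(out0, "diagnostic") <- "no shared events meet the prevalence floor"
    return(out0)
  }
  la <- league_aggregate_scores(cohort_a, shared, n_iterations, resample_fraction)
  lb <- league_aggregate_scores(cohort_b, shared, n_iterations, resample_fraction)
  keep <- la$keep & lb$keep
  res <- lapply(shared, function(e) {
    dt <- la$scores[e, keep] - lb$scores[e, keep]
    dt <- dt[!is.na(dt)]
    # ties (exact zeros) split evenly so that a degenerate all-zero trace is
    # null (p1 = 0.5), not significant
    p1 <- if (length(dt)) mean(dt > 0) + 0.5 * mean(dt == 0) else NA_real_
    list(delta = dt, p1 = p1)
  })
  names(res) <- shared
  p1 <- vapply(res, `[[`, numeric(1), "p1")
  p2 <- 1 - 2 * abs(0.5 - p1)
  out <- data.frame(
    event = shared,
    delta_median = vapply(res, function(r)
      if (length(r$delta)) stats::median(r$delta) else NA_real_, numeric(1)),
    p_one_way = p1,
    p_two_way = p2,
    q = bh_fdr(p2),
    n_a = vapply(shared, function(e) carriers(cohort_a, e), numeric(1)),
    n_b = vapply(shared, function(e) carriers(cohort_b, e), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "delta_traces") <- lapply(res, `[[`, "delta")
  class(out) <- c("timing_comparison", "data.frame")
  out
}

# one league pass returning the raw per-iteration score matrix (no trace union)
league_aggregate_scores <- function(cohort, events, n_iterations,
                                    resample_fraction) {
  n_t <- length(cohort)
  incl <- matrix(stats::runif(n_t * n_iterations) < resample_fraction,
                 n_t, n_iterations)
  scores <- matrix(NA_real_, length(events), n_iterations,
                   dimnames = list(events, NULL))
  for (k in seq_along(events)) {
    e <- events[k]
    m <- matrix(NA_real_, n_t, n_iterations)
    for (ti in seq_len(n_t)) {
      d <- cohort[[ti]][[e]]
      if (!is.null(d)) m[ti, ] <- pi_sample(d, n_iterations)
    }
    carrier <- !is.na(m[, 1])
    use <- incl & carrier
    cnt <- colSums(use)
    sm <- colSums(ifelse(use, m, 0))
    scores[k, ] <- ifelse(cnt > 0, sm / cnt, NA_real_)
  }
  keep <- logical(n_iterations)
  for (j in seq_len(n_iterations)) {
    s <- scores[, j]
    ok <- !is.na(s)
    if (sum(ok) < 2 || diff(range(s[ok])) == 0) next
    scores[ok, j] <- (s[ok] - min(s[ok])) / (max(s[ok]) - min(s[ok]))
    keep[j] <- TRUE
  }
  list(scores = scores, keep = keep)
}

#' Benjamini-Hochberg q values
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return q values, monotone in `p`; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
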