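#' Time a chromosomal gain from multiplicity-stratified mutation counts
#'
#' A clonal mutation on a region that was later gained is carried on every
#' copy descended from its chromatid: mutations predating the gain appear at
#' high multiplicity, mutations after it at multiplicity one. If `d` of the
#' pre-gain copies were duplicated, `u` were not, and the region has `C`
#' total copies afterwards, then a gain at molecular time `t` leaves an
#' expected fraction
#' \deqn{\phi(t) = \frac{d\,t}{(d+u)\,t + C(1-t)}}
#' of clonal mutations at high multiplicity. With a uniform prior on
#' \eqn{\phi}, observing `n_hi` high-multiplicity and `n_1` multiplicity-one
#' clonal mutations gives the conjugate posterior Beta(`n_hi`+1, `n_1`+1) on
#' \eqn{\phi} (truncated to its attainable range \eqn{[0, d/(d+u)]}), which is
#' pushed forward to molecular time through the inverse of \eqn{\phi(t)}. The
#' posterior is computed deterministically on a fine grid in `t` carrying the
#' Jacobian \eqn{|d\phi/dt|}. Counts may be non-integer (power weighting).
#'
#' @param n_hi Count (or power-weighted mass) of high-multiplicity clonal
#'   mutations in the region.
#' @param n_1 Count of multiplicity-one clonal mutations.
#' @param d Pre-gain copies that were duplicated (>= 1).
#' @param u Pre-gain copies not duplicated.
#' @param C Post-gain total copy number (> d + u).
#' @param nbins Histogram bins of the returned posterior.
#' @param grid_n Fine-grid resolution used for the computation.
#' @return A [pi_dist] over the molecular time of the gain. With
#'   `n_hi = n_1 = 0` the event is unpowered and a uniform posterior is
#'   returned.
#' @examples
#' time_segment_gain(0, 20, d = 1, u = 0, C = 2)$mean   # early gain
#' time_segment_gain(20, 0, d = 1, u = 0, C = 2)$mean   # late gain
#' @export
time_segment_gain <- function(n_hi, n_1, d, u, C, nbins = 100L, grid_n = 2001L) {
  if (d < 1) stop("d must be >= 1")
  if (C <= d + u) stop("C must exceed d + u (the region must have been gained)")
  if (n_hi < 0 || n_1 < 0) stop("counts must be non-negative")
  if (n_hi == 0 && n_1 == 0) return(pi_uniform(nbins, flags = "unpowered"))
  t <- seq(1 / (2 * grid_n), 1 - 1 / (2 * grid_n), length.out = grid_n)
  b <- (d + u - C)  # negative
  phi <- d * t / (b * t + C)
  jac <- d * C / (b * t + C)^2
  logw <- n_hi * log(phi) + n_1 * log1p(-phi) + log(jac)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  mids <- pmin(floor(t * nbins) + 1L, nbins)
  prob <- vapply(seq_len(nbins), function(j) sum(w[mids == j]), numeric(1))
  pi_dist(prob, mean = sum(w * t))
}

#' Time a whole-genome event by aggregating doubled arms
#'
#' Each doubled chromosome arm carries an independent record of the same
#' event: the joint posterior over the event's molecular time is the product
#' of the per-arm count likelihoods evaluated on a common time grid (the prior
#' Jacobian is taken from the copy configuration carrying the most mutations).
#' Arms with identical copy configuration contribute exactly as pooled counts
#' would; the credible interval narrows as informative arms accumulate. Arms
#' whose individual timings disagree strongly (range of per-arm posterior
#' means > 0.5) yield a `"discordant_arms"` QC flag.
#'
#' @param arm_counts A data.frame (or list of lists) with one row per doubled
#'   arm: columns `n_hi`, `n_1`, `d`, `u`, `C`.
#' @inheritParams time_segment_gain
#' @return A [pi_dist] for the whole-genome event.
#' @export
time_wgd <- function(arm_counts, nbins = 100L, grid_n = 2001L) {
  ac <- as.data.frame(arm_counts)
  if (!nrow(ac)) return(pi_uniform(nbins, flags = "no_doubled_arms"))
  informative <- ac$n_hi + ac$n_1 > 0
  if (!any(informative)) return(pi_uniform(nbins, flags = "unpowered"))
  ac <- ac[informative, , drop = FALSE]
  t <- seq(1 / (2 * grid_n), 1 - 1 / (2 * grid_n), length.out = grid_n)
  logw <- numeric(grid_n)
  for (i in seq_len(nrow(ac))) {
    b <- ac$d[i] + ac$u[i] - ac$C[i]
    phi <- ac$d[i] * t / (b * t + ac$C[i])
    logw <- logw + ac$n_hi[i] * log(phi) + ac$n_1[i] * log1p(-phi)
  }
  dom <- which.max(ac$n_hi + ac$n_1)
  b <- ac$d[dom] + ac$u[dom] - ac$C[dom]
  logw <- logw + log(ac$d[dom] * ac$C[dom] / (b * t + ac$C[dom])^2)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  mids <- pmin(floor(t * nbins) + 1L, nbins)
  prob <- vapply(seq_len(nbins), function(j) sum(w[mids == j]), numeric(1))
  flags <- character()
  if (nrow(ac) > 1) {
    per_arm <- vapply(seq_len(nrow(ac)), function(i)
      time_segment_gain(ac$n_hi[i], ac$n_1[i], ac$d[i], ac$u[i], ac$C[i],
                        nbins = nbins, grid_n = 501L)$mean, numeric(1))
    if (diff(range(per_arm)) > 0.5) flags <- "discordant_arms"
  }
  pi_dist(prob, mean = sum(w * t), flags = flags)
}

#' Time a driver point mutation against the gain of its segment
#'
#' A clonal driver mutation with multiplicity above one on a gained segment
#' must predate the gain: its molecular time is uniform on `[0, t_gain]`,
#' marginalized over the gain's posterior. A multiplicity-one driver on a
#' segment gained as a clean duplication (no non-duplicated pre-gain copies)
#' must postdate the gain: uniform on `[t_gain, 1]`. A clonal driver with no
#' informative copy context is assigned a uniform posterior; a subclonal
#' driver a point mass at 1.
#'
#' @param annotation A `mut_annotation` from [annotate_mutation()].
#' @param gain A [pi_dist] for the segment's gain, or `NULL` when the segment
#'   carries no timed gain.
#' @param u Number of pre-gain copies of the segment that were not duplicated
#'   (0 for a clean duplication; when `u > 0` a multiplicity-one mutation may
#'   also predate the gain, so no post-gain constraint is applied).
#' @param nbins Histogram bins.
#' @return A [pi_dist].
#' @export
time_snv_driver <- function(annotation, gain = NULL, u = 0, nbins = 100L) {
  stopifnot(inherits(annotation, "mut_annotation"))
  if (isTRUE(annotation$unpowered)) return(pi_uniform(nbins, flags = "unpowered"))
  if (!classify_clonal(annotation)) return(pi_delta_one(nbins))
  if (is.null(gain)) return(pi_uniform(nbins))
  g <- rebin_pi(gain, nbins)
  mids <- (seq_len(nbins) - 0.5) / nbins
  if (annotation$map_multiplicity > 1) {
    # x ~ U(0, T), T ~ gain posterior: f(x) = E[ 1(x < T) / T ]
    f <- rev(cumsum(rev(g$prob / mids)))
  } else if (u == 0) {
    # x ~ U(T, 1): f(x) = E[ 1(x > T) / (1 - T) ]
    f <- cumsum(g$prob / pmax(1 - mids, 1 / nbins))
  } else {
    return(pi_uniform(nbins))
  }
  pi_dist(f)
}

rebin_pi <- function(d, nbins) {
  if (length(d$prob) == nbins) return(d)
  x <- d$mids
  j <- pmin(floor(x * nbins) + 1L, nbins)
  pi_dist(vapply(seq_len(nbins), function(k) sum(d$prob[j == k]), numeric(1)),
          mean = d$mean, flags = d$flags)
}

#' Call arm-level copy events from a segment table
#'
#' An arm is assigned the copy state covering the majority of its length; an
#' arm gain/loss is called when at least half of the arm length lies above or
#' below the one-copy-per-allele baseline.
#'
#' @param segments Segment data.frame (`chrom_arm`, `start`, `end`,
#'   `major_cn`, `minor_cn`).
#' @return A data.frame per arm: modal `major_cn`, `minor_cn`, and the
#'   fractions of arm length with major above 1, both alleles >= 2, and an
#'   allele lost.
#' @export
call_arm_events <- function(segments) {
  arms <- split(segments, segments$chrom_arm)
  out <- lapply(names(arms), function(a) {
    s <- arms[[a]]
    len <- s$end - s$start
    state <- paste(s$major_cn, s$minor_cn)
    modal <- names(sort(tapply(len, state, sum), decreasing = TRUE))[1]
    mm <- as.integer(strsplit(modal, " ")[[1]])
    data.frame(chrom_arm = a, major_cn = mm[1], minor_cn = mm[2],
               frac_gain = sum(len[s$major_cn + s$minor_cn > 2]) / sum(len),
               frac_both_amp = sum(len[s$major_cn >= 2 & s$minor_cn >= 2]) / sum(len),
               frac_loss = sum(len[s$minor_cn == 0]) / sum(len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# copy configuration (d, u, C) of the gain implied by an arm's modal state,
# assuming a 1:1 ancestral state; NULL when the arm carries no timeable gain
gain_config <- function(major_cn, minor_cn) {
  if (major_cn == 2 && minor_cn == 2) return(list(d = 2, u = 0, C = 4))  # doubling
  if (major_cn == 2 && minor_cn == 1) return(list(d = 1, u = 1, C = 3))  # single gain
  if (major_cn == 2 && minor_cn == 0) return(list(d = 1, u = 0, C = 2))  # loss + doubling
  NULL
}

#' Assemble the full within-tumor timing of one tumor
#'
#' Produces the per-tumor event list with molecular-time (pi) posteriors:
#' arm gains and whole-genome events are timed from multiplicity-stratified
#' clonal mutation counts (power-weighted by 1/P(detect)); losses whose
#' remaining allele was subsequently doubled are constrained before that
#' doubling; other losses and untimeable clonal events get uniform
#' posteriors; clonal driver mutations are constrained by the gain status of
#' their segment; subclonal events are point masses at 1.
#'
#' The pi value of an event in each joint posterior sample is the fraction of
#' clonal point-mutation mass — each mutation weighted by
#' 2 x multiplicity / total copies, i.e. normalized per megabase at risk at
#' its time of origin — that falls before the event's sampled time, so that 0
#' and 1 correspond to the first and last clonal events of the tumor.
#'
#' @param ann Annotated mutation table from [annotate_mutations()]; driver
#'   mutations are rows with a non-empty `gene` column.
#' @param segments Segment table for the tumor.
#' @param n_samples Number of joint posterior samples (default 1000).
#' @param nbins Histogram bins of the output posteriors.
#' @param contexts Which mutation contexts enter the clonal mass that defines
#'   pi: `"all"` (default) or `"CpG>T"` for the clock-only scale used by
#'   real-time conversion.
#' @param mass_mode Whether the pi mass uses all clonal mutations (`"all"`,
#'   default) or only those on copy states where pre/post-gain status is
#'   identifiable (`"timeable"`).
#' @param min_clonal Minimum number of clonal mutations required; below this
#'   an empty result with a diagnostic attribute is returned.
#' @return A data.frame of class `patient_timing` with one row per event:
#'   `event`, `class`, `locus`, `pi_mean`, `ci_lo`, `ci_hi`, `flags`, and the
#'   [pi_dist] objects in the list column `pi`.
#' @export
assemble_patient_timing <- function(ann, segments, n_samples = 1000L,
                                    nbins = 100L, contexts = c("all", "CpG>T"),
                                    mass_mode = c("all", "timeable"),
                                    min_clonal = 1L) {
  contexts <- match.arg(contexts)
  mass_mode <- match.arg(mass_mode)
  empty <- structure(
    data.frame(event = character(), class = character(), locus = character(),
               pi_mean = numeric(), ci_lo = numeric(), ci_hi = numeric(),
               flags = character(), stringsAsFactors = FALSE),
    class = c("patient_timing", "data.frame"))

  usable <- !ann$unpowered & !is.na(ann$clonal)
  clonal <- usable & ann$clonal
  if (sum(clonal) < min_clonal) {
    attr(empty, "diagnostic") <- "no clonal mutations; tumor cannot be timed"
    return(empty)
  }

  arm_tab <- call_arm_events(segments)
  wge <- call_whole_genome_event(segments)

  # per-arm weighted multiplicity-stratified counts (excluding drivers, which
  # are events themselves)
  w <- 1 / pmax(ann$p_detect, 0.1)
  is_driver <- if (is.null(ann$gene)) rep(FALSE, nrow(ann))
               else !is.na(ann$gene) & ann$gene != ""
  counts_for_arm <- function(arm) {
    i <- clonal & ann$chrom_arm == arm & !is_driver
    cfg <- gain_config(arm_tab$major_cn[arm_tab$chrom_arm == arm],
                       arm_tab$minor_cn[arm_tab$chrom_arm == arm])
    if (is.null(cfg)) return(NULL)
    hi <- i & ann$map_multiplicity >= 2
    c(cfg, list(n_hi = sum(w[hi]), n_1 = sum(w[i & !hi])))
  }

  # arms pooled into the whole-genome event: doubled (and loss-then-doubled)
  # arms always; in a triploid-profile (WGT) genome the 2:1 arms are the
  # per-arm record of the original doubling and are pooled as well
  pool_states <- if (!wge$called) character()
                 else if (wge$wge_call == "WGT") c("2 1", "2 2", "2 0")
                 else c("2 2", "2 0")

  events <- list()   # name -> list(class, locus, dist, before/after constraint)
  doubled_arm_counts <- list()
  for (k in seq_len(nrow(arm_tab))) {
    a <- arm_tab[k, ]
    cfg <- gain_config(a$major_cn, a$minor_cn)
    state <- paste(a$major_cn, a$minor_cn)
    if (state %in% setdiff(pool_states, "2 0")) {
      cc <- counts_for_arm(a$chrom_arm)
      doubled_arm_counts[[a$chrom_arm]] <- as.data.frame(cc)
    } else if (state %in% c("2 1", "2 2")) {
      cc <- counts_for_arm(a$chrom_arm)
      events[[paste0("gain_", a$chrom_arm)]] <- list(
        class = "arm_gain", locus = a$chrom_arm,
        dist = time_segment_gain(cc$n_hi, cc$n_1, cc$d, cc$u, cc$C, nbins = nbins),
        u = cc$u)
    } else if (state == "2 0") {
      # remaining allele doubled: time the doubling, constrain the loss before it
      cc <- counts_for_arm(a$chrom_arm)
      if ("2 0" %in% pool_states) {
        doubled_arm_counts[[a$chrom_arm]] <- as.data.frame(cc)
        events[[paste0("loss_", a$chrom_arm)]] <- list(
          class = "arm_loss", locus = a$chrom_arm, dist = NULL,
          before = "wgd")
      } else {
        gd <- time_segment_gain(cc$n_hi, cc$n_1, cc$d, cc$u, cc$C, nbins = nbins)
        events[[paste0("gain_", a$chrom_arm)]] <- list(
          class = "arm_gain", locus = a$chrom_arm, dist = gd, u = 0)
        events[[paste0("loss_", a$chrom_arm)]] <- list(
          class = "arm_loss", locus = a$chrom_arm, dist = NULL,
          before = paste0("gain_", a$chrom_arm))
      }
    } else if (state %in% c("1 0")) {
      events[[paste0("loss_", a$chrom_arm)]] <- list(
        class = "arm_loss", locus = a$chrom_arm, dist = pi_uniform(nbins))
    } else if (a$major_cn == 0 && a$minor_cn == 0) {
      events[[paste0("homdel_", a$chrom_arm)]] <- list(
        class = "homozygous_deletion", locus = a$chrom_arm,
        dist = pi_uniform(nbins))
    }
  }
  if (wge$called && length(doubled_arm_counts)) {
    events[["wgd"]] <- list(
      class = "wgd", locus = "genome",
      dist = time_wgd(do.call(rbind, doubled_arm_counts), nbins = nbins))
  }

  # driver point mutations
  for (i in which(is_driver)) {
    gene <- ann$gene[i]
    if (ann$unpowered[i]) next
    a <- annotation_from_row(ann[i, ])
    arm <- ann$chrom_arm[i]
    arm_row <- arm_tab[arm_tab$chrom_arm == arm, ]
    gain_name <- if (nrow(arm_row) &&
                     paste(arm_row$major_cn, arm_row$minor_cn) %in% pool_states)
      "wgd" else paste0("gain_", arm)
    if (!is.null(events[[gain_name]]) || gain_name == "wgd" && !is.null(events[["wgd"]])) {
      gd <- events[[gain_name]]$dist
      u <- gain_config(arm_row$major_cn, arm_row$minor_cn)$u
      if (!classify_clonal(a)) {
        events[[gene]] <- list(class = "driver_snv", locus = arm, dist = pi_delta_one(nbins))
      } else if (a$map_multiplicity > 1) {
        events[[gene]] <- list(class = "driver_snv", locus = arm, dist = NULL,
                               before = gain_name)
      } else if (u == 0) {
        events[[gene]] <- list(class = "driver_snv", locus = arm, dist = NULL,
                               after = gain_name)
      } else {
        events[[gene]] <- list(class = "driver_snv", locus = arm,
                               dist = pi_uniform(nbins))
      }
    } else {
      events[[gene]] <- list(class = "driver_snv", locus = arm,
                             dist = if (classify_clonal(a)) pi_uniform(nbins)
                                    else pi_delta_one(nbins))
    }
  }

  if (!length(events)) {
    attr(empty, "diagnostic") <- "no timeable events"
    return(empty)
  }

  # ---- joint sampling -------------------------------------------------------
  # sample event times respecting pairwise constraints, then convert each
  # sampled time to a pi value: the weighted fraction of clonal mutation mass
  # occurring before it
  nm <- names(events)
  Tmat <- matrix(NA_real_, n_samples, length(nm), dimnames = list(NULL, nm))
  for (e in nm) {
    ev <- events[[e]]
    if (!is.null(ev$dist) && is.null(ev$before) && is.null(ev$after))
      Tmat[, e] <- pi_sample(ev$dist, n_samples)
  }
  for (e in nm) {
    ev <- events[[e]]
    if (!is.null(ev$before)) Tmat[, e] <- stats::runif(n_samples) * Tmat[, ev$before]
    if (!is.null(ev$after))
      Tmat[, e] <- Tmat[, ev$after] + stats::runif(n_samples) * (1 - Tmat[, ev$after])
  }

  # clonal mutation mass: sampled origin times per joint sample
  mi <- which(clonal)
  if (contexts == "CpG>T" && !is.null(ann$context))
    mi <- mi[classify_context(ann[mi, ]) == "CpG>T"]
  keep_arm <- ann$chrom_arm[mi]
  arm_state <- paste(arm_tab$major_cn, arm_tab$minor_cn)[match(keep_arm, arm_tab$chrom_arm)]
  timeable <- arm_state %in% c("2 1", "2 2", "2 0")
  if (mass_mode == "timeable") { mi <- mi[timeable]; keep_arm <- keep_arm[timeable]
                                 arm_state <- arm_state[timeable]; timeable <- timeable[timeable] }
  if (!length(mi)) {
    attr(empty, "diagnostic") <- "no clonal mutation mass on the requested contexts"
    return(empty)
  }
  mw <- 2 * ann$map_multiplicity[mi] / pmax(ann$total_cn[mi], 1)
  Mt <- matrix(stats::runif(length(mi) * n_samples), length(mi), n_samples)
  for (j in seq_along(mi)) {
    st <- arm_state[j]
    if (is.na(st) || !timeable[j]) next
    gname <- if (!is.null(doubled_arm_counts[[keep_arm[j]]])) "wgd"
             else paste0("gain_", keep_arm[j])
    if (!gname %in% nm) next
    tg <- Tmat[, gname]
    cfg <- gain_config_from_state(st)
    if (ann$map_multiplicity[mi[j]] >= 2) {
      Mt[j, ] <- Mt[j, ] * tg                       # pre-gain
    } else if (cfg$u == 0) {
      Mt[j, ] <- tg + Mt[j, ] * (1 - tg)            # post-gain
    }                                               # else: ambiguous, uniform
  }
  total_w <- sum(mw)
  pi_of <- function(tv) as.vector(crossprod(Mt < rep(tv, each = nrow(Mt)), mw)) / total_w

  rows <- lapply(nm, function(e) {
    ev <- events[[e]]
    if (!is.null(ev$dist) && is_delta_one(ev$dist)) {
      d <- pi_delta_one(nbins)
    } else {
      d <- bin_pi(pi_of(Tmat[, e]), nbins,
                  flags = if (!is.null(ev$dist)) ev$dist$flags else character())
    }
    list(event = e, class = ev$class, locus = ev$locus, dist = d)
  })
  out <- data.frame(
    event = vapply(rows, `[[`, "", "event"),
    class = vapply(rows, `[[`, "", "class"),
    locus = vapply(rows, `[[`, "", "locus"),
    pi_mean = vapply(rows, function(r) r$dist$mean, numeric(1)),
    ci_lo = vapply(rows, function(r) r$dist$ci[1], numeric(1)),
    ci_hi = vapply(rows, function(r) r$dist$ci[2], numeric(1)),
    flags = vapply(rows, function(r) paste(r$dist$flags, collapse = ","), ""),
    stringsAsFactors = FALSE)
  out$pi <- lapply(rows, `[[`, "dist")
  attr(out, "event_samples") <- Tmat
  class(out) <- c("patient_timing", "data.frame")
  out
}

gain_config_from_state <- function(state) {
  mm <- as.integer(strsplit(state, " ")[[1]])
  gain_config(mm[1], mm[2])
}

annotation_from_row <- function(row) {
  out <- list(map_multiplicity = row$map_multiplicity, ccf_mean = row$ccf_mean,
              ccf_map = row$ccf_map, p_clonal = row$p_clonal,
              clonal = row$clonal, unpowered = row$unpowered,
              multiplicity_posterior = NULL, ccf_posterior = NULL)
  class(out) <- "mut_annotation"
  out
}

#' Time HPV integration sites like mutations
#'
#' Pre-extracted breakpoint read support (variant-like and reference-like
#' counts at each integration site) is annotated with [annotate_mutation()]
#' and timed against the gain of its local copy-number segment with
#' [time_snv_driver()]. Because APOBEC-context mutations cluster near
#' integration sites, they are removed from the local mutation counts before
#' the gain is timed. When several sites are timed for one participant, the
#' site with the earliest timing estimate (smallest posterior mean pi, i.e.
#' earliest in real time for a given tumor clock) is marked representative.
#'
#' @param support Data.frame of integration sites: `site_id`, `chrom_arm`,
#'   `pos`, `alt_count`, `ref_count`.
#' @param ann Annotated mutation table of the tumor (for local timing counts).
#' @param segments Segment table.
#' @param purity Sample purity.
#' @param nbins Histogram bins.
#' @return A data.frame: `site_id`, `pi_mean`, `representative`, with a list
#'   column `pi` of [pi_dist] objects. Zero rows when no site has coverage.
#' @export
time_hpv_integration <- function(support, ann, segments, purity, nbins = 100L) {
  keep <- support$alt_count + support$ref_count > 0
  support <- support[keep, , drop = FALSE]
  if (!nrow(support))
    return(data.frame(site_id = character(), pi_mean = numeric(),
                      representative = logical()))
  arm_tab <- call_arm_events(segments)
  w <- 1 / pmax(ann$p_detect, 0.1)
  apobec <- classify_context(ann) == "APOBEC"
  dists <- vector("list", nrow(support))
  for (i in seq_len(nrow(support))) {
    arm <- support$chrom_arm[i]
    at <- arm_tab[arm_tab$chrom_arm == arm, ]
    seg <- segments[segments$chrom_arm == arm & segments$start <= support$pos[i] &
                      segments$end > support$pos[i], ]
    major <- if (nrow(seg)) seg$major_cn[1] else 1L
    minor <- if (nrow(seg)) seg$minor_cn[1] else 1L
    a <- annotate_mutation(support$alt_count[i], support$ref_count[i], purity,
                           major, minor)
    cfg <- gain_config(at$major_cn, at$minor_cn)
    gain <- NULL
    u <- 0
    if (!is.null(cfg)) {
      j <- !ann$unpowered & ann$clonal & ann$chrom_arm == arm & !apobec
      hi <- j & ann$map_multiplicity >= 2
      gain <- time_segment_gain(sum(w[hi]), sum(w[j & !hi]),
                                cfg$d, cfg$u, cfg$C, nbins = nbins)
      u <- cfg$u
    }
    dists[[i]] <- time_snv_driver(a, gain, u = u, nbins = nbins)
  }
  out <- data.frame(site_id = support$site_id,
                    pi_mean = vapply(dists, function(d) d$mean, numeric(1)),
                    stringsAsFactors = FALSE)
  out$representative <- seq_len(nrow(out)) == which.min(out$pi_mean)
  out$pi <- dists
  out
}
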