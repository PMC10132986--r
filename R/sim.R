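#' Configuration of a synthetic tumor cohort
#'
#' Defines the generative conditions of a simulated cohort with fully known
#' ground truth: clonal mutations accrue linearly over the patient's life on
#' the lineage copies present at the time (so mutations predating a gain are
#' carried at the post-gain copy count), read counts are purity-diluted
#' binomial draws, CpG>T clock mutations accrue at `clock_rate` per Mb of
#' covered CpG sites per year, arm-level and whole-genome copy events occur
#' with configured prevalence and timing windows, and whole-genome doublings
#' convert to triploid profiles at a fixed annual rate with a never-converting
#' (immune) fraction.
#'
#' @param n_tumors Number of tumors (>= 1).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @param coverage_mean Mean sequencing depth (> 0).
#' @param purity_range Range of tumor purity, in (0, 1].
#' @param clock_rate Clonal CpG>T mutations per Mb at risk per year.
#' @param age_range Range of age at diagnosis (years).
#' @param covered_cpg_mb Megabases of CpG sites at risk.
#' @param event_menu Data.frame of cohort events: `name`, `class`
#'   (`"arm_gain"`, `"arm_loss"`, `"driver_snv"`, `"wgd"`), `locus`
#'   (chromosome arm, or `"genome"` for wgd), `prevalence` in `[0, 1]`,
#'   `t_lo`, `t_hi` (true molecular-time window). Defaults to
#'   [default_event_menu()].
#' @param wgd_params List: `origin_window` (years before diagnosis within
#'   which a whole-genome doubling originates), `conversion_rate` (per year,
#'   >= 0), `immune_fraction` in `[0, 1]`.
#' @param other_mut_per_year Non-clock clonal mutations accrued per year.
#' @param apobec_fraction Fraction of non-clock mutations with APOBEC context.
#' @param hpv_prevalence Fraction of tumors that are HPV positive.
#' @param subclone_prevalence Fraction of tumors carrying one subclone.
#' @param subclone_ccf CCF of the subclone.
#' @param subclone_mut_fraction Subclonal mutations as a fraction of the
#'   clonal count.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 100L,
                       seed = 1L,
                       coverage_mean = 100,
                       purity_range = c(0.4, 0.9),
                       clock_rate = 0.37,
                       age_range = c(40, 80),
                       covered_cpg_mb = 30,
                       event_menu = default_event_menu(),
                       wgd_params = list(origin_window = c(5, 35),
                                         conversion_rate = 0.11,
                                         immune_fraction = 0.35),
                       other_mut_per_year = 10,
                       apobec_fraction = 0.25,
                       hpv_prevalence = 0,
                       subclone_prevalence = 0,
                       subclone_ccf = 0.3,
                       subclone_mut_fraction = 0.3) {
  cfg <- list(n_tumors = as.integer(n_tumors), seed = as.integer(seed),
              coverage_mean = coverage_mean, purity_range = purity_range,
              clock_rate = clock_rate, age_range = age_range,
              covered_cpg_mb = covered_cpg_mb, event_menu = event_menu,
              wgd_params = wgd_params, other_mut_per_year = other_mut_per_year,
              apobec_fraction = apobec_fraction, hpv_prevalence = hpv_prevalence,
              subclone_prevalence = subclone_prevalence,
              subclone_ccf = subclone_ccf,
              subclone_mut_fraction = subclone_mut_fraction)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) stop("invalid sim_config field '", field, "': ", why)
  if (cfg$n_tumors < 1) fail("n_tumors", "must be >= 1")
  if (cfg$coverage_mean <= 0) fail("coverage_mean", "must be > 0")
  if (any(cfg$purity_range <= 0) || any(cfg$purity_range > 1))
    fail("purity_range", "must lie in (0, 1]")
  if (cfg$clock_rate < 0) fail("clock_rate", "must be >= 0")
  if (cfg$covered_cpg_mb <= 0) fail("covered_cpg_mb", "must be > 0")
  m <- cfg$event_menu
  if (!all(c("name", "class", "locus", "prevalence", "t_lo", "t_hi") %in% names(m)))
    fail("event_menu", "missing required columns")
  if (any(m$prevalence < 0 | m$prevalence > 1)) fail("event_menu", "prevalences must be in [0, 1]")
  if (any(m$t_lo > m$t_hi)) fail("event_menu", "timing windows must have t_lo <= t_hi")
  arms <- m$locus[m$class %in% c("arm_gain", "arm_loss")]
  if (length(arms) && !all(arms %in% chrom_arms()$arm)) fail("event_menu", "unknown arm locus")
  w <- cfg$wgd_params
  if (w$conversion_rate < 0) fail("wgd_params", "conversion_rate must be >= 0")
  if (w$immune_fraction < 0 || w$immune_fraction > 1)
    fail("wgd_params", "immune_fraction must be in [0, 1]")
  invisible(cfg)
}

#' Default event menu emulating head-and-neck-like driver prevalence
#'
#' Arm losses, gains, driver point mutations and a whole-genome doubling with
#' prevalences and staggered true timing windows resembling an HPV-negative
#' head and neck cohort.
#'
#' @return Event menu data.frame for [sim_config()].
#' @export
default_event_menu <- function() {
  data.frame(
    name = c("loss_9p", "TP53", "loss_3p", "loss_17p", "loss_13q",
             "gain_3q", "gain_8q", "loss_8p", "wgd"),
    class = c("arm_loss", "driver_snv", "arm_loss", "arm_loss", "arm_loss",
              "arm_gain", "arm_gain", "arm_loss", "wgd"),
    locus = c("9p", "17p", "3p", "17p", "13q", "3q", "8q", "8p", "genome"),
    prevalence = c(0.85, 0.78, 0.80, 0.54, 0.45, 0.56, 0.50, 0.63, 0.48),
    t_lo = c(0.00, 0.05, 0.05, 0.10, 0.25, 0.40, 0.45, 0.15, 0.60),
    t_hi = c(0.15, 0.25, 0.25, 0.30, 0.45, 0.60, 0.65, 0.40, 0.95),
    stringsAsFactors = FALSE)
}

#' Simulate one tumor
#'
#' Draws the tumor's events from the configured menu, lays down clonal
#' mutations uniformly over the patient's lifetime, assigns each mutation its
#' lineage copy of origin (pre-gain mutations on a duplicated copy get the
#' post-gain multiplicity), and emits purity-diluted binomial read counts at
#' Poisson depth. Uses the current RNG state; [simulate_cohort()] seeds it.
#'
#' @param config A [sim_config()].
#' @param tumor_id Identifier written into the tables.
#' @return List of class `sim_tumor`: `truth` (events with true molecular
#'   times and years before diagnosis, plus per-mutation truth columns),
#'   `mutations`, `segments`, `metadata`.
#' @export
simulate_tumor <- function(config, tumor_id = "T001") {
  validate_sim_config(config)
  arms <- chrom_arms()
  age <- stats::runif(1, config$age_range[1], config$age_range[2])
  purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  hpv <- stats::runif(1) < config$hpv_prevalence
  site <- sample(c("oral_cavity", "larynx", "oropharynx"), 1,
                 prob = if (hpv) c(0.1, 0.05, 0.85) else c(0.6, 0.3, 0.1))

  # --- events -----------------------------------------------------------------
  menu <- config$event_menu
  carried <- stats::runif(nrow(menu)) < menu$prevalence
  ev <- menu[carried, , drop = FALSE]
  ev$t_true <- stats::runif(nrow(ev), ev$t_lo, ev$t_hi)
  ev$wge_outcome <- rep(NA_character_, nrow(ev))
  wgd_row <- which(ev$class == "wgd")
  if (length(wgd_row)) {
    w <- config$wgd_params
    tau <- stats::runif(1, w$origin_window[1], min(w$origin_window[2], age))
    ev$t_true[wgd_row] <- 1 - tau / age
    immune <- stats::runif(1) < w$immune_fraction
    wait <- if (w$conversion_rate > 0) stats::rexp(1, w$conversion_rate) else Inf
    ev$wge_outcome[wgd_row] <- if (!immune && wait < tau) "WGT" else "WGD"
  }
  ev <- ev[order(ev$t_true), , drop = FALSE]
  ev$years_before_dx <- (1 - ev$t_true) * age

  # --- copy-number state per arm ---------------------------------------------
  major <- stats::setNames(rep(1L, nrow(arms)), arms$arm)
  minor <- stats::setNames(rep(1L, nrow(arms)), arms$arm)
  gain_time <- stats::setNames(rep(NA_real_, nrow(arms)), arms$arm)  # time the major allele gained
  loss_time <- stats::setNames(rep(NA_real_, nrow(arms)), arms$arm)
  for (i in seq_len(nrow(ev))) {
    cls <- ev$class[i]
    if (cls == "arm_gain") {
      a <- ev$locus[i]
      major[a] <- major[a] + 1L
      gain_time[a] <- ev$t_true[i]
    } else if (cls == "arm_loss") {
      a <- ev$locus[i]
      minor[a] <- 0L
      loss_time[a] <- ev$t_true[i]
    } else if (cls == "wgd") {
      t_w <- ev$t_true[i]
      if (ev$wge_outcome[i] == "WGD") {
        # both alleles double everywhere still 1:1; lost arms redouble the
        # surviving allele (2:0)
        dbl <- major == 1 & minor == 1
        major[dbl] <- 2L; minor[dbl] <- 2L; gain_time[dbl] <- t_w
        lost <- minor == 0 & major == 1
        major[lost] <- 2L; gain_time[lost] <- t_w
      } else {
        # WGT: early doubling followed by losses leaves most arms 2:1
        dbl <- major == 1 & minor == 1
        major[dbl] <- 2L; gain_time[dbl] <- t_w
        lost <- minor == 0 & major == 1
        major[lost] <- 2L; gain_time[lost] <- t_w
      }
    }
  }

  segments <- data.frame(
    tumor_id = tumor_id,
    chrom_arm = arms$arm,
    start = 0L,
    end = as.integer(arms$length_mb * 1e6),
    major_cn = unname(major[arms$arm]),
    minor_cn = unname(minor[arms$arm]),
    stringsAsFactors = FALSE)

  # --- mutations --------------------------------------------------------------
  # clonal mutations accrue per surviving lineage copy per unit time: relative
  # to a 1:1 arm, an arm carrying a gain at molecular time g accumulates
  # observable mutations at intensity kappa = ((d+u) g + C (1-g)) / 2, a lost
  # arm at kappa = 1/2 (mutations on the lost allele vanish). Mutations before
  # a gain fall on a duplicated copy with probability d/(d+u) and then carry
  # that copy's post-gain count (multiplicity 2); all others are multiplicity 1
  arm_model <- function(a) {
    st <- paste(major[a], minor[a])
    g <- gain_time[a]
    if (st == "2 1") list(kappa = (2 * g + 3 * (1 - g)) / 2, g = g,
                          p_pre = 2 * g / (2 * g + 3 * (1 - g)), p_dup = 0.5)
    else if (st == "2 2") list(kappa = (2 * g + 4 * (1 - g)) / 2, g = g,
                               p_pre = 2 * g / (2 * g + 4 * (1 - g)), p_dup = 1)
    else if (st == "2 0") list(kappa = (g + 2 * (1 - g)) / 2, g = g,
                               p_pre = g / (g + 2 * (1 - g)), p_dup = 1)
    else if (st == "1 0") list(kappa = 0.5, g = NA_real_, p_pre = 0, p_dup = 0)
    else list(kappa = 1, g = NA_real_, p_pre = 0, p_dup = 0)
  }
  models <- lapply(arms$arm, arm_model)
  names(models) <- arms$arm
  kappa <- vapply(models, `[[`, numeric(1), "kappa")
  len_w <- arms$length_mb / sum(arms$length_mb)

  n_clock <- stats::rpois(1, config$clock_rate * age * config$covered_cpg_mb *
                            sum(len_w * kappa))
  n_other <- stats::rpois(1, config$other_mut_per_year * age * sum(len_w * kappa))
  n_apo <- stats::rbinom(1, n_other, config$apobec_fraction)
  n <- n_clock + n_other
  context <- c(rep("ACG", n_clock), rep("TCA", n_apo), rep("ACA", n_other - n_apo))
  ref <- rep("C", n)
  alt <- c(rep("T", n_clock), rep("G", n_apo), rep("A", n_other - n_apo))

  n_sub <- stats::rpois(1, config$subclone_mut_fraction * n *
                          (stats::runif(1) < config$subclone_prevalence))
  ccf <- c(rep(1, n), rep(config$subclone_ccf, n_sub))
  if (n_sub > 0) {
    context <- c(context, rep("ACA", n_sub)); ref <- c(ref, rep("C", n_sub))
    alt <- c(alt, rep("A", n_sub))
  }
  ntot <- n + n_sub
  arm_of <- c(sample(arms$arm, n, replace = TRUE, prob = len_w * kappa),
              sample(arms$arm, n_sub, replace = TRUE, prob = len_w))
  pos <- as.integer(floor(stats::runif(ntot) * arms$length_mb[match(arm_of, arms$arm)] * 1e6))

  t_mut <- c(rep(NA_real_, n), rep(1, n_sub))
  mult <- rep(1L, ntot)
  for (i in seq_len(n)) {
    mo <- models[[arm_of[i]]]
    if (stats::runif(1) < mo$p_pre) {
      t_mut[i] <- stats::runif(1, 0, mo$g)
      if (stats::runif(1) < mo$p_dup) mult[i] <- 2L
    } else {
      t_mut[i] <- stats::runif(1, if (is.na(mo$g)) 0 else mo$g, 1)
    }
  }
  tot_cn <- unname(major[arm_of] + minor[arm_of])
  depth <- stats::rpois(ntot, config$coverage_mean)
  evaf <- expected_vaf(mult, ccf, purity, pmax(tot_cn, mult))
  alt_count <- stats::rbinom(ntot, depth, evaf)

  mutations <- data.frame(
    tumor_id = tumor_id,
    chrom_arm = arm_of,
    pos = pos,
    ref = ref,
    alt = alt,
    alt_count = alt_count,
    ref_count = depth - alt_count,
    context = context,
    gene = "",
    stringsAsFactors = FALSE)
  mut_truth <- data.frame(
    true_t = t_mut, true_multiplicity = mult, true_ccf = ccf,
    expected_vaf = evaf, stringsAsFactors = FALSE)

  # driver point mutations from the menu become dedicated rows
  for (i in which(ev$class == "driver_snv")) {
    a <- ev$locus[i]
    t_d <- ev$t_true[i]
    m_d <- 1L
    if (!is.na(gain_time[a]) && t_d < gain_time[a] && major[a] >= 2L) {
      d_cop <- if (minor[a] == 2L) 2L else 1L
      u_cop <- if (minor[a] == 1L) 1L else 0L
      if (minor[a] == 2L || stats::runif(1) < d_cop / (d_cop + u_cop)) m_d <- 2L
    }
    dep <- stats::rpois(1, config$coverage_mean)
    ev_vaf <- expected_vaf(m_d, 1, purity, max(major[a] + minor[a], m_d))
    ac <- stats::rbinom(1, dep, ev_vaf)
    mutations <- rbind(mutations, data.frame(
      tumor_id = tumor_id, chrom_arm = a,
      pos = as.integer(arms$length_mb[match(a, arms$arm)] * 5e5),
      ref = "C", alt = "A", alt_count = ac, ref_count = dep - ac,
      context = "ACA", gene = ev$name[i], stringsAsFactors = FALSE))
    mut_truth <- rbind(mut_truth, data.frame(
      true_t = t_d, true_multiplicity = m_d, true_ccf = 1, expected_vaf = ev_vaf))
  }

  truth <- list(
    events = data.frame(
      name = ev$name, class = ev$class, locus = ev$locus,
      t_true = ev$t_true, years_before_dx = ev$years_before_dx,
      wge_outcome = ev$wge_outcome, stringsAsFactors = FALSE),
    mutations = mut_truth,
    age = age, purity = purity, hpv = hpv)
  metadata <- data.frame(
    tumor_id = tumor_id, purity = purity, age = age,
    hpv_status = if (hpv) "positive" else "negative", site = site,
    stringsAsFactors = FALSE)
  out <- list(truth = truth, mutations = mutations, segments = segments,
              metadata = metadata)
  class(out) <- "sim_tumor"
  out
}

#' Simulate a cohort with ground truth
#'
#' Seeds the RNG from `config$seed` and simulates `n_tumors` tumors
#' sequentially, so the full bundle is a deterministic function of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `mutations` (stacked table),
#'   `segments`, `metadata`, `truth` (per-tumor list), `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ids <- sprintf("T%04d", seq_len(config$n_tumors))
  tumors <- lapply(ids, function(id) simulate_tumor(config, id))
  names(tumors) <- ids
  out <- list(
    mutations = do.call(rbind, lapply(tumors, `[[`, "mutations")),
    segments = do.call(rbind, lapply(tumors, `[[`, "segments")),
    metadata = do.call(rbind, lapply(tumors, `[[`, "metadata")),
    truth = lapply(tumors, `[[`, "truth"),
    config = config)
  rownames(out$mutations) <- rownames(out$segments) <- rownames(out$metadata) <- NULL
  class(out) <- "sim_cohort"
  out
}

#' Write a simulated cohort to disk
#'
#' One mutation TSV and one segment TSV per tumor, a cohort metadata TSV, and
#' the truth ledger as JSON. File contents are byte-identical across runs of
#' the same configuration.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, path) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in unique(cohort$metadata$tumor_id)) {
    tsv(cohort$mutations[cohort$mutations$tumor_id == id, , drop = FALSE],
        file.path(dir, paste0(id, ".mutations.tsv")))
    tsv(cohort$segments[cohort$segments$tumor_id == id, , drop = FALSE],
        file.path(dir, paste0(id, ".segments.tsv")))
  }
  tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- lapply(cohort$truth, function(tr) {
    tr$events$wge_outcome[is.na(tr$events$wge_outcome)] <- ""
    tr
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate a clock-calibration cohort
#'
#' Minimal cohort for clock-rate recovery: per tumor, an age is drawn
#' uniformly and the clonal CpG>T count is Poisson with mean
#' `rate * age * covered_cpg_mb`; burdens are computed through
#' [count_clock_mutations()] on a diploid multiplicity-one mutation table.
#'
#' @param n_tumors Number of tumors.
#' @param rate True clock rate (CpG>T per Mb at risk per year).
#' @param age_range Age window (years).
#' @param covered_cpg_mb Mb of CpG sites at risk.
#' @param hypermutated_fraction Fraction of tumors with a 10x inflated burden
#'   (clock outliers); 0 by default.
#' @return Data.frame: `age`, `burden` (per Mb), `hypermutated`.
#' @export
simulate_clock_cohort <- function(n_tumors, rate = 0.37, age_range = c(40, 80),
                                  covered_cpg_mb = 30,
                                  hypermutated_fraction = 0) {
  age <- stats::runif(n_tumors, age_range[1], age_range[2])
  hyper <- stats::runif(n_tumors) < hypermutated_fraction
  lam <- rate * age * covered_cpg_mb * ifelse(hyper, 10, 1)
  counts <- stats::rpois(n_tumors, lam)
  burden <- vapply(counts, function(k) {
    if (k == 0) return(0)
    ann <- data.frame(clonal = TRUE, context = "CpG>T",
                      map_multiplicity = 1L, total_cn = 2L,
                      ref = "C", alt = "T")
    ann <- ann[rep(1, k), , drop = FALSE]
    count_clock_mutations(ann, covered_cpg_mb)
  }, numeric(1))
  data.frame(age = age, burden = burden, hypermutated = hyper)
}

#' Simulate real-timed whole-genome events for the conversion model
#'
#' Events originate uniformly over `origin_window` years before diagnosis; a
#' fraction `immune_fraction` never converts; the rest convert after an
#' exponential waiting time at `conversion_rate` per year and are labeled WGT
#' when conversion happens before diagnosis.
#'
#' @param n_events Number of whole-genome events.
#' @param conversion_rate True annual conversion rate.
#' @param immune_fraction True never-converting fraction.
#' @param origin_window Years-before-diagnosis window of origination.
#' @return Data.frame: `tau` (years before diagnosis), `class`
#'   (`"WGD"`/`"WGT"`).
#' @export
simulate_conversion_events <- function(n_events, conversion_rate = 0.11,
                                       immune_fraction = 0.35,
                                       origin_window = c(0, 40)) {
  tau <- stats::runif(n_events, origin_window[1], origin_window[2])
  immune <- stats::runif(n_events) < immune_fraction
  wait <- stats::rexp(n_events, max(conversion_rate, 1e-12))
  cls <- ifelse(!immune & wait < tau & conversion_rate > 0, "WGT", "WGD")
  data.frame(tau = tau, class = cls, stringsAsFactors = FALSE)
}
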