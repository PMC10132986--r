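#' Event prevalence comparison between groups
#'
#' Per-event carrier counts and percentages in each of two groups, with
#' two-sided Fisher exact p values and Benjamini-Hochberg q values across
#' events.
#'
#' @param calls Logical (or 0/1) matrix, tumors in rows, events in columns.
#' @param group Factor/vector with exactly two levels, one entry per tumor.
#' @return Data.frame: `event`, per-group `n`, `total`, `percent` (full
#'   precision; format with [format_percent()]), `p`, `q`.
#' @export
cohort_stats <- function(calls, group) {
  calls <- as.matrix(calls)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("cohort_stats compares exactly two groups")
  if (any(table(group) == 0)) stop("empty group")
  g1 <- group == levels(group)[1]
  n1 <- colSums(calls[g1, , drop = FALSE] > 0)
  n2 <- colSums(calls[!g1, , drop = FALSE] > 0)
  N1 <- sum(g1); N2 <- sum(!g1)
  p <- vapply(seq_len(ncol(calls)), function(j)
    stats::fisher.test(matrix(c(n1[j], N1 - n1[j], n2[j], N2 - n2[j]), 2))$p.value,
    numeric(1))
  data.frame(
    event = colnames(calls),
    n_1 = n1, total_1 = N1, percent_1 = 100 * n1 / N1,
    n_2 = n2, total_2 = N2, percent_2 = 100 * n2 / N2,
    p = p, q = bh_fdr(p),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Display rounding for percentages
#'
#' One rounding rule for all reported percentages: round half away from zero
#' at the requested number of decimals (so 201/421 prints as 48\% at 0
#' decimals and 388/421 as 92.2\% at 1 decimal).
#'
#' @param x Percentage values.
#' @param digits Decimals to keep (default 1).
#' @return Numeric, rounded.
#' @export
format_percent <- function(x, digits = 1L) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Run the full timing pipeline
#'
#' Orchestrates simulate (or load) -> annotate -> per-tumor timing -> league
#' -> real-time -> heterogeneity (-> compare/stats when two cohorts are
#' defined), writing every stage's output and a manifest that reproduces the
#' run bit for bit.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{list passed to [sim_config()] (alternatively supply
#'       `input_dir` with cohort files written by [write_cohort()]).}
#'     \item{league}{optional list: `n_iterations`, `resample_fraction`,
#'       `min_cases`.}
#'     \item{compare_by}{optional metadata column defining two cohorts
#'       (e.g. `"hpv_status"`).}
#'     \item{covered_cpg_mb}{Mb of CpG sites at risk (default 30).}
#'     \item{seed}{root seed (default 1).}
#'   }
#' @param outdir Output directory.
#' @return Invisibly, a list with the stage results (`cohort`, `annotated`,
#'   `timing`, `league`, `realtime`, `heterogeneity`, `comparison`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cpg_mb <- if (is.null(config$covered_cpg_mb)) 30 else config$covered_cpg_mb
  lg <- utils::modifyList(list(n_iterations = 200L, resample_fraction = 0.63,
                               min_cases = 3L), config$league %||% list())
  manifest <- list(package_version = as.character(utils::packageVersion("tumortime")),
                   seed = seed, config = config, stages = list())
  t_start <- proc.time()[["elapsed"]]
  stage <- local({
    last <- t_start
    function(name) {
      now <- proc.time()[["elapsed"]]
      manifest$stages[[name]] <<- list(wall_seconds = round(now - last, 2))
      last <<- now
    }
  })
  fail <- function(name, why) stop("pipeline stage '", name, "' failed: ", why)

  # ---- stage: cohort ---------------------------------------------------------
  if (!is.null(config$input_dir)) {
    dirp <- config$input_dir
    meta_path <- file.path(dirp, "metadata.tsv")
    if (!file.exists(meta_path)) fail("load", paste("missing metadata file", meta_path))
    metadata <- read_metadata_table(meta_path)
    muts <- do.call(rbind, lapply(metadata$tumor_id, function(id)
      read_mutation_table(file.path(dirp, paste0(id, ".mutations.tsv")))))
    segs <- do.call(rbind, lapply(metadata$tumor_id, function(id)
      read_segment_table(file.path(dirp, paste0(id, ".segments.tsv")))))
    cohort <- list(mutations = muts, segments = segs, metadata = metadata)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cfg)
    write_cohort(cohort, file.path(outdir, "cohort"))
    if (!is.null(cfg$covered_cpg_mb)) cpg_mb <- cfg$covered_cpg_mb
  }
  stage("cohort")

  # ---- stage: annotate + per-tumor timing + heterogeneity --------------------
  ids <- cohort$metadata$tumor_id
  annotated <- list(); timing <- list(); het <- list(); burdens <- numeric(length(ids))
  timing_dir <- file.path(outdir, "timing")
  dir.create(timing_dir, showWarnings = FALSE)
  for (k in seq_along(ids)) {
    id <- ids[k]
    muts <- cohort$mutations[cohort$mutations$tumor_id == id, , drop = FALSE]
    segs <- cohort$segments[cohort$segments$tumor_id == id, , drop = FALSE]
    pur <- cohort$metadata$purity[k]
    ann <- annotate_mutations(muts, segs, pur)
    annotated[[id]] <- ann
    set.seed(seed + k)   # per-tumor stream for the joint posterior sampling
    timing[[id]] <- assemble_patient_timing(ann, segs)
    write_timing_json(timing[[id]], file.path(timing_dir, paste0(id, ".timing.json")))
    het[[id]] <- cbind(tumor_id = id, heterogeneity_profile(ann, segs))
    burdens[k] <- count_clock_mutations(ann, cpg_mb)
  }
  stage("annotate_time_het")
  het_tab <- do.call(rbind, het)
  utils::write.table(het_tab, file.path(outdir, "heterogeneity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage: league ---------------------------------------------------------
  pi_lists <- lapply(timing, function(tt) stats::setNames(tt$pi, tt$event))
  league <- league_aggregate(pi_lists, n_iterations = lg$n_iterations,
                             resample_fraction = lg$resample_fraction,
                             seed = seed + 10000L)
  league_tab <- data.frame(event = names(league$mrt), mrt = league$mrt,
                           ci_lo = league$ci[, 1], ci_hi = league$ci[, 2],
                           prevalence = league$prevalence, row.names = NULL)
  utils::write.table(league_tab, file.path(outdir, "league.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("league")

  # ---- stage: real time ------------------------------------------------------
  rate_fit <- fit_aging_rate(burdens, cohort$metadata$age)
  rt_rows <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    tt <- timing[[id]]
    if (!nrow(tt) || burdens[k] <= 0) next
    for (i in seq_len(nrow(tt))) {
      yr <- pi_to_years(tt$pi[[i]], burdens[k], rate_fit$rate,
                        cohort$metadata$age[k])
      rt_rows[[length(rt_rows) + 1L]] <- data.frame(
        tumor_id = id, event = tt$event[i], class = tt$class[i],
        years_mean = attr(yr, "mean"),
        years_lo = attr(yr, "ci")[1], years_hi = attr(yr, "ci")[2])
    }
  }
  realtime <- do.call(rbind, rt_rows)
  utils::write.table(realtime, file.path(outdir, "realtime.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conv <- NULL
  wge_rt <- realtime[realtime$class == "wgd", , drop = FALSE]
  wge_cls <- het_tab$wge_call[match(wge_rt$tumor_id, het_tab$tumor_id)]
  okc <- wge_cls %in% c("WGD", "WGT")
  if (sum(okc) >= 10) {
    conv <- fit_wgd_wgt_conversion(wge_rt$years_mean[okc], wge_cls[okc])
    jsonlite::write_json(list(lambda = conv$lambda, f = conv$f,
                              lambda_ci = conv$lambda_ci, f_ci = conv$f_ci),
                         file.path(outdir, "conversion_model.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  stage("realtime")

  # ---- stage: compare / stats ------------------------------------------------
  comparison <- NULL
  if (!is.null(config$compare_by)) {
    gv <- cohort$metadata[[config$compare_by]]
    if (is.null(gv)) fail("compare", paste("no metadata column", config$compare_by))
    lv <- unique(gv)
    if (length(lv) == 2) {
      a <- pi_lists[gv == lv[1]]; b <- pi_lists[gv == lv[2]]
      comparison <- compare_cohorts(a, b, min_cases = lg$min_cases,
                                    n_iterations = lg$n_iterations,
                                    resample_fraction = lg$resample_fraction,
                                    seed = seed + 20000L)
      utils::write.table(comparison, file.path(outdir, "comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      events <- sort(unique(unlist(lapply(pi_lists, names))))
      calls <- t(vapply(pi_lists, function(x) events %in% names(x),
                        logical(length(events))))
      colnames(calls) <- events
      st <- cohort_stats(calls, gv)
      utils::write.table(st, file.path(outdir, "prevalence_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  stage("compare")

  manifest$clock_rate <- rate_fit$rate
  manifest$total_wall_seconds <- round(proc.time()[["elapsed"]] - t_start, 2)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(list(cohort = cohort, annotated = annotated, timing = timing,
                 league = league, rate_fit = rate_fit, conversion = conv,
                 heterogeneity = het_tab, realtime = realtime,
                 comparison = comparison, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
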