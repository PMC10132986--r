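#' Read and write the package's tabular formats
#'
#' Tab-separated tables with headers: mutation tables (`tumor_id`,
#' `chrom_arm`, `pos`, `ref`, `alt`, `alt_count`, `ref_count`, `context`,
#' optional `gene`), segment tables (`tumor_id`, `chrom_arm`, `start`, `end`,
#' `major_cn`, `minor_cn`) and cohort metadata (`tumor_id`, `purity`, `age`,
#' `hpv_status`, `site`).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_mutation_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "chrom_arm", "pos", "alt_count", "ref_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("mutation table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname read_mutation_table
#' @export
read_segment_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "chrom_arm", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("segment table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname read_mutation_table
#' @export
read_metadata_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tumor_id", "purity", "age"), names(x))
  if (length(miss)) stop("metadata table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' Read somatic SNVs from a VCF with AD fields
#'
#' Optional adapter mapping the first sample's allelic-depth (`AD`) field to
#' `alt_count`/`ref_count`; requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @param tumor_id Identifier for the output table.
#' @return A mutation data.frame in the package dialect (context `"other"`;
#'   `chrom_arm` taken from the CHROM column).
#' @export
read_mutations_vcf <- function(path, tumor_id = "tumor") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_mutations_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_count <- as.integer(vapply(parts, `[`, "", 1))
  alt_count <- as.integer(vapply(parts, `[`, "", 2))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(tumor_id = tumor_id, chrom_arm = fix$CHROM,
             pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
             alt_count = alt_count, ref_count = ref_count,
             context = "other", gene = "", stringsAsFactors = FALSE)
}

#' Write and read per-tumor event timing as JSON
#'
#' Serializes a [assemble_patient_timing()] result (event names, classes,
#' posterior histograms, means and 75\% credible intervals) so that cohort
#' stages can run from files.
#'
#' @param timing A `patient_timing` data.frame.
#' @param path Output path.
#' @export
write_timing_json <- function(timing, path) {
  payload <- lapply(seq_len(nrow(timing)), function(i) list(
    event = timing$event[i], class = timing$class[i], locus = timing$locus[i],
    pi_mean = timing$pi_mean[i], ci = c(timing$ci_lo[i], timing$ci_hi[i]),
    flags = timing$flags[i], prob = timing$pi[[i]]$prob))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_timing_json
#' @return `read_timing_json()` returns a named list of [pi_dist] objects.
#' @export
read_timing_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(payload)), function(i) {
    prob <- payload$prob[[i]]
    flags <- if (nzchar(payload$flags[i]))
      strsplit(payload$flags[i], ",")[[1]] else character()
    if ("delta_one" %in% flags) pi_delta_one(length(prob))
    else pi_dist(prob, flags = setdiff(flags, "delta_one"))
  })
  names(out) <- payload$event
  out
}
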