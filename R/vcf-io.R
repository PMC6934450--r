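#' Default VCF field dialect for per-tissue depth and allele counts
#'
#' Somatic callers emit different VCF dialects; the mapping from FORMAT keys
#' to per-tissue depth and alt-allele counts is therefore configurable. The
#' default dialect matches the VCFs written by [write_vcf()] /
#' [emulate_caller()]: two genotype columns named `TARGET` and `REFERENCE`,
#' total depth under FORMAT key `DP`, and allelic depths under `AD` as
#' `ref,alt` (the alt count is the second element). Unknown or missing keys
#' degrade to `NA` ("unknown"), never to silent zeros.
#'
#' @param format_depth FORMAT key holding total read depth.
#' @param format_ad FORMAT key holding comma-separated allelic depths.
#' @param ad_alt_index 1-based index of the alt count within the AD field.
#' @param target_sample,reference_sample genotype column names for the
#'   affected and the reference tissue.
#' @return a named list describing the dialect.
#' @export
vcf_dialect <- function(format_depth = "DP", format_ad = "AD",
                        ad_alt_index = 2L,
                        target_sample = "TARGET",
                        reference_sample = "REFERENCE") {
  list(
    format_depth = format_depth, format_ad = format_ad,
    ad_alt_index = as.integer(ad_alt_index),
    target_sample = target_sample, reference_sample = reference_sample
  )
}

#' Read somatic SNV calls from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [call_set()]. Only
#' single-nucleotide records are retained; indels and other non-SNV records
#' are skipped with a logged count. Multi-allelic records are split into one
#' call per alt allele before the CallSet's duplicate-position policy
#' (keep first, log the rest) applies. Records with malformed positions are
#' collected as record-level errors and parsing continues.
#'
#' Subject, tissue, caller and functional class are taken from the INFO keys
#' `SUBJECT`, `TISSUE`, `CALLER`, `FCLASS` when present, otherwise from the
#' corresponding arguments.
#'
#' @param path VCF file (plain or bgzipped).
#' @param dialect field mapping from [vcf_dialect()].
#' @param subject,tissue,caller fallback identifiers.
#' @return a `CallSet`.
#' @export
read_vcf <- function(path, dialect = vcf_dialect(),
                     subject = "unknown", tissue = "unknown",
                     caller = "unknown") {
  if (!file.exists(path)) stop("read_vcf(): cannot read '", path, "'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    return(call_set(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      subject = subject, tissue = tissue, caller = caller
    ))
  }

  pos <- suppressWarnings(as.integer(fix$POS))
  bad_pos <- is.na(pos) | pos < 1L
  if (any(bad_pos)) {
    message(sum(bad_pos), " record(s) with malformed position skipped")
  }

  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }

  gt_field <- function(key, sample_name, as_num = TRUE) {
    if (is.null(v@gt) || ncol(v@gt) < 2L) return(rep(NA_character_, n_in))
    if (!sample_name %in% colnames(v@gt)) return(rep(NA_character_, n_in))
    x <- tryCatch(
      vcfR::extract.gt(v, element = key)[, sample_name],
      error = function(e) rep(NA_character_, n_in)
    )
    unname(x)
  }

  dp_t <- suppressWarnings(as.integer(gt_field(dialect$format_depth, dialect$target_sample)))
  dp_r <- suppressWarnings(as.integer(gt_field(dialect$format_depth, dialect$reference_sample)))
  ad_alt <- function(x) {
    vapply(strsplit(x, ",", fixed = TRUE), function(p) {
      if (length(p) >= dialect$ad_alt_index) {
        suppressWarnings(as.numeric(p[dialect$ad_alt_index]))
      } else NA_real_
    }, numeric(1))
  }
  alt_t <- ad_alt(gt_field(dialect$format_ad, dialect$target_sample))
  alt_r <- ad_alt(gt_field(dialect$format_ad, dialect$reference_sample))

  rec <- data.frame(
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
    depth_target = dp_t, depth_reference = dp_r,
    alt_target = alt_t, alt_reference = alt_r,
    functional_class = info_field(fix$INFO, "FCLASS"),
    info_subject = info_field(fix$INFO, "SUBJECT"),
    info_tissue = info_field(fix$INFO, "TISSUE"),
    info_caller = info_field(fix$INFO, "CALLER"),
    stringsAsFactors = FALSE
  )
  rec <- rec[!bad_pos, , drop = FALSE]

  # split multi-allelic records into one row per alt allele
  alt_list <- strsplit(rec$alt, ",", fixed = TRUE)
  rec <- rec[rep(seq_len(nrow(rec)), lengths(alt_list)), , drop = FALSE]
  rec$alt <- unlist(alt_list)

  snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T") &
    rec$ref != rec$alt
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) skipped")
  rec <- rec[snv, , drop = FALSE]

  rec$vaf_target <- ifelse(!is.na(rec$depth_target) & rec$depth_target > 0,
                           rec$alt_target / rec$depth_target, NA_real_)
  rec$vaf_reference <- ifelse(!is.na(rec$depth_reference) & rec$depth_reference > 0,
                              rec$alt_reference / rec$depth_reference, NA_real_)
  rec$functional_class[is.na(rec$functional_class)] <- "unknown"

  pick <- function(info_col, fallback) {
    vals <- unique(stats::na.omit(rec[[info_col]]))
    if (length(vals) == 1L) vals else fallback
  }
  call_set(
    rec[, c("chrom", "pos", "ref", "alt", "vaf_target", "vaf_reference",
            "depth_target", "depth_reference", "functional_class")],
    subject = pick("info_subject", subject),
    tissue = pick("info_tissue", tissue),
    caller = pick("info_caller", caller)
  )
}

#' Write a CallSet as a VCF 4.2 file
#'
#' Emits one SNV record per call with two genotype columns (`TARGET`,
#' `REFERENCE`) carrying `GT:DP:AD`, and the provenance INFO keys `SUBJECT`,
#' `TISSUE`, `CALLER`, `FCLASS` so that [read_vcf()] round-trips positions,
#' alleles, depths and VAFs.
#'
#' @param callset a `CallSet`.
#' @param path output file path (plain text).
#' @param seed optional integer recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path, seed = NULL) {
  stopifnot(inherits(callset, "CallSet"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=polyclonesmc_", as.character(utils::packageVersion("polyclonesmc"))),
    if (!is.null(seed)) paste0("##simulation_seed=", as.integer(seed)),
    "##INFO=<ID=SUBJECT,Number=1,Type=String,Description=\"Subject identifier\">",
    "##INFO=<ID=TISSUE,Number=1,Type=String,Description=\"Affected tissue\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling tool\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTARGET\tREFERENCE"
  )
  fmt_sample <- function(gt, dp, alt) {
    dp_s <- ifelse(is.na(dp), ".", as.character(as.integer(dp)))
    alt_s <- ifelse(is.na(alt) | is.na(dp), ".,.",
                    paste0(as.integer(dp) - as.integer(round(alt)), ",",
                           as.integer(round(alt))))
    paste(gt, dp_s, alt_s, sep = ":")
  }
  n <- nrow(callset)
  body <- character(0)
  if (n > 0L) {
    alt_t <- ifelse(is.na(callset$vaf_target) | is.na(callset$depth_target),
                    NA_real_, callset$vaf_target * callset$depth_target)
    alt_r <- ifelse(is.na(callset$vaf_reference) | is.na(callset$depth_reference),
                    NA_real_, callset$vaf_reference * callset$depth_reference)
    info <- sprintf(
      "SUBJECT=%s;TISSUE=%s;CALLER=%s;FCLASS=%s",
      cs_subject(callset), cs_tissue(callset), cs_caller(callset),
      callset$functional_class
    )
    body <- paste(
      callset$chrom, callset$pos, ".", callset$ref, callset$alt, ".", "PASS",
      info, "GT:DP:AD",
      fmt_sample("0/1", callset$depth_target, alt_t),
      fmt_sample("0/0", callset$depth_reference, alt_r),
      sep = "\t"
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
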