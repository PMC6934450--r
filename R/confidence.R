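#' Assign a confidence tier from annotation flags
#'
#' The tier of a call depends on three binary annotations: overlap with a
#' common SNP (MAF >= 1%), overlap with a repetitive region, and 50-mer
#' mappability uniqueness.
#'
#' * **high**: not a SNP, not repetitive, and unique;
#' * **low**: a SNP (regardless of the other flags), or both repetitive and
#'   non-unique;
#' * **medium**: not a SNP and exactly one of \{repetitive, non-unique\}.
#'
#' The three predicates partition all 8 flag combinations with no gaps or
#' overlaps. Rare or unknown-frequency SNPs (the all-SNP track minus the
#' common-SNP track) never influence the tier; they enter only the stringent
#' re-assessment flags ([stringent_reassess()]).
#'
#' @param in_common_snp,in_repeat,non_unique logical vectors (recycled).
#' @return character vector: `"high"`, `"medium"` or `"low"`.
#' @export
#' @examples
#' assign_tier(FALSE, FALSE, FALSE)  # high
#' assign_tier(TRUE,  FALSE, FALSE)  # low: SNP overrides everything
#' assign_tier(FALSE, TRUE,  FALSE)  # medium
#' assign_tier(FALSE, TRUE,  TRUE)   # low: repetitive AND non-unique
assign_tier <- function(in_common_snp, in_repeat, non_unique) {
  n <- max(length(in_common_snp), length(in_repeat), length(non_unique))
  snp <- rep_len(as.logical(in_common_snp), n)
  rep_ <- rep_len(as.logical(in_repeat), n)
  nu <- rep_len(as.logical(non_unique), n)
  ifelse(snp | (rep_ & nu), "low",
         ifelse(!rep_ & !nu, "high", "medium"))
}

#' Annotate a call set with track flags, tiers and stringent flags
#'
#' For every call: membership in the common-SNP, all-SNP and repeat tracks,
#' mappability uniqueness, the confidence tier per [assign_tier()], and the
#' three stringent re-assessment flags with their conjunction
#' (`stringent_pass`).
#'
#' @param callset a `CallSet` (typically the consensus).
#' @param tracks named list of `Track`s; `common_snp`, `repeat` and
#'   `mappability_unique` are required, `all_snp` is needed for the
#'   stringent flags.
#' @return data frame of class `AnnotatedCalls`: the call columns plus
#'   `subject`, `tissue`, `in_common_snp`, `in_all_snp`, `in_repeat`,
#'   `non_unique`, `tier`, `depth_ge20_both`, `ref_vaf_zero`,
#'   `not_in_any_snp`, `stringent_pass`.
#' @export
annotate_calls <- function(callset, tracks) {
  for (req in c("common_snp", "repeat", "mappability_unique")) {
    if (is.null(tracks[[req]])) {
      stop("annotate_calls(): required track '", req, "' is missing")
    }
  }
  df <- as.data.frame(callset)
  df$subject <- rep_len(cs_subject(callset), nrow(df))
  df$tissue <- rep_len(cs_tissue(callset), nrow(df))
  if (nrow(df) == 0L) {
    for (col in c("in_common_snp", "in_all_snp", "in_repeat", "non_unique",
                  "depth_ge20_both", "ref_vaf_zero", "not_in_any_snp",
                  "stringent_pass")) df[[col]] <- logical(0)
    df$tier <- character(0)
    class(df) <- c("AnnotatedCalls", "data.frame")
    return(df)
  }
  df$in_common_snp <- overlaps(tracks$common_snp, df$chrom, df$pos)
  df$in_repeat <- overlaps(tracks[["repeat"]], df$chrom, df$pos)
  df$non_unique <- !overlaps(tracks$mappability_unique, df$chrom, df$pos)
  df$in_all_snp <- if (!is.null(tracks$all_snp)) {
    overlaps(tracks$all_snp, df$chrom, df$pos)
  } else NA
  df$tier <- assign_tier(df$in_common_snp, df$in_repeat, df$non_unique)

  # stringent flags: unknown depth/VAF conservatively fails the flag
  dep_known <- !is.na(df$depth_target) & !is.na(df$depth_reference)
  if (any(!dep_known)) {
    warning(sum(!dep_known),
            " call(s) with unknown depths: depth flag set FALSE")
  }
  df$depth_ge20_both <- dep_known & df$depth_target >= 20L &
    df$depth_reference >= 20L
  vaf_known <- !is.na(df$vaf_reference)
  if (any(!vaf_known)) {
    warning(sum(!vaf_known),
            " call(s) with unknown reference VAF: flag set FALSE")
  }
  df$ref_vaf_zero <- vaf_known & df$vaf_reference == 0
  df$not_in_any_snp <- !is.na(df$in_all_snp) & !df$in_all_snp
  df$stringent_pass <- df$depth_ge20_both & df$ref_vaf_zero & df$not_in_any_snp
  class(df) <- c("AnnotatedCalls", "data.frame")
  df
}

#' Stringent re-assessment of an annotated call
#'
#' The still-rather-permissive combined criteria applied retrospectively to
#' high-confidence calls: read depth >= 20 in both tissues, zero variant
#' reads in the reference tissue, and no overlap with any known SNP (even of
#' rare or unknown population frequency).
#'
#' @param annotated a data frame from [annotate_calls()] (or any data frame
#'   with the `stringent_pass` column's inputs).
#' @return logical vector, `TRUE` where all three criteria hold.
#' @export
stringent_reassess <- function(annotated) {
  stopifnot(all(c("depth_ge20_both", "ref_vaf_zero", "not_in_any_snp") %in%
                  names(annotated)))
  annotated$depth_ge20_both & annotated$ref_vaf_zero & annotated$not_in_any_snp
}

#' Summarise a call set (spectrum, track overlap, VAF, coverage)
#'
#' Computes the characteristics used to appraise a call set: the
#' substitution spectrum folded to the six pyrimidine-context classes
#' (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`; purine-reference calls are
#' complemented, e.g. `G>T` counts as `C>A`), the fraction of calls
#' overlapping each supplied track, the median target-tissue VAF, the
#' fraction of calls with depth >= 20 in both tissues, and per-chromosome
#' counts. Medians and fractions are computed over known values only.
#'
#' @param callset a `CallSet`.
#' @param tracks named list of `Track`s (any subset; each contributes an
#'   overlap fraction).
#' @return object of class `CallSetSummary`: list with `n`, `spectrum`
#'   (named fractions summing to 1 over classified calls), `track_overlap`,
#'   `median_vaf`, `frac_depth_ge20_both`, `per_chrom_counts`.
#' @export
summarize_callset <- function(callset, tracks = list()) {
  df <- as.data.frame(callset)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- df$ref
  alt <- df$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[df$ref[flip]]
  alt[flip] <- comp[df$alt[flip]]
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  subst <- factor(paste0(ref, ">", alt), levels = classes)
  spectrum <- if (nrow(df) > 0L && any(!is.na(subst))) {
    prop.table(table(subst))
  } else {
    table(subst)  # all-zero
  }
  track_overlap <- vapply(tracks, function(tr) {
    if (nrow(df) == 0L) return(NA_real_)
    mean(overlaps(tr, df$chrom, df$pos))
  }, numeric(1))
  dep_both <- df$depth_target >= 20L & df$depth_reference >= 20L
  structure(
    list(
      n = nrow(df),
      spectrum = stats::setNames(as.numeric(spectrum), classes),
      track_overlap = track_overlap,
      median_vaf = stats::median(df$vaf_target, na.rm = TRUE),
      frac_depth_ge20_both = mean(dep_both, na.rm = TRUE),
      per_chrom_counts = table(df$chrom)
    ),
    class = "CallSetSummary"
  )
}

#' @export
print.CallSetSummary <- function(x, ...) {
  cat(sprintf("CallSetSummary: %d call(s), median VAF %.3f, depth>=20 both: %.1f%%\n",
              x$n, x$median_vaf, 100 * x$frac_depth_ge20_both))
  cat("spectrum:", paste(names(x$spectrum),
                         sprintf("%.3f", x$spectrum), collapse = " "), "\n")
  invisible(x)
}

#' Substitution class of calls in pyrimidine context
#' @param ref,alt single-base allele vectors.
#' @return character vector of classes (`"C>A"`, ...).
#' @export
substitution_class <- function(ref, alt) {
  if (length(ref) == 0L) return(character(0))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  paste0(r, ">", a)
}
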