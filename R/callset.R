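#' Construct a CallSet of somatic single-nucleotide mutation calls
#'
#' A `CallSet` is a data frame of SSM calls from one subject x tissue x
#' caller, sorted by genomic position and unique per position (the matching
#' key used throughout: chromosome and 1-based position, alleles are carried
#' along but never used for matching). Duplicate positions keep the first
#' record; the rest are dropped with a message, since position is the
#' matching key for consensus building.
#'
#' @param calls data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `vaf_target`, `vaf_reference`, `depth_target`,
#'   `depth_reference`, `functional_class` (one of `"nonsynonymous"`,
#'   `"splice_site"`, `"other"`, `"unknown"`). Missing optional columns are
#'   filled with `NA` / `"unknown"`.
#' @param subject subject identifier.
#' @param tissue tissue identifier (`"blood"`, `"lower_lobe"`,
#'   `"upper_lobe"`, ...).
#' @param caller caller identifier, or `"consensus"`.
#' @return object of class `CallSet` (a data frame with metadata attributes
#'   `subject`, `tissue`, `caller`).
#' @export
#' @examples
#' cs <- call_set(data.frame(chrom = "1", pos = c(200L, 100L),
#'                           ref = c("A", "C"), alt = c("G", "T")),
#'                subject = "s01", tissue = "lower_lobe", caller = "toy")
#' cs$pos  # sorted
call_set <- function(calls, subject = "unknown", tissue = "unknown",
                     caller = "unknown") {
  stopifnot(is.data.frame(calls))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("call_set(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  optional <- list(
    vaf_target = NA_real_, vaf_reference = NA_real_,
    depth_target = NA_integer_, depth_reference = NA_integer_,
    functional_class = "unknown"
  )
  for (nm in names(optional)) {
    if (is.null(calls[[nm]])) calls[[nm]] <- rep_len(optional[[nm]], nrow(calls))
  }
  calls <- calls[, c(required, names(optional))]
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  if (nrow(calls) > 0L) {
    validate_calls(calls)
    calls <- calls[order_positions(calls$chrom, calls$pos), , drop = FALSE]
    dup <- duplicated(pos_key(calls$chrom, calls$pos))
    if (any(dup)) {
      message(sum(dup), " duplicate position(s) dropped (keep-first policy)")
      calls <- calls[!dup, , drop = FALSE]
    }
    rownames(calls) <- NULL
  }
  structure(calls,
    subject = subject, tissue = tissue, caller = caller,
    class = c("CallSet", "data.frame")
  )
}

validate_calls <- function(calls) {
  if (any(calls$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(!nzchar(calls$chrom))) stop("chromosome names must be non-empty")
  bases <- c("A", "C", "G", "T")
  snv <- calls$ref %in% bases & calls$alt %in% bases
  if (any(!snv)) stop("CallSet records must be single-base SNVs (ACGT)")
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  vafs <- c(calls$vaf_target, calls$vaf_reference)
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) stop("VAFs must lie in [0, 1]")
  depths <- c(calls$depth_target, calls$depth_reference)
  if (any(depths < 0, na.rm = TRUE)) stop("depths must be >= 0")
  invisible(TRUE)
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf(
    "CallSet: %d call(s) | subject=%s tissue=%s caller=%s\n",
    nrow(x), attr(x, "subject"), attr(x, "tissue"), attr(x, "caller")
  ))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Subject / tissue / caller accessors for a CallSet
#' @param x a `CallSet`.
#' @return a scalar character.
#' @export
cs_subject <- function(x) attr(x, "subject")

#' @rdname cs_subject
#' @export
cs_tissue <- function(x) attr(x, "tissue")

#' @rdname cs_subject
#' @export
cs_caller <- function(x) attr(x, "caller")
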