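#' Construct an annotation Track from intervals
#'
#' A Track is a named, sorted, non-overlapping interval set used to annotate
#' calls (common SNPs, all SNPs, repeats, 50-mer unique mappability, DNase
#' hypersensitive sites). Intervals are supplied in BED convention (0-based
#' half-open) and merged on construction. Internally a
#' [GenomicRanges::GRanges] with normalised (``chr``-stripped) seqnames
#' holds the intervals in 1-based closed coordinates, so a 1-based VCF
#' position can be queried directly; the BED conversion happens exactly
#' once, here.
#'
#' @param name one of `"common_snp"`, `"all_snp"`, `"repeat"`,
#'   `"mappability_unique"`, `"dhs"`.
#' @param chrom,start,end parallel vectors; `start`/`end` 0-based half-open.
#' @return an object of class `Track`.
#' @export
track <- function(name, chrom = character(), start = integer(),
                  end = integer()) {
  name <- match.arg(name,
    c("common_snp", "all_snp", "repeat", "mappability_unique", "dhs"))
  if (length(start) != length(end)) {
    stop("track(): start and end must have equal length")
  }
  chrom <- rep_len(as.character(chrom), length(start))
  bad <- start >= end
  if (any(bad)) {
    message(sum(bad), " interval(s) with start >= end skipped in track '",
            name, "'")
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(name = name, gr = gr), class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("Track '%s': %d interval(s), %d bp covered\n",
              x$name, length(x$gr), track_coverage_bp(x)))
  invisible(x)
}

#' Read a BED3+ file into a Track
#'
#' Intervals are merged and sorted on load; records with `start >= end` are
#' skipped with a message; an empty file yields a valid empty track.
#'
#' @param path BED file path.
#' @param name track name (see [track()]).
#' @return a `Track`.
#' @export
read_bed_track <- function(path, name) {
  if (!file.exists(path)) stop("read_bed_track(): cannot read '", path, "'")
  info <- file.size(path)
  if (is.na(info) || info == 0L) return(track(name))
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(track(name))
  track(name,
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr))
}

#' Write a Track to a BED3 file
#' @param x a `Track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(x, path) {
  stopifnot(inherits(x, "Track"))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x$gr)),
    start = GenomicRanges::start(x$gr) - 1L,
    end = GenomicRanges::end(x$gr)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Does a 1-based genomic position fall inside a track?
#'
#' The query position comes from VCF coordinates (1-based); the track stores
#' BED intervals, so position `p` overlaps an interval `[start, end)` iff
#' `p - 1` lies in it.
#'
#' @param x a `Track`.
#' @param chrom chromosome name (any `chr` prefix is ignored for matching).
#' @param pos 1-based position vector.
#' @return logical vector.
#' @export
#' @examples
#' tr <- track("repeat", "chr1", 99, 100)
#' overlaps(tr, "1", 100)  # TRUE: BED [99,100) is base 100 in 1-based
#' overlaps(tr, "1", 101)  # FALSE
overlaps <- function(x, chrom, pos) {
  stopifnot(inherits(x, "Track"))
  if (length(pos) == 0L) return(logical(0))
  chrom <- rep_len(as.character(chrom), length(pos))
  q <- GenomicRanges::GRanges(
    seqnames = norm_chrom(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
  # seqlevels present in only one of query/track are legitimate (no overlap)
  suppressWarnings(
    GenomicRanges::countOverlaps(q, x$gr, ignore.strand = TRUE) > 0L
  )
}

#' Total base pairs covered by a track
#' @param x a `Track`.
#' @return integer bp count.
#' @export
track_coverage_bp <- function(x) {
  stopifnot(inherits(x, "Track"))
  sum(GenomicRanges::width(x$gr))
}
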