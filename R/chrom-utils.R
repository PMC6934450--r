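#' Normalise a chromosome name for matching
#'
#' Strips a leading \code{"chr"} prefix (case-insensitive) so that call sets
#' and annotation tracks from sources with different naming conventions can
#' be matched. Original names are preserved on output objects; normalisation
#' happens only at comparison time.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalised names.
#' @export
#' @examples
#' norm_chrom(c("chr1", "1", "chrX"))
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Natural ordering rank for chromosome names
#'
#' Numeric chromosomes sort numerically (1, 2, ..., 22), non-numeric ones
#' (X, Y, MT, ...) follow in lexical order. Used for the total ordering of
#' genomic positions: (chromosome, then position).
#'
#' @param chrom character vector of chromosome names.
#' @return integer rank vector usable with [order()].
#' @keywords internal
chrom_rank <- function(chrom) {
  ch <- norm_chrom(chrom)
  num <- suppressWarnings(as.numeric(ch))
  is_num <- !is.na(num)
  lex <- sort(unique(ch[!is_num]))
  rank <- numeric(length(ch))
  rank[is_num] <- num[is_num]
  rank[!is_num] <- 1e6 + match(ch[!is_num], lex)
  rank
}

#' Order indices for (chrom, pos) pairs
#' @param chrom chromosome names
#' @param pos 1-based positions
#' @return integer permutation
#' @keywords internal
order_positions <- function(chrom, pos) {
  order(chrom_rank(chrom), pos)
}

#' Position keys for set algebra on (chrom, pos)
#' @keywords internal
pos_key <- function(chrom, pos) {
  if (length(pos) == 0L) return(character(0))
  paste0(norm_chrom(chrom), ":", as.integer(pos))
}
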