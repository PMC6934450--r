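#' Per-position read-depth profile for one sample
#'
#' The contract is positional query: `query_depth(profile, chrom, pos)`
#' returns the read depth at a 1-based position, 0 where uncovered. At desk
#' scale the profile is stored densely as one integer vector per chromosome
#' (position `i` = element `i`).
#'
#' @param depths named list of non-negative integer vectors, one per
#'   chromosome; names are chromosome names.
#' @return object of class `DepthProfile`.
#' @export
depth_profile <- function(depths) {
  stopifnot(is.list(depths), !is.null(names(depths)), all(nzchar(names(depths))))
  depths <- lapply(depths, function(d) {
    d <- as.integer(d)
    if (any(d < 0L, na.rm = TRUE)) stop("depths must be >= 0")
    d[is.na(d)] <- 0L
    d
  })
  names(depths) <- norm_chrom(names(depths))
  structure(list(depths = depths), class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile: %d chromosome(s), %d bp assessed\n",
              length(x$depths), sum(lengths(x$depths))))
  invisible(x)
}

#' Query read depth at 1-based positions
#' @param profile a `DepthProfile`.
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return integer vector of depths (0 where uncovered).
#' @export
query_depth <- function(profile, chrom, pos) {
  stopifnot(inherits(profile, "DepthProfile"))
  chrom <- rep_len(norm_chrom(chrom), length(pos))
  pos <- as.integer(pos)
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    vec <- profile$depths[[ch]]
    if (is.null(vec)) next
    p <- pos[idx]
    ok <- p >= 1L & p <= length(vec)
    out[idx[ok]] <- vec[p[ok]]
  }
  out
}

#' Read a depth profile from TSV or bedGraph
#'
#' Accepts either a three-column TSV (`chrom`, `pos`, `depth`; 1-based
#' positions, with or without a header line) or a four-column bedGraph
#' (`chrom`, `start`, `end`, `depth`; 0-based half-open). The format is
#' chosen by column count. Positions not listed get depth 0 up to the
#' highest listed position per chromosome.
#'
#' @param path input file.
#' @return a `DepthProfile`.
#' @export
read_depth_profile <- function(path) {
  if (!file.exists(path)) stop("read_depth_profile(): cannot read '", path, "'")
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 3L) {
    names(df) <- c("chrom", "pos", "depth")
    df$start <- df$pos; df$end <- df$pos
  } else if (ncol(df) == 4L) {
    names(df) <- c("chrom", "start0", "end0", "depth")
    df$start <- df$start0 + 1L; df$end <- df$end0
  } else {
    stop("read_depth_profile(): expected 3 (TSV) or 4 (bedGraph) columns")
  }
  df$chrom <- norm_chrom(df$chrom)
  depths <- lapply(split(df, df$chrom), function(d) {
    vec <- integer(max(d$end))
    for (i in seq_len(nrow(d))) vec[d$start[i]:d$end[i]] <- as.integer(d$depth[i])
    vec
  })
  depth_profile(depths)
}

#' Write a depth profile as a TSV (chrom, pos, depth)
#' @param profile a `DepthProfile`.
#' @param path output path.
#' @param skip_zero drop zero-depth positions (default TRUE).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path, skip_zero = TRUE) {
  stopifnot(inherits(profile, "DepthProfile"))
  parts <- lapply(names(profile$depths), function(ch) {
    d <- profile$depths[[ch]]
    keep <- if (skip_zero) which(d > 0L) else seq_along(d)
    data.frame(chrom = ch, pos = keep, depth = d[keep])
  })
  df <- do.call(rbind, parts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
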