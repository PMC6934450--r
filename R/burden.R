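#' SMC power: callable base pairs at a depth threshold
#'
#' The somatic-mutation-calling power of a subject is the number of base
#' pairs with read depth at or above the threshold (default 10) in both the
#' affected and the reference tissue — the genome fraction where calling was
#' possible at all. Both profiles must assess the same region set (same
#' chromosomes and lengths).
#'
#' @param depth_target,depth_reference `DepthProfile`s for the affected and
#'   the reference tissue.
#' @param threshold minimum depth in both tissues (default 10).
#' @return object of class `PowerResult`: list with `callable_bp`,
#'   `threshold`, `genome_bp`.
#' @export
smc_power <- function(depth_target, depth_reference, threshold = 10L) {
  stopifnot(inherits(depth_target, "DepthProfile"),
            inherits(depth_reference, "DepthProfile"))
  ct <- names(depth_target$depths)
  cr <- names(depth_reference$depths)
  if (!setequal(ct, cr) ||
      !all(lengths(depth_target$depths)[ct] == lengths(depth_reference$depths)[ct])) {
    stop("smc_power(): profiles must assess the same region set")
  }
  callable <- 0L
  genome <- 0L
  for (ch in ct) {
    a <- depth_target$depths[[ch]]
    b <- depth_reference$depths[[ch]]
    callable <- callable + sum(a >= threshold & b >= threshold)
    genome <- genome + length(a)
  }
  structure(list(callable_bp = callable, threshold = as.integer(threshold),
                 genome_bp = genome),
            class = "PowerResult")
}

#' @export
print.PowerResult <- function(x, ...) {
  cat(sprintf("PowerResult: %d of %d bp callable (depth >= %d in both tissues)\n",
              x$callable_bp, x$genome_bp, x$threshold))
  invisible(x)
}

#' Mutational burden normalised by callable genome
#'
#' Calls per megabase over the SMC power: `count / (callable_bp / 1e6)`.
#'
#' @param callset a `CallSet` (or anything with `nrow()`), or an integer
#'   call count.
#' @param power a [smc_power()] result.
#' @return object of class `BurdenResult`: list with `n_calls`,
#'   `callable_mb`, `calls_per_mb`.
#' @export
burden <- function(callset, power) {
  stopifnot(inherits(power, "PowerResult"))
  n <- if (is.numeric(callset) && length(callset) == 1L) as.integer(callset)
       else nrow(callset)
  if (power$callable_bp == 0L) {
    stop("burden(): callable_bp is 0; burden per Mb undefined")
  }
  mb <- power$callable_bp / 1e6
  structure(list(n_calls = n, callable_mb = mb, calls_per_mb = n / mb),
            class = "BurdenResult")
}

#' @export
print.BurdenResult <- function(x, ...) {
  cat(sprintf("BurdenResult: %d call(s) / %.3f Mb callable = %.2f per Mb\n",
              x$n_calls, x$callable_mb, x$calls_per_mb))
  invisible(x)
}

#' Intermutation distances for rainfall analysis
#'
#' Distances between consecutive calls are computed within chromosomes only
#' (a chromosome with <= 1 call contributes no distance). For the rainfall
#' x-axis a genome-wide cumulative position is added using cumulative
#' chromosome offsets. Input order is irrelevant: calls are sorted first.
#'
#' @param callset a `CallSet` (or data frame with `chrom`, `pos`, and
#'   optionally `ref`, `alt` for the substitution class column).
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   the cumulative offsets; defaults to the maximum call position per
#'   chromosome.
#' @return object of class `ImdSeries`: data frame with `chrom`, `pos`,
#'   `cum_pos`, `imd` (`NA` for the first call of each chromosome) and
#'   `class` (substitution class, `NA` when alleles are unknown).
#' @export
imd <- function(callset, chrom_lengths = NULL) {
  df <- as.data.frame(callset)
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      cum_pos = numeric(), imd = integer(),
                      class = character())
    class(out) <- c("ImdSeries", "data.frame")
    return(out)
  }
  df <- df[order_positions(df$chrom, df$pos), , drop = FALSE]
  chroms <- unique(df$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(df$pos[df$chrom == ch])
    }, numeric(1))
  }
  # offsets in natural chromosome order
  ord <- chroms[order(chrom_rank(chroms))]
  offs <- stats::setNames(cumsum(c(0, as.numeric(chrom_lengths[ord])))[
    seq_along(ord)], ord)
  dist <- unlist(lapply(ord, function(ch) {
    p <- df$pos[df$chrom == ch]
    if (length(p) <= 1L) rep(NA_integer_, length(p))
    else c(NA_integer_, diff(p))
  }), use.names = FALSE)
  df2 <- df[order(match(df$chrom, ord), df$pos), , drop = FALSE]
  out <- data.frame(
    chrom = df2$chrom, pos = df2$pos,
    cum_pos = offs[df2$chrom] + df2$pos,
    imd = dist,
    class = if (!is.null(df2$ref)) substitution_class(df2$ref, df2$alt)
            else NA_character_
  )
  rownames(out) <- NULL
  class(out) <- c("ImdSeries", "data.frame")
  out
}
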