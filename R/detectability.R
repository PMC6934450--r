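#' Minimum cell fraction for a callable mutation
#'
#' At a caller's minimal VAF threshold `t`, a mutation carried on `c` of
#' `ploidy` chromosome copies is callable only when the carrying cell
#' fraction reaches `t * ploidy / c`, capped at 1. At the typical threshold
#' of 0.15, a heterozygous diploid mutation requires ~30% of the sampled
#' cells to carry it — the detection limit that polyclonal bulk samples
#' fail to reach.
#'
#' @param vaf_threshold minimal callable VAF, in (0, 1].
#' @param zygosity `"het"` (one copy) or `"hom"` (all copies).
#' @param ploidy copy number at the locus (default 2).
#' @return minimum carrying cell fraction, in (0, 1].
#' @export
#' @examples
#' min_cell_fraction(0.15, "het")  # 0.30
#' min_cell_fraction(0.15, "hom")  # 0.15
min_cell_fraction <- function(vaf_threshold, zygosity = c("het", "hom"),
                              ploidy = 2) {
  zygosity <- match.arg(zygosity)
  if (any(vaf_threshold <= 0) || any(vaf_threshold > 1)) {
    stop("vaf_threshold must lie in (0, 1]")
  }
  copies <- if (zygosity == "hom") ploidy else 1
  pmin(vaf_threshold * ploidy / copies, 1)
}

#' Probability of detecting a clone-private mutation at a given depth
#'
#' Exact binomial model of the detection limit: with a clone fraction `f`,
#' the expected VAF is `f * copies / ploidy` (copies = 1 for het, = ploidy
#' for hom) and the variant read count at depth `D` is
#' `X ~ Binomial(D, expected VAF)`. The mutation is detected when
#' `X >= max(m, ceiling(t * D))`, i.e. when the sampled VAF reaches the
#' caller threshold `t` with at least `m` supporting reads. The tail
#' probability is computed exactly (no normal approximation) via
#' [stats::pbinom()].
#'
#' @param f clone fraction in `[0, 1]`.
#' @param depth read depth `D >= 1`.
#' @param vaf_threshold caller VAF threshold `t` (default 0.15).
#' @param min_alt_reads minimum supporting reads `m` (default 3; `m = 0`
#'   recovers the pure-threshold model).
#' @param zygosity `"het"` or `"hom"`.
#' @param ploidy copy number (default 2).
#' @return detection probability (vectorised over `f` and `depth`).
#' @export
detection_probability <- function(f, depth, vaf_threshold = 0.15,
                                  min_alt_reads = 3L,
                                  zygosity = c("het", "hom"), ploidy = 2) {
  zygosity <- match.arg(zygosity)
  stopifnot(all(depth >= 1), all(f >= 0), all(f <= 1),
            vaf_threshold >= 0, vaf_threshold <= 1, min_alt_reads >= 0)
  n <- max(length(f), length(depth))
  f <- rep_len(f, n)
  depth <- rep_len(as.integer(depth), n)
  copies <- if (zygosity == "hom") ploidy else 1
  evaf <- pmin(f * copies / ploidy, 1)
  k_min <- pmax(as.integer(min_alt_reads), as.integer(ceiling(vaf_threshold * depth)))
  stats::pbinom(k_min - 1L, depth, evaf, lower.tail = FALSE)
}

#' Detection-probability surface over clone-fraction and depth grids
#'
#' Evaluates [detection_probability()] on the Cartesian product of a clone
#' fraction grid and a depth grid — the quantitative rendering of the
#' sampling-area / read-depth trade-off: calling succeeds only by sampling
#' fewer clones (raising `f`) and/or sequencing deeper (lowering the
#' detection limit).
#'
#' @param f_grid clone fractions.
#' @param depth_grid read depths.
#' @param vaf_threshold,min_alt_reads,zygosity,ploidy see
#'   [detection_probability()].
#' @return data frame `f`, `depth`, `p_detect`, one row per grid pair.
#' @export
detectability_curve <- function(f_grid, depth_grid, vaf_threshold = 0.15,
                                min_alt_reads = 3L,
                                zygosity = c("het", "hom"), ploidy = 2) {
  stopifnot(length(f_grid) > 0, length(depth_grid) > 0)
  zygosity <- match.arg(zygosity)
  grid <- expand.grid(f = f_grid, depth = depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$p_detect <- detection_probability(
    grid$f, grid$depth, vaf_threshold = vaf_threshold,
    min_alt_reads = min_alt_reads, zygosity = zygosity, ploidy = ploidy
  )
  grid
}
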