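#' Construct a clone mixture model of a polyclonal tissue sample
#'
#' A bulk brush-style sample is modelled as a mixture of cellular clones of
#' recent common origin. Every cell carries the subject's germline variants;
#' each clone additionally carries its private somatic mutations. An
#' infiltrate fraction models cells (e.g. immune cells) carrying no somatic
#' mutations. For a clone of fraction `f`, a heterozygous private mutation
#' has expected variant allele frequency `f / 2` in the diploid bulk sample
#' — the dilution that puts clone-private mutations below the callers'
#' detection limit in highly polyclonal tissue.
#'
#' @param subject subject identifier.
#' @param clones list of clones, each a list with elements `fraction`
#'   (in (0, 1]) and `mutations` (data frame `chrom`, `pos`, `zygosity`
#'   with zygosity `"het"` or `"hom"`).
#' @param germline data frame (`chrom`, `pos`, `zygosity`) of germline
#'   variants shared by all clones and by the reference tissue. An optional
#'   logical column `hidden` marks heterozygous variants whose blood
#'   evidence is lost in the sequencing data, so callers miscall them as
#'   somatic (default `FALSE`).
#' @param infiltrate_fraction fraction of sampled cells carrying no somatic
#'   mutations; clone fractions plus infiltrate must sum to 1 (tolerance
#'   1e-9).
#' @param genome_length genome slice length in bp (single chromosome model
#'   unless mutations name several chromosomes).
#' @return object of class `CloneMixture`.
#' @export
clone_mixture <- function(subject, clones, germline =
                            data.frame(chrom = character(), pos = integer(),
                                       zygosity = character()),
                          infiltrate_fraction = 0, genome_length = 1e6) {
  fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (any(fr <= 0 | fr > 1)) stop("clone fractions must lie in (0, 1]")
  tot <- sum(fr) + infiltrate_fraction
  if (abs(tot - 1) > 1e-9) {
    stop("clone fractions + infiltrate_fraction must sum to 1 (got ",
         format(tot), ")")
  }
  if (is.null(germline$hidden)) {
    germline$hidden <- rep(FALSE, nrow(germline))
  }
  germ_key <- pos_key(germline$chrom, germline$pos)
  for (cl in clones) {
    if (any(pos_key(cl$mutations$chrom, cl$mutations$pos) %in% germ_key)) {
      stop("clone-private mutation positions must be disjoint from germline")
    }
  }
  structure(
    list(subject = subject, clones = clones, germline = germline,
         infiltrate_fraction = infiltrate_fraction,
         genome_length = as.integer(genome_length)),
    class = "CloneMixture"
  )
}

#' @export
print.CloneMixture <- function(x, ...) {
  cat(sprintf(
    "CloneMixture subject=%s: %d clone(s) (fractions %s), %d germline variant(s), infiltrate %.2f\n",
    x$subject, length(x$clones),
    paste(sprintf("%.3f", vapply(x$clones, `[[`, numeric(1), "fraction")),
          collapse = ", "),
    nrow(x$germline), x$infiltrate_fraction
  ))
  invisible(x)
}

#' All clone-private somatic mutations of a mixture
#' @param mixture a `CloneMixture`.
#' @return data frame `chrom`, `pos`, `zygosity`, `clone_fraction`.
#' @export
somatic_truth <- function(mixture) {
  stopifnot(inherits(mixture, "CloneMixture"))
  parts <- lapply(mixture$clones, function(cl) {
    if (nrow(cl$mutations) == 0L) return(NULL)
    cbind(cl$mutations, clone_fraction = cl$fraction)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      zygosity = character(), clone_fraction = numeric())
  }
  out[order_positions(out$chrom, out$pos), , drop = FALSE]
}

#' Expected variant allele frequency at a position in a mixture
#'
#' In the reference tissue (blood) only germline variants contribute
#' (heterozygous 0.5, homozygous 1.0). In the target tissue a clone-private
#' mutation carried by clone fraction `f` contributes `f/2` (het) or `f`
#' (hom); germline variants contribute as in blood. Positions without any
#' variant have expected VAF 0.
#'
#' @param mixture a `CloneMixture`.
#' @param chrom,pos genomic position (vectors allowed).
#' @param tissue `"target"` (brush) or `"reference"` (blood).
#' @return numeric vector of expected VAFs in `[0, 1]`.
#' @export
expected_vaf <- function(mixture, chrom, pos, tissue = c("target", "reference")) {
  stopifnot(inherits(mixture, "CloneMixture"))
  tissue <- match.arg(tissue)
  key <- pos_key(chrom, pos)
  ev <- numeric(length(key))
  if (nrow(mixture$germline) > 0L) {
    gk <- pos_key(mixture$germline$chrom, mixture$germline$pos)
    m <- match(key, gk)
    hit <- !is.na(m)
    ev[hit] <- ifelse(mixture$germline$zygosity[m[hit]] == "hom", 1.0, 0.5)
  }
  if (tissue == "target") {
    for (cl in mixture$clones) {
      if (nrow(cl$mutations) == 0L) next
      mk <- pos_key(cl$mutations$chrom, cl$mutations$pos)
      m <- match(key, mk)
      hit <- !is.na(m)
      copies <- ifelse(cl$mutations$zygosity[m[hit]] == "hom", 2, 1)
      ev[hit] <- ev[hit] + cl$fraction * copies / 2
    }
  }
  pmin(ev, 1)
}
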