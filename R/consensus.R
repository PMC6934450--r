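#' Combine per-caller call sets into a consensus
#'
#' Implements the conservative multi-caller strategy: rather than unifying
#' results or applying post-calling filters, calls are matched across
#' callers on position alone (chromosome, 1-based position; alleles are
#' ignored by default) and combined by set algebra. `intersection_all`
#' keeps positions called by every caller — the strategy that trades a
#' marginal recall loss for a material precision gain; `union` keeps any
#' call; `k_of_n` keeps positions called by at least `k` callers
#' (`k_of_n(1)` is the union, `k_of_n(n)` the full intersection).
#'
#' Attributes (VAF, depths) of a consensus call are taken from a configured
#' reporting caller (default: the last call set supplied, conventionally the
#' restrictive one), falling back to the first caller that saw the position.
#'
#' @param callsets list of >= 2 `CallSet`s from the same subject x tissue.
#' @param strategy `"intersection_all"`, `"union"` or `"k_of_n"`.
#' @param k minimum caller count for `"k_of_n"`.
#' @param reporting_caller name of the caller whose per-call attributes are
#'   reported; default the caller of the last call set.
#' @param strict_alleles if `TRUE`, match on (chrom, pos, ref, alt) instead
#'   of position only (off by default, matching the method's definition).
#' @return object of class `ConsensusResult`: list with elements `strategy`,
#'   `calls` (a `CallSet` with caller `"consensus"`), `per_caller_counts`,
#'   and `venn` (data frame of caller-membership pattern counts).
#' @export
combine_callsets <- function(callsets,
                             strategy = c("intersection_all", "union", "k_of_n"),
                             k = 2L, reporting_caller = NULL,
                             strict_alleles = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(length(callsets) >= 2L,
            all(vapply(callsets, inherits, logical(1), "CallSet")))
  subjects <- unique(vapply(callsets, cs_subject, character(1)))
  tissues <- unique(vapply(callsets, cs_tissue, character(1)))
  if (length(subjects) != 1L || length(tissues) != 1L) {
    stop("combine_callsets(): call sets must come from one subject x tissue")
  }
  callers <- vapply(callsets, cs_caller, character(1))
  if (anyDuplicated(callers)) stop("duplicate caller identifiers")
  names(callsets) <- callers
  n <- length(callsets)
  k_needed <- switch(strategy,
    intersection_all = n,
    union = 1L,
    k_of_n = {
      if (k < 1L || k > n) stop("k must be in 1..", n)
      as.integer(k)
    }
  )

  keyfun <- function(cs) {
    if (strict_alleles) paste(pos_key(cs$chrom, cs$pos), cs$ref, cs$alt)
    else pos_key(cs$chrom, cs$pos)
  }
  keys <- lapply(callsets, keyfun)
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(kk) all_keys %in% kk,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, callers))
  support <- rowSums(member)
  selected_keys <- all_keys[support >= k_needed]

  if (is.null(reporting_caller)) reporting_caller <- callers[n]
  if (!reporting_caller %in% callers) {
    stop("reporting_caller '", reporting_caller, "' not among inputs")
  }
  # attribute lookup: reporting caller first, then the remaining callers
  pref <- c(reporting_caller, setdiff(callers, reporting_caller))
  pick_rows <- function(key_sel) {
    remaining <- key_sel
    out <- list()
    for (cl in pref) {
      if (length(remaining) == 0L) break
      cs <- callsets[[cl]]
      m <- match(remaining, keyfun(cs))
      hit <- !is.na(m)
      if (any(hit)) {
        out[[cl]] <- as.data.frame(cs)[m[hit], , drop = FALSE]
        remaining <- remaining[!hit]
      }
    }
    do.call(rbind, out)
  }
  calls_df <- if (length(selected_keys) > 0L) pick_rows(selected_keys) else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character())
  }
  consensus <- suppressMessages(call_set(
    calls_df, subject = subjects, tissue = tissues, caller = "consensus"
  ))

  if (length(all_keys) > 0L) {
    pattern <- apply(member, 1L, function(r) paste(callers[r], collapse = "&"))
    venn <- as.data.frame(table(pattern = pattern), stringsAsFactors = FALSE)
    names(venn) <- c("pattern", "count")
    venn$count <- as.integer(venn$count)
  } else {
    venn <- data.frame(pattern = character(), count = integer())
  }
  structure(
    list(strategy = if (strategy == "k_of_n") sprintf("k_of_n(%d)", k_needed)
                    else strategy,
         calls = consensus,
         per_caller_counts = vapply(callsets, nrow, integer(1)),
         venn = venn),
    class = "ConsensusResult"
  )
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult (%s): %d call(s)\n", x$strategy, nrow(x$calls)))
  cat("per-caller counts:",
      paste(names(x$per_caller_counts), x$per_caller_counts,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Dice similarity coefficient between two call sets
#'
#' `S = 2 * |A intersect B| / (|A| + |B|)` with matching on position only.
#' When both sets are empty the coefficient is undefined: `NA` is returned
#' with a warning.
#'
#' @param a,b `CallSet`s (or data frames with `chrom`, `pos`).
#' @return similarity in `[0, 1]`, or `NA` if both sets are empty.
#' @export
#' @examples
#' a <- call_set(data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "C"))
#' b <- call_set(data.frame(chrom = "1", pos = 3:8, ref = "A", alt = "C"))
#' dice(a, b)  # 2*2 / (4+6) = 0.4
dice <- function(a, b) {
  ka <- pos_key(a$chrom, a$pos)
  kb <- pos_key(b$chrom, b$pos)
  if (length(ka) == 0L && length(kb) == 0L) {
    warning("dice(): both call sets empty; coefficient undefined")
    return(NA_real_)
  }
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

#' Evaluate a call set against a truth set of positions
#'
#' Sensitivity (recall) and precision (positive predictive value) are based
#' solely on the predicted position, without considering mutation type:
#' `tp = |calls intersect truth|`, `fp = |calls \ truth|`,
#' `fn = |truth \ calls|`. An empty call set has precision reported as 0 by
#' convention, with a warning; recall is computed normally.
#'
#' @param callset a `CallSet` (or data frame with `chrom`, `pos`).
#' @param truth data frame with columns `chrom`, `pos`.
#' @return object of class `EvaluationResult`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_calls <- function(callset, truth) {
  kc <- unique(pos_key(callset$chrom, callset$pos))
  kt <- unique(pos_key(truth$chrom, truth$pos))
  tp <- length(intersect(kc, kt))
  fp <- length(setdiff(kc, kt))
  fn <- length(setdiff(kt, kc))
  if (length(kc) == 0L) {
    warning("evaluate_calls(): empty call set; precision reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult: tp=%d fp=%d fn=%d precision=%.4f recall=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}
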