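#' Select verification candidates under the study constraints
#'
#' From tiered, annotated calls, selects up to `n_per_tier` candidates per
#' confidence tier for amplicon re-sequencing, subject to:
#'
#' * calls on the Y chromosome are never eligible;
#' * all calls with functional class `nonsynonymous` or `splice_site` are
#'   force-included (counting against their own tier's quota);
#' * every subject with at least one eligible call contributes at least one
#'   selected call overall (greedy repair: subjects processed in sorted
#'   order, one random eligible call each, placed in its own tier's quota);
#' * the remaining quota per tier is filled by uniform sampling without
#'   replacement.
#'
#' Selection is deterministic under `seed`. A tier with fewer eligible calls
#' than the quota is taken in full, with a warning; a subject whose only
#' calls lie on chrY cannot be represented, with a warning.
#'
#' @param annotated data frame from [annotate_calls()] (needs columns
#'   `chrom`, `pos`, `subject`, `tier`, `functional_class`).
#' @param n_per_tier per-tier quota (default 30).
#' @param seed integer seed.
#' @return object of class `CandidateSet`: list with `candidates` (the
#'   selected rows plus a `forced` flag), `seed`, and `report` (forced
#'   inclusions, per-subject coverage, exclusions, warnings).
#' @export
select_candidates <- function(annotated, n_per_tier = 30L, seed = 1L) {
  stopifnot(all(c("chrom", "pos", "subject", "tier", "functional_class") %in%
                  names(annotated)))
  set.seed(seed)
  df <- as.data.frame(annotated)
  df$.row <- seq_len(nrow(df))
  on_y <- norm_chrom(df$chrom) == "Y"
  eligible <- df[!on_y, , drop = FALSE]
  report <- list(n_excluded_chry = sum(on_y), warnings = character(0))

  tiers <- c("high", "medium", "low")
  if (nrow(eligible) == 0L) stop("select_candidates(): no eligible calls")

  forced <- eligible$functional_class %in% c("nonsynonymous", "splice_site")
  selected <- eligible$.row[forced]
  report$n_forced <- sum(forced)

  # subject-coverage repair, deterministic order
  all_subjects <- sort(unique(df$subject))
  for (subj in all_subjects) {
    pool <- eligible[eligible$subject == subj, , drop = FALSE]
    if (nrow(pool) == 0L) {
      msg <- paste0("subject '", subj,
                    "' has no eligible (non-chrY) calls; cannot be represented")
      warning(msg)
      report$warnings <- c(report$warnings, msg)
      next
    }
    if (!any(pool$.row %in% selected)) {
      selected <- c(selected, pool$.row[sample.int(nrow(pool), 1L)])
    }
  }

  # fill remaining quota per tier by uniform sampling without replacement
  for (ti in tiers) {
    in_tier <- eligible[eligible$tier == ti, , drop = FALSE]
    chosen <- sum(in_tier$.row %in% selected)
    avail <- in_tier[!in_tier$.row %in% selected, , drop = FALSE]
    n_need <- n_per_tier - chosen
    if (nrow(in_tier) < n_per_tier) {
      msg <- sprintf("tier '%s' has only %d eligible call(s) (< quota %d): all selected",
                     ti, nrow(in_tier), n_per_tier)
      warning(msg)
      report$warnings <- c(report$warnings, msg)
    }
    if (n_need > 0L && nrow(avail) > 0L) {
      take <- min(n_need, nrow(avail))
      selected <- c(selected, avail$.row[sample.int(nrow(avail), take)])
    }
  }

  cand <- df[df$.row %in% selected, , drop = FALSE]
  cand$forced <- cand$functional_class %in% c("nonsynonymous", "splice_site")
  cand$.row <- NULL
  cand <- cand[order(match(cand$tier, tiers),
                     chrom_rank(cand$chrom), cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  report$per_tier <- table(factor(cand$tier, levels = tiers))
  report$per_subject <- table(cand$subject)
  structure(list(candidates = cand, seed = as.integer(seed), report = report),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: %d candidate(s) (seed %d); per tier: %s\n",
              nrow(x$candidates), x$seed,
              paste(names(x$report$per_tier), x$report$per_tier,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Classify an amplicon pileup VAF
#'
#' The decision matrix for a verification measurement at one position in one
#' sample:
#'
#' * VAF < 1% supports the reference allele (`"reference"`);
#' * VAF in \[20%, 80%\] suggests a heterozygous variant (`"heterozygous"`);
#' * VAF > 80% a homozygous variant (`"homozygous"`);
#' * VAF in \[5%, 20%) at good coverage (depth > `good_coverage`, default
#'   1000) suggests subclonal presence (`"subclonal"`);
#' * everything else — VAF in \[1%, 5%), or \[5%, 20%) at suboptimal
#'   coverage — is `"indeterminate"` and must be adjudicated against the
#'   other samples ([adjudicate()]).
#'
#' Depth 0 yields the distinct no-data marker `"no_data"`.
#'
#' @param vaf variant allele frequency vector in `[0, 1]`.
#' @param depth read depth vector.
#' @param good_coverage depth above which 5-20% VAFs count as subclonal.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_vaf(0.5, 5000)    # heterozygous
#' classify_vaf(0.10, 2000)   # subclonal
#' classify_vaf(0.10, 300)    # indeterminate
#' classify_vaf(0.03, 20000)  # indeterminate
classify_vaf <- function(vaf, depth, good_coverage = 1000L) {
  n <- max(length(vaf), length(depth))
  vaf <- rep_len(vaf, n)
  depth <- rep_len(depth, n)
  out <- character(n)
  out[depth == 0L] <- "no_data"
  ok <- depth > 0L
  v <- vaf[ok]
  cls <- ifelse(v < 0.01, "reference",
         ifelse(v >= 0.20 & v <= 0.80, "heterozygous",
         ifelse(v > 0.80, "homozygous",
         ifelse(v >= 0.05 & v < 0.20 & depth[ok] > good_coverage, "subclonal",
                "indeterminate"))))
  out[ok] <- cls
  out
}

#' Adjudicate indeterminate VAF classes against the other samples
#'
#' The automated counterpart of the manual review step: an indeterminate
#' observation at a position is compared with the same position in all other
#' samples. With `b` the median VAF across the other samples, the
#' observation resolves to `"reference"` (a shared background signal) when
#' its VAF is at most `max(bg_factor * b, floor_vaf)`, and to `"subclonal"`
#' (sample-elevated signal) otherwise. A position observed in only one
#' sample cannot be adjudicated: the class stays `"indeterminate"` and the
#' observation is flagged unresolved.
#'
#' @param observations data frame for one candidate position across samples:
#'   columns `subject`, `tissue`, `vaf`, `depth`, and `class` (from
#'   [classify_vaf()]).
#' @param bg_factor multiplier on the median background VAF (default 2).
#' @param floor_vaf background floor (default 0.01).
#' @return the input data frame with `class` resolved where possible, plus
#'   columns `resolved` (logical) and `evidence` (the background median used).
#' @export
adjudicate <- function(observations, bg_factor = 2, floor_vaf = 0.01) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("subject", "tissue", "vaf", "depth", "class") %in% names(obs)))
  obs$resolved <- obs$class != "indeterminate"
  obs$evidence <- NA_real_
  idx <- which(obs$class == "indeterminate")
  for (i in idx) {
    others <- obs$vaf[-i]
    others <- others[!is.na(others)]
    if (length(others) == 0L) next  # single-sample position: stays flagged
    b <- stats::median(others)
    obs$evidence[i] <- b
    obs$class[i] <- if (obs$vaf[i] <= max(bg_factor * b, floor_vaf)) {
      "reference"
    } else {
      "subclonal"
    }
    obs$resolved[i] <- TRUE
  }
  obs
}

#' Assign the verification outcome for one candidate
#'
#' Given the adjudicated VAF classes of one candidate position across all
#' samples, assigns the outcome category for the target subject:
#'
#' * `confirmed_somatic` — subclonal in the target subject's brush,
#'   reference in their blood, and no sample of any other subject shows the
#'   variant (subject-specific);
#' * `germline_polymorphism` — heterozygous or homozygous in both target
#'   tissues (~50% or ~100% VAF everywhere);
#' * `subclonal_shared` — variant present in both target tissues, or
#'   subclonal in samples of multiple subjects (mosaicism or allele-specific
#'   sequencing bias);
#' * `absent` — reference in both target tissues (sequencing or mapping
#'   inaccuracies in the original call);
#' * `unclear` — missing, no-data or unresolved-indeterminate observations
#'   in the target tissues, or a class pattern matching none of the above.
#'
#' @param classes data frame with columns `subject`, `tissue`, `class` for
#'   one candidate position (output of [adjudicate()]).
#' @param target_subject the subject in whom the call was made.
#' @param target_tissue the affected-tissue label (default `"lower_lobe"`).
#' @return a single outcome string.
#' @export
assign_outcome <- function(classes, target_subject,
                           target_tissue = "lower_lobe") {
  cl <- as.data.frame(classes)
  variant_classes <- c("subclonal", "heterozygous", "homozygous")
  brush <- cl$class[cl$subject == target_subject & cl$tissue == target_tissue]
  blood <- cl$class[cl$subject == target_subject & cl$tissue == "blood"]
  if (length(brush) != 1L || length(blood) != 1L) return("unclear")
  if (brush %in% c("no_data", "indeterminate") ||
      blood %in% c("no_data", "indeterminate")) return("unclear")

  others <- cl[cl$subject != target_subject, , drop = FALSE]
  others_variant <- any(others$class %in% variant_classes)
  n_subclonal_subjects <- length(unique(
    cl$subject[cl$class == "subclonal"]))

  if (brush %in% c("heterozygous", "homozygous") &&
      blood %in% c("heterozygous", "homozygous")) {
    return("germline_polymorphism")
  }
  if (brush == "reference" && blood == "reference") return("absent")
  if (brush == "subclonal" && blood == "reference" && !others_variant) {
    return("confirmed_somatic")
  }
  if ((brush %in% variant_classes && blood %in% variant_classes) ||
      n_subclonal_subjects >= 2L) {
    return("subclonal_shared")
  }
  "unclear"
}

#' Verify a candidate set against amplicon pileups
#'
#' Runs the full verification for every candidate: classify each sample's
#' pileup VAF ([classify_vaf()]), adjudicate indeterminates across samples
#' ([adjudicate()]), and assign the outcome category for the candidate's
#' subject ([assign_outcome()]). Candidates without any pileup observation
#' (e.g. failed PCRs) are dropped with a message, mirroring the tested
#' counts being smaller than the selected counts.
#'
#' @param candidates data frame with `chrom`, `pos`, `subject`, `tier`.
#' @param pileups data frame from [simulate_pileups()] (or a TSV with the
#'   same columns: `subject`, `tissue`, `chrom`, `pos`, `depth`,
#'   `alt_count`).
#' @param good_coverage passed to [classify_vaf()].
#' @param target_tissue affected-tissue label.
#' @param bg_factor,floor_vaf passed to [adjudicate()].
#' @return data frame: the candidate columns plus `outcome`, and attribute
#'   `class_matrix` (long data frame of per-sample classes — the
#'   presence/absence matrix of the verification experiment).
#' @export
verify_candidates <- function(candidates, pileups, good_coverage = 1000L,
                              target_tissue = "lower_lobe",
                              bg_factor = 2, floor_vaf = 0.01) {
  cand <- as.data.frame(candidates)
  pu <- as.data.frame(pileups)
  if (is.null(pu$vaf)) {
    pu$vaf <- ifelse(pu$depth > 0, pu$alt_count / pu$depth, NA_real_)
  }
  pu$class <- classify_vaf(pu$vaf, pu$depth, good_coverage)
  key_c <- pos_key(cand$chrom, cand$pos)
  key_p <- pos_key(pu$chrom, pu$pos)

  outcomes <- character(nrow(cand))
  class_rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(cand))) {
    obs <- pu[key_p == key_c[i], , drop = FALSE]
    if (nrow(obs) == 0L) {
      outcomes[i] <- NA_character_
      dropped <- dropped + 1L
      next
    }
    obs <- adjudicate(obs, bg_factor = bg_factor, floor_vaf = floor_vaf)
    outcomes[i] <- assign_outcome(obs, cand$subject[i], target_tissue)
    class_rows[[i]] <- cbind(candidate = key_c[i],
                             obs[, c("subject", "tissue", "vaf", "depth",
                                     "class", "resolved")])
  }
  if (dropped > 0L) {
    message(dropped, " candidate(s) without pileup data dropped from testing")
  }
  out <- cand[!is.na(outcomes), , drop = FALSE]
  out$outcome <- outcomes[!is.na(outcomes)]
  attr(out, "class_matrix") <- do.call(rbind, class_rows)
  out
}

#' Tabulate verification outcomes by confidence tier
#'
#' Builds the outcome x tier contingency table of the verification
#' experiment, with per-tier tested counts and the proportion falling in
#' each outcome category.
#'
#' @param outcomes data frame with columns `tier` and `outcome` (from
#'   [verify_candidates()], or constructed directly from reported counts).
#' @return list with `counts` (outcome x tier matrix), `tested` (per-tier
#'   column sums) and `proportions` (counts / tested).
#' @export
outcome_table <- function(outcomes) {
  tiers <- c("high", "medium", "low")
  cats <- c("confirmed_somatic", "subclonal_shared", "germline_polymorphism",
            "unclear", "absent")
  counts <- table(factor(outcomes$outcome, levels = cats),
                  factor(outcomes$tier, levels = tiers))
  counts <- unclass(counts)
  tested <- colSums(counts)
  proportions <- sweep(counts, 2L, pmax(tested, 1L), "/")
  proportions[, tested == 0L] <- NA_real_
  list(counts = counts, tested = tested, proportions = proportions)
}

#' Extrapolate confirmed counts to a genome-wide false-positive estimate
#'
#' Scales the per-tier confirmed fraction linearly to the tier's total call
#' count: `estimated_true = confirmed / tested * tier_total` (0 when the
#' tier has no calls). The overall false-positive fraction is
#' `1 - sum(estimated_true) / sum(tier_totals)`. A tier with calls but no
#' tested candidates leaves the estimate undefined and is an error.
#'
#' @param confirmed integer vector of confirmed counts per tier.
#' @param tested integer vector of tested counts per tier.
#' @param tier_totals integer vector of total calls per tier.
#' @return object of class `ExtrapolationResult`: list with `per_tier`
#'   (data frame `tested`, `confirmed`, `tier_total`, `estimated_true`),
#'   `estimated_true_total`, `fp_fraction`.
#' @export
#' @examples
#' # one confirmed call of 28/29/28 tested, scaled to 156/711/784 total calls
#' ex <- extrapolate(c(1, 0, 0), c(28, 29, 28), c(156, 711, 784))
#' ex$fp_fraction  # > 0.99
extrapolate <- function(confirmed, tested, tier_totals) {
  stopifnot(length(confirmed) == length(tested),
            length(tested) == length(tier_totals))
  if (any(confirmed > tested)) stop("confirmed cannot exceed tested")
  bad <- tier_totals > 0 & tested == 0
  if (any(bad)) {
    stop("extrapolate(): tier(s) with calls but no tested candidates: ",
         "estimate undefined")
  }
  est <- ifelse(tier_totals == 0, 0, confirmed / pmax(tested, 1) * tier_totals)
  structure(
    list(
      per_tier = data.frame(tested = tested, confirmed = confirmed,
                            tier_total = tier_totals, estimated_true = est),
      estimated_true_total = sum(est),
      fp_fraction = 1 - sum(est) / sum(tier_totals)
    ),
    class = "ExtrapolationResult"
  )
}

#' @export
print.ExtrapolationResult <- function(x, ...) {
  cat(sprintf(
    "ExtrapolationResult: %.2f estimated true calls of %d total (FP fraction %.4f)\n",
    x$estimated_true_total, sum(x$per_tier$tier_total), x$fp_fraction))
  invisible(x)
}
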