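# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# quick CallSet from positions only
make_callset <- function(pos, chrom = "1", subject = "s01",
                         tissue = "lower_lobe", caller = "toy", ...) {
  n <- length(pos)
  suppressMessages(call_set(
    data.frame(chrom = rep_len(chrom, n), pos = pos, ref = rep_len("A", n),
               alt = rep_len("C", n), ...),
    subject = subject, tissue = tissue, caller = caller
  ))
}

# brute-force membership oracle for interval queries: linear scan over the
# raw (0-based half-open) intervals, independent of the Track implementation
bruteforce_member <- function(chrom, pos, iv) {
  vapply(seq_along(pos), function(i) {
    p0 <- pos[i] - 1L  # 1-based query to 0-based
    any(iv$chrom == chrom[i] & iv$start <= p0 & p0 < iv$end)
  }, logical(1))
}

# mixture with a single clone of fraction f (plus infiltrate) carrying
# `n_mut` het mutations, and `n_germ` germline variants
single_clone_mixture <- function(f, n_mut = 10, n_germ = 0, subject = "s01",
                                 genome_length = 1e5, zygosity = "het",
                                 germ_zygosity = "het", seed = 42) {
  set.seed(seed)
  pos <- sample.int(genome_length, n_mut + n_germ)
  germ <- if (n_germ > 0) {
    data.frame(chrom = "1", pos = sort(pos[seq_len(n_germ)]),
               zygosity = germ_zygosity)
  } else {
    data.frame(chrom = character(), pos = integer(), zygosity = character())
  }
  clone_mixture(
    subject,
    clones = list(list(
      fraction = f,
      mutations = data.frame(chrom = "1",
                             pos = sort(pos[n_germ + seq_len(n_mut)]),
                             zygosity = zygosity)
    )),
    germline = germ,
    infiltrate_fraction = 1 - f,
    genome_length = genome_length
  )
}

# synthetic annotated-call table for candidate selection tests:
# n_subjects subjects, per-tier eligible counts, a few forced functional
# calls, optionally some chrY calls
make_tiered_calls <- function(n_per_tier_eligible = 40, n_subjects = 12,
                              n_forced = 4, n_chry = 9, seed = 1) {
  set.seed(seed)
  tiers <- c("high", "medium", "low")
  df <- do.call(rbind, lapply(tiers, function(ti) {
    data.frame(
      chrom = "1",
      pos = sample.int(1e6, n_per_tier_eligible),
      subject = rep_len(sprintf("s%02d", seq_len(n_subjects)),
                        n_per_tier_eligible),
      tier = ti,
      functional_class = "other"
    )
  }))
  forced_idx <- sample.int(nrow(df), n_forced)
  df$functional_class[forced_idx] <- rep_len(c("nonsynonymous", "splice_site"),
                                             n_forced)
  if (n_chry > 0) {
    y <- data.frame(
      chrom = "chrY", pos = sample.int(1e6, n_chry),
      subject = rep_len(sprintf("s%02d", seq_len(n_subjects)), n_chry),
      tier = rep_len(tiers, n_chry), functional_class = "other"
    )
    df <- rbind(df, y)
  }
  df
}

# checks every selection constraint; returns character(0) when all hold
check_selection_constraints <- function(sel, calls, n_per_tier = 30) {
  cand <- sel$candidates
  problems <- character(0)
  for (ti in c("high", "medium", "low")) {
    n_el <- sum(calls$tier == ti & norm_chrom(calls$chrom) != "Y")
    n_sel <- sum(cand$tier == ti)
    if (n_sel != min(n_per_tier, n_el)) {
      problems <- c(problems, sprintf("tier %s: %d selected", ti, n_sel))
    }
  }
  if (any(norm_chrom(cand$chrom) == "Y")) problems <- c(problems, "chrY selected")
  forced <- calls[calls$functional_class %in% c("nonsynonymous", "splice_site") &
                    norm_chrom(calls$chrom) != "Y", ]
  fk <- paste(forced$chrom, forced$pos, forced$subject)
  ck <- paste(cand$chrom, cand$pos, cand$subject)
  if (!all(fk %in% ck)) problems <- c(problems, "forced call missing")
  subj_eligible <- unique(calls$subject[norm_chrom(calls$chrom) != "Y"])
  if (!all(subj_eligible %in% cand$subject)) {
    problems <- c(problems, "subject without representation")
  }
  problems
}
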