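#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the analysis in one auditable place: the
#' simulation conditions, the clone-mixture specification, the three caller
#' personalities, the consensus strategy, the depth threshold of the SMC
#' power, the per-tier verification quota, the VAF decision-matrix
#' good-coverage cutoff, and the adjudication coefficients.
#'
#' @param sim a [sim_config()].
#' @param clone_spec clone specification passed to [simulate_mixture()];
#'   the default emulates a polyclonal brushing (many small clones). For a
#'   cancer-like regime pass e.g. `list(fractions = 0.9,
#'   infiltrate_fraction = 0.1, muts_per_clone = 50)`.
#' @param caller_profiles named list of [caller_profile()]s (>= 2).
#' @param consensus_strategy `"intersection_all"`, `"union"` or `"k_of_n"`.
#' @param k consensus `k` for `"k_of_n"`.
#' @param depth_threshold SMC-power depth threshold (default 10).
#' @param n_per_tier verification quota per confidence tier (default 30).
#' @param good_coverage pileup depth above which 5-20% VAFs count as
#'   subclonal (default 1000).
#' @param bg_factor,floor_vaf adjudication coefficients (see [adjudicate()]).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param outdir output directory (`NULL` = no files written).
#' @return object of class `RunConfig`.
#' @export
run_config <- function(sim = sim_config(), clone_spec = list(),
                       caller_profiles = caller_profiles_default(),
                       consensus_strategy = "intersection_all", k = 2L,
                       depth_threshold = 10L, n_per_tier = 30L,
                       good_coverage = 1000L, bg_factor = 2,
                       floor_vaf = 0.01, seed = sim$seed, outdir = NULL) {
  stopifnot(length(caller_profiles) >= 2L, n_per_tier >= 1L,
            depth_threshold >= 0L, good_coverage >= 1L)
  structure(
    list(sim = sim, clone_spec = clone_spec,
         caller_profiles = caller_profiles,
         consensus_strategy = consensus_strategy, k = as.integer(k),
         depth_threshold = as.integer(depth_threshold),
         n_per_tier = as.integer(n_per_tier),
         good_coverage = as.integer(good_coverage),
         bg_factor = bg_factor, floor_vaf = floor_vaf,
         seed = as.integer(seed), outdir = outdir),
    class = "RunConfig"
  )
}

#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates the whole method from one config: simulate clone mixtures
#' and annotation tracks; emulate each caller per subject; build the
#' consensus; annotate and tier the pooled consensus calls; compute SMC
#' power, per-Mb burden and intermutation distances; select verification
#' candidates under the constraints; simulate amplicon pileups; classify,
#' adjudicate and assign outcomes; and extrapolate confirmed counts to the
#' genome-wide false-positive estimate. Every stochastic stage draws its
#' seed deterministically from the master seed, so a rerun with the same
#' config is identical.
#'
#' @param config a [run_config()].
#' @return list of class `RunResult` with elements `mixtures`, `tracks`,
#'   `callsets`, `consensus` (per subject), `annotated` (pooled data frame),
#'   `tier_totals`, `power`, `burden`, `imd`, `candidates`, `pileups`,
#'   `outcomes`, `outcome_table`, `extrapolation`, `evaluation` (per subject
#'   consensus vs truth), and `manifest` (config snapshot, version, stage
#'   counts, output checksums when files were written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  sim <- config$sim
  base <- config$seed
  subjects <- sprintf("s%02d", seq_len(sim$n_subjects))

  tracks <- simulate_tracks(sim, seed = base + 1L)

  mixtures <- list()
  for (i in seq_along(subjects)) {
    mixtures[[subjects[i]]] <- simulate_mixture(sim, config$clone_spec,
                                                subject = subjects[i],
                                                seed = base + 10L + i)
  }
  # germline variants are catalogued polymorphisms: they join the SNP tracks
  tracks <- augment_snp_tracks(tracks, mixtures)

  callsets <- list()
  consensus <- list()
  evaluation <- list()
  annotated_parts <- list()
  power <- list()
  burden_res <- list()
  imd_res <- list()

  for (i in seq_along(subjects)) {
    subj <- subjects[i]
    reads <- sample_mutation_reads(mixtures[[subj]], sim,
                                   seed = base + 50L + i)
    artifacts <- simulate_artifacts(sim, tracks = tracks,
                                    seed = base + 70L + i)
    per_caller <- list()
    for (j in seq_along(config$caller_profiles)) {
      pr <- config$caller_profiles[[j]]
      per_caller[[pr$name]] <- emulate_caller(
        mixtures[[subj]], pr, sim, tracks = tracks, reads = reads,
        artifacts = artifacts, seed = base + 100L * i + j
      )
    }
    callsets[[subj]] <- per_caller
    cr <- combine_callsets(per_caller, strategy = config$consensus_strategy,
                           k = config$k)
    consensus[[subj]] <- cr
    truth <- somatic_truth(mixtures[[subj]])
    evaluation[[subj]] <- suppressWarnings(evaluate_calls(cr$calls, truth))

    dp_t <- simulate_depth_profile(sim, sim$depth_target_mean,
                                   seed = base + 500L + 2L * i)
    dp_r <- simulate_depth_profile(sim, sim$depth_reference_mean,
                                   seed = base + 500L + 2L * i + 1L)
    power[[subj]] <- smc_power(dp_t, dp_r, threshold = config$depth_threshold)
    burden_res[[subj]] <- burden(cr$calls, power[[subj]])
    imd_res[[subj]] <- imd(cr$calls,
                           chrom_lengths = stats::setNames(sim$genome_length,
                                                           sim$chrom))
    annotated_parts[[subj]] <- suppressWarnings(
      annotate_calls(cr$calls, tracks))
  }

  annotated <- do.call(rbind, annotated_parts)
  rownames(annotated) <- NULL
  tier_totals <- table(factor(annotated$tier,
                              levels = c("high", "medium", "low")))

  n_calls_total <- nrow(annotated)
  candidates <- NULL
  outcomes <- NULL
  otab <- NULL
  extrap <- NULL
  pileups <- NULL
  if (n_calls_total > 0L) {
    candidates <- suppressWarnings(select_candidates(
      annotated, n_per_tier = config$n_per_tier, seed = base + 2000L))
    cand_pos <- unique(candidates$candidates[, c("chrom", "pos")])
    pileups <- simulate_pileups(mixtures, cand_pos, sim, seed = base + 3000L)
    outcomes <- verify_candidates(candidates$candidates, pileups,
                                  good_coverage = config$good_coverage,
                                  bg_factor = config$bg_factor,
                                  floor_vaf = config$floor_vaf)
    otab <- outcome_table(outcomes)
    extrap <- extrapolate(
      confirmed = otab$counts["confirmed_somatic", ],
      tested = otab$tested,
      tier_totals = as.integer(tier_totals)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polyclonesmc")),
    seed = base,
    config = list(
      genome_length = sim$genome_length, n_subjects = sim$n_subjects,
      depth_target_mean = sim$depth_target_mean,
      depth_reference_mean = sim$depth_reference_mean,
      pileup_depth_mean = sim$pileup_depth_mean,
      error_rate = sim$error_rate,
      consensus_strategy = config$consensus_strategy,
      depth_threshold = config$depth_threshold,
      n_per_tier = config$n_per_tier,
      good_coverage = config$good_coverage,
      bg_factor = config$bg_factor, floor_vaf = config$floor_vaf,
      caller_profiles = lapply(config$caller_profiles, unclass)
    ),
    counts = list(
      per_caller = lapply(callsets, function(x) vapply(x, nrow, integer(1))),
      consensus_per_subject = vapply(consensus, function(x) nrow(x$calls),
                                     integer(1)),
      consensus_total = n_calls_total,
      tier_totals = as.list(tier_totals),
      n_candidates = if (!is.null(candidates)) nrow(candidates$candidates)
                     else 0L,
      n_tested = if (!is.null(otab)) as.list(otab$tested) else NULL,
      outcome_matrix = if (!is.null(otab)) otab$counts else NULL
    ),
    extrapolation = if (!is.null(extrap)) {
      list(estimated_true_total = extrap$estimated_true_total,
           fp_fraction = extrap$fp_fraction)
    } else NULL
  )

  result <- structure(
    list(mixtures = mixtures, tracks = tracks, callsets = callsets,
         consensus = consensus, annotated = annotated,
         tier_totals = tier_totals, power = power, burden = burden_res,
         imd = imd_res, candidates = candidates, pileups = pileups,
         outcomes = outcomes, outcome_table = otab, extrapolation = extrap,
         evaluation = evaluation, manifest = manifest),
    class = "RunResult"
  )

  if (!is.null(config$outdir)) {
    result$manifest$checksums <- write_run_outputs(result, config)
  }
  result
}

#' @export
print.RunResult <- function(x, ...) {
  cat(sprintf("RunResult: %d subject(s), %d consensus call(s); tiers %s\n",
              length(x$mixtures), nrow(x$annotated),
              paste(names(x$tier_totals), as.integer(x$tier_totals),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$extrapolation)) {
    cat(sprintf("  estimated FP fraction: %.4f\n",
                x$extrapolation$fp_fraction))
  }
  invisible(x)
}

# write all stage outputs + manifest JSON; returns named md5 checksums
write_run_outputs <- function(result, config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  for (subj in names(result$callsets)) {
    for (cl in names(result$callsets[[subj]])) {
      p <- file.path(outdir, sprintf("%s_%s.vcf", subj, cl))
      write_vcf(result$callsets[[subj]][[cl]], p, seed = config$seed)
      paths <- c(paths, p)
    }
    p <- file.path(outdir, sprintf("%s_consensus.vcf", subj))
    write_vcf(result$consensus[[subj]]$calls, p, seed = config$seed)
    paths <- c(paths, p)
    p <- file.path(outdir, sprintf("%s_truth.tsv", subj))
    write_truth_tsv(somatic_truth(result$mixtures[[subj]]), p)
    paths <- c(paths, p)
  }
  for (nm in names(result$tracks)) {
    p <- file.path(outdir, paste0("track_", nm, ".bed"))
    write_bed_track(result$tracks[[nm]], p)
    paths <- c(paths, p)
  }
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  tsv(result$annotated, "annotated_calls.tsv")
  if (!is.null(result$candidates)) {
    tsv(result$candidates$candidates, "candidates.tsv")
  }
  if (!is.null(result$pileups)) tsv(result$pileups, "pileups.tsv")
  if (!is.null(result$outcomes)) {
    tsv(result$outcomes, "outcomes.tsv")
    omat <- as.data.frame(result$outcome_table$counts)
    omat <- cbind(outcome = rownames(omat), omat)
    tsv(omat, "outcome_by_tier.tsv")
  }
  imd_all <- do.call(rbind, lapply(names(result$imd), function(s) {
    cbind(subject = s, as.data.frame(result$imd[[s]]))
  }))
  tsv(imd_all, "imd.tsv")
  bur <- data.frame(
    subject = names(result$burden),
    n_calls = vapply(result$burden, `[[`, integer(1), "n_calls"),
    callable_mb = vapply(result$burden, `[[`, numeric(1), "callable_mb"),
    calls_per_mb = round(
      vapply(result$burden, `[[`, numeric(1), "calls_per_mb"), 2)
  )
  tsv(bur, "burden.tsv")
  if (!is.null(result$extrapolation)) {
    p <- file.path(outdir, "extrapolation.json")
    jsonlite::write_json(
      list(per_tier = result$extrapolation$per_tier,
           estimated_true_total = result$extrapolation$estimated_true_total,
           fp_fraction = result$extrapolation$fp_fraction),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }

  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)
  manifest <- result$manifest
  manifest$checksums <- as.list(sums)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  as.list(sums)
}
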