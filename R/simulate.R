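#' Simulation configuration
#'
#' Bundles the study-condition parameters of the synthetic data generator.
#' Defaults mirror the medium-coverage whole-genome design the pipeline is
#' built for: mean read depth around 20x in the brush (target) tissue and
#' 27x in blood (reference), and amplicon re-sequencing pileups with mean
#' depth in the tens of thousands.
#'
#' @param genome_length genome slice length in bp.
#' @param n_subjects number of subjects to simulate.
#' @param depth_target_mean mean read depth, target tissue.
#' @param depth_reference_mean mean read depth, reference tissue.
#' @param seed integer seed recorded in every output header.
#' @param pileup_depth_mean mean amplicon pileup depth for verification.
#' @param dispersion negative-binomial size parameter for depth draws;
#'   `NULL` (default) uses the Poisson limit, `0` makes every depth draw
#'   exactly `round(mean)` (useful for exact binomial cross-checks).
#' @param error_rate per-base sequencing error rate adding variant reads at
#'   non-variant sites (default 0, which keeps the binomial oracles exact).
#' @param artifact_rate_per_mb rate of shared data artifacts per Mb —
#'   positions where the sequencing/mapping data themselves carry a spurious
#'   variant signal that every caller sees (unlike caller-private false
#'   positives, these survive the consensus intersection). Default 0.05/Mb,
#'   of the order of the consensus call burden observed in polyclonal
#'   brushings.
#' @param chrom chromosome name of the simulated slice.
#' @return object of class `SimulationConfig` (a named list).
#' @export
sim_config <- function(genome_length = 1e6, n_subjects = 12,
                       depth_target_mean = 20, depth_reference_mean = 27,
                       seed = 1L, pileup_depth_mean = 27000,
                       dispersion = NULL, error_rate = 0,
                       artifact_rate_per_mb = 0.05, chrom = "1") {
  stopifnot(genome_length > 0, n_subjects > 0, depth_target_mean > 0,
            depth_reference_mean > 0, pileup_depth_mean > 0, error_rate >= 0,
            artifact_rate_per_mb >= 0)
  structure(
    list(genome_length = as.integer(genome_length),
         n_subjects = as.integer(n_subjects),
         depth_target_mean = depth_target_mean,
         depth_reference_mean = depth_reference_mean,
         seed = as.integer(seed),
         pileup_depth_mean = pileup_depth_mean,
         dispersion = dispersion, error_rate = error_rate,
         artifact_rate_per_mb = artifact_rate_per_mb,
         chrom = as.character(chrom)),
    class = "SimulationConfig"
  )
}

#' Caller personality profile
#'
#' Emulates a somatic caller's behaviour with four parameters: the minimum
#' target-tissue VAF needed to emit a call, a false-positive rate per Mb, an
#' enrichment multiplier that places false positives preferentially on known
#' SNP positions (emulating the high dbSNP overlap of permissive callers on
#' real data), and a miss probability for otherwise detectable mutations.
#'
#' @param name caller identifier.
#' @param vaf_call_threshold minimum sampled target VAF to emit a call.
#' @param fp_rate_per_mb expected false positives per Mb.
#' @param fp_snp_enrichment multiplier for placing false positives on
#'   common-SNP positions (1 = uniform).
#' @param fn_rate miss probability for detectable true mutations.
#' @return object of class `CallerProfile`.
#' @export
caller_profile <- function(name, vaf_call_threshold = 0.15,
                           fp_rate_per_mb = 1.0, fp_snp_enrichment = 10,
                           fn_rate = 0.05) {
  stopifnot(vaf_call_threshold >= 0, vaf_call_threshold <= 1,
            fp_rate_per_mb >= 0, fp_snp_enrichment >= 0,
            fn_rate >= 0, fn_rate <= 1)
  structure(list(name = name, vaf_call_threshold = vaf_call_threshold,
                 fp_rate_per_mb = fp_rate_per_mb,
                 fp_snp_enrichment = fp_snp_enrichment, fn_rate = fn_rate),
            class = "CallerProfile")
}

#' Default trio of caller personalities
#'
#' Two permissive callers and one restrictive caller, echoing the observed
#' order-of-magnitude contrast in unfiltered call counts between common
#' somatic callers: the permissive pair emits ~10x more false positives per
#' Mb than the restrictive one.
#'
#' @return named list of three `CallerProfile`s.
#' @export
caller_profiles_default <- function() {
  list(
    permissive_a = caller_profile("permissive_a", vaf_call_threshold = 0.10,
                                  fp_rate_per_mb = 1.0, fp_snp_enrichment = 10,
                                  fn_rate = 0.02),
    permissive_b = caller_profile("permissive_b", vaf_call_threshold = 0.15,
                                  fp_rate_per_mb = 1.0, fp_snp_enrichment = 10,
                                  fn_rate = 0.02),
    restrictive = caller_profile("restrictive", vaf_call_threshold = 0.15,
                                 fp_rate_per_mb = 0.1, fp_snp_enrichment = 10,
                                 fn_rate = 0.02)
  )
}

# depth draw: Poisson (dispersion NULL), negative binomial (size = dispersion),
# or deterministic (dispersion 0: every draw equals round(mean))
rdepth <- function(n, mean, dispersion = NULL) {
  if (is.null(dispersion)) return(stats::rpois(n, mean))
  if (dispersion == 0) return(rep.int(as.integer(round(mean)), n))
  stats::rnbinom(n, size = dispersion, mu = mean)
}

# alt-read success probability including optional sequencing error
alt_prob <- function(evaf, error_rate) {
  pmin(1, evaf + (1 - evaf) * error_rate)
}

#' Simulate a clone mixture
#'
#' Draws a subject's clone mixture under a clone specification: clone
#' fractions (given explicitly or drawn from a symmetric Dirichlet and
#' rescaled to `1 - infiltrate_fraction`), clone-private heterozygous
#' mutations at uniformly sampled positions disjoint from the germline
#' background, and germline het/hom variants shared by all cells.
#'
#' @param config a [sim_config()].
#' @param clone_spec list with elements: `fractions` (explicit clone
#'   fractions, or `NULL` to draw), `n_clones`, `concentration` (Dirichlet),
#'   `infiltrate_fraction`, `muts_per_clone`, `n_germline`,
#'   `germline_hom_fraction`, `n_hidden_germline` (heterozygous germline
#'   variants whose blood evidence is lost in the sequencing data — callers
#'   will miscall them as somatic; they are real germline variants in every
#'   other respect). The defaults model a polyclonal brushing: many small
#'   clones whose private mutations sit far below the VAF detection limit.
#' @param subject subject identifier.
#' @param seed optional integer seed (deterministic output under a seed).
#' @return a [clone_mixture()].
#' @export
simulate_mixture <- function(config, clone_spec = list(), subject = "s01",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- utils::modifyList(
    list(fractions = NULL, n_clones = 200L, concentration = 1,
         infiltrate_fraction = 0.1, muts_per_clone = 5L,
         n_germline = 100L, germline_hom_fraction = 1 / 3,
         n_hidden_germline = 10L),
    clone_spec
  )
  if (is.null(spec$fractions)) {
    g <- stats::rgamma(spec$n_clones, shape = spec$concentration)
    fr <- g / sum(g) * (1 - spec$infiltrate_fraction)
  } else {
    fr <- spec$fractions
    if (abs(sum(fr) + spec$infiltrate_fraction - 1) > 1e-9) {
      stop("explicit clone fractions + infiltrate_fraction must sum to 1")
    }
  }
  n_clones <- length(fr)
  n_germ <- spec$n_germline + spec$n_hidden_germline
  n_pos <- n_germ + n_clones * spec$muts_per_clone
  if (n_pos > config$genome_length) {
    stop("genome_length too small for requested variant counts")
  }
  pos <- sample.int(config$genome_length, n_pos, replace = FALSE)
  germ_pos <- sort(utils::head(pos, n_germ))
  mut_pos <- utils::tail(pos, n_clones * spec$muts_per_clone)
  hidden <- rep(FALSE, n_germ)
  if (spec$n_hidden_germline > 0L && n_germ > 0L) {
    hidden[sample.int(n_germ, spec$n_hidden_germline)] <- TRUE
  }
  germline <- data.frame(
    chrom = rep_len(config$chrom, length(germ_pos)), pos = germ_pos,
    zygosity = ifelse(
      stats::runif(length(germ_pos)) < spec$germline_hom_fraction,
      "hom", "het"),
    hidden = hidden
  )
  # hidden germline variants are heterozygous (the miscall arises from the
  # variant looking absent in blood, which needs an intermediate VAF)
  germline$zygosity[germline$hidden] <- "het"
  clones <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    idx <- seq.int((i - 1L) * spec$muts_per_clone + 1L,
                   length.out = spec$muts_per_clone)
    clones[[i]] <- list(
      fraction = fr[i],
      mutations = data.frame(chrom = config$chrom, pos = sort(mut_pos[idx]),
                             zygosity = "het")
    )
  }
  clone_mixture(subject, clones, germline,
                infiltrate_fraction = spec$infiltrate_fraction,
                genome_length = config$genome_length)
}

#' Simulate read counts at positions of a mixture
#'
#' Depth is drawn from the configured count distribution and the variant
#' read count from `Binomial(depth, expected VAF)` at the mixture-implied
#' VAF of each position.
#'
#' @param mixture a `CloneMixture`.
#' @param chrom,pos genomic position vectors.
#' @param tissue `"target"` or `"reference"`.
#' @param depth_mean mean depth.
#' @param dispersion negative-binomial size (`NULL` = Poisson).
#' @param error_rate per-base error rate (adds variant reads everywhere).
#' @param seed optional integer seed.
#' @return data frame `chrom`, `pos`, `depth`, `alt_count`, `vaf`.
#' @export
simulate_reads <- function(mixture, chrom, pos, tissue = "target",
                           depth_mean = 30, dispersion = NULL,
                           error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  evaf <- expected_vaf(mixture, chrom, pos, tissue = tissue)
  depth <- rdepth(n, depth_mean, dispersion)
  alt <- stats::rbinom(n, depth, alt_prob(evaf, error_rate))
  data.frame(chrom = chrom, pos = as.integer(pos), depth = depth,
             alt_count = alt,
             vaf = ifelse(depth > 0, alt / depth, NA_real_))
}

#' Simulate a read-depth profile across the genome slice
#'
#' @param config a [sim_config()].
#' @param depth_mean mean depth (defaults to the config's target mean).
#' @param seed optional integer seed.
#' @return a [depth_profile()].
#' @export
simulate_depth_profile <- function(config, depth_mean = config$depth_target_mean,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- rdepth(config$genome_length, depth_mean, config$dispersion)
  out <- list(d)
  names(out) <- config$chrom
  depth_profile(out)
}

#' Simulate annotation tracks with realistic genome coverage fractions
#'
#' Generates the four tracks the confidence tiering needs plus a DHS track,
#' with coverage fractions emulating the human genome annotation the method
#' uses: repeats ~55% (leaving ~45% non-repetitive), 50-mer-unique
#' mappability 77%, common SNPs (MAF >= 1%) ~0.5% of positions, all known
#' SNPs ~5%, with the common SNPs a subset of all SNPs. Interval tracks are
#' built from fixed-width windows so realised coverage is within 2
#' percentage points of the nominal fraction by construction.
#'
#' @param config a [sim_config()].
#' @param fractions named list overriding nominal coverage fractions
#'   (`repeat`, `mappability_unique`, `common_snp`, `all_snp`, `dhs`).
#' @param window_bp window width for interval tracks.
#' @param seed optional integer seed.
#' @return named list of `Track`s.
#' @export
simulate_tracks <- function(config, fractions = list(), window_bp = 1000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- utils::modifyList(
    list("repeat" = 0.55, mappability_unique = 0.77,
         common_snp = 0.005, all_snp = 0.05, dhs = 0.03),
    fractions
  )
  L <- config$genome_length
  window_bp <- min(as.integer(window_bp), L)
  n_win <- L %/% window_bp
  win_track <- function(name, frac) {
    k <- round(frac * n_win)
    sel <- sort(sample.int(n_win, k))
    start <- (sel - 1L) * window_bp
    track(name, chrom = rep(config$chrom, k), start = start,
          end = start + window_bp)
  }
  n_all <- round(fr$all_snp * L)
  all_pos <- sort(sample.int(L, n_all))
  n_common <- round(fr$common_snp * L)
  common_pos <- sort(sample(all_pos, n_common))
  list(
    "repeat" = win_track("repeat", fr[["repeat"]]),
    mappability_unique = win_track("mappability_unique", fr$mappability_unique),
    dhs = win_track("dhs", fr$dhs),
    all_snp = track("all_snp", rep(config$chrom, n_all),
                    start = all_pos - 1L, end = all_pos),
    common_snp = track("common_snp", rep(config$chrom, n_common),
                       start = common_pos - 1L, end = common_pos)
  )
}

#' Simulate shared data artifacts for one subject
#'
#' Artifacts are positions where the sequencing or mapping data themselves
#' carry a spurious somatic-looking signal. Because the signal lives in the
#' data, every caller sees the same artifact (it survives the consensus
#' intersection), unlike a caller's private false positives. Artifact
#' positions are enriched in repetitive and non-unique regions when tracks
#' are supplied (weight `region_enrichment`); each artifact carries a shared
#' apparent target VAF drawn above the common caller thresholds.
#'
#' @param config a [sim_config()] (rate taken from `artifact_rate_per_mb`).
#' @param tracks optional track list for region-enriched placement.
#' @param region_enrichment weight multiplier for positions in repetitive or
#'   non-unique regions (default 5).
#' @param seed optional integer seed.
#' @return data frame `chrom`, `pos`, `strength` (apparent target VAF).
#' @export
simulate_artifacts <- function(config, tracks = NULL, region_enrichment = 5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, config$artifact_rate_per_mb *
                      config$genome_length / 1e6)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strength = numeric()))
  }
  # oversample, then accept difficult-region positions with higher weight
  pool <- sample.int(config$genome_length, min(config$genome_length, 20L * n))
  w <- rep(1, length(pool))
  if (!is.null(tracks)) {
    difficult <- overlaps(tracks[["repeat"]], config$chrom, pool) |
      !overlaps(tracks$mappability_unique, config$chrom, pool)
    w[difficult] <- region_enrichment
  }
  pos <- sample(pool, n, prob = w)
  data.frame(chrom = config$chrom, pos = sort(pos),
             strength = stats::runif(n, 0.15, 0.5))
}

#' Add the subjects' germline variants to the SNP annotation tracks
#'
#' Most germline variants of any subject are catalogued polymorphisms, so
#' the simulated SNP tracks are augmented with every mixture's germline
#' positions (both the common-SNP and the all-SNP track). This gives
#' hidden-germline miscalls their characteristic SNP overlap — and hence
#' their low confidence tier.
#'
#' @param tracks track list from [simulate_tracks()].
#' @param mixtures list of `CloneMixture`s.
#' @return the track list with `all_snp` and `common_snp` augmented.
#' @export
augment_snp_tracks <- function(tracks, mixtures) {
  germ <- do.call(rbind, lapply(mixtures, function(mx) mx$germline))
  if (is.null(germ) || nrow(germ) == 0L) return(tracks)
  add <- function(tr, chrom, pos) {
    old <- tr$gr
    track_df <- data.frame(
      chrom = c(as.character(GenomicRanges::seqnames(old)), norm_chrom(chrom)),
      start = c(GenomicRanges::start(old) - 1L, pos - 1L),
      end = c(GenomicRanges::end(old), pos)
    )
    track(tr$name, track_df$chrom, track_df$start, track_df$end)
  }
  tracks$all_snp <- add(tracks$all_snp, germ$chrom, germ$pos)
  tracks$common_snp <- add(tracks$common_snp, germ$chrom, germ$pos)
  tracks
}

#' Sample the sequencing reads of one subject at all somatic positions
#'
#' Draws one set of per-tissue depths and variant read counts at every
#' planted somatic position of a mixture — the shared sequencing data that
#' all emulated callers of one subject then interpret. Sharing the reads
#' (rather than resampling per caller) mirrors reality: the callers run on
#' the same alignments and differ in thresholds and filters, not in the
#' data.
#'
#' @param mixture a `CloneMixture`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return data frame with one row per somatic truth position: `chrom`,
#'   `pos`, `depth_target`, `alt_target`, `vaf_target`, `depth_reference`,
#'   `alt_reference`, `vaf_reference`.
#' @export
sample_mutation_reads <- function(mixture, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- somatic_truth(mixture)
  if (nrow(truth) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      depth_target = integer(), alt_target = integer(),
                      vaf_target = numeric(), depth_reference = integer(),
                      alt_reference = integer(), vaf_reference = numeric()))
  }
  rt <- simulate_reads(mixture, truth$chrom, truth$pos, tissue = "target",
                       depth_mean = config$depth_target_mean,
                       dispersion = config$dispersion,
                       error_rate = config$error_rate)
  rr <- simulate_reads(mixture, truth$chrom, truth$pos, tissue = "reference",
                       depth_mean = config$depth_reference_mean,
                       dispersion = config$dispersion,
                       error_rate = config$error_rate)
  data.frame(
    chrom = truth$chrom, pos = truth$pos,
    depth_target = rt$depth, alt_target = rt$alt_count, vaf_target = rt$vaf,
    depth_reference = rr$depth, alt_reference = rr$alt_count,
    vaf_reference = ifelse(rr$depth > 0, rr$alt_count / rr$depth, 0)
  )
}

#' Emulate one somatic caller on a clone mixture
#'
#' True clone-private mutations are read-sampled at the configured depths
#' (or taken from `reads`, the shared per-subject sequencing draw from
#' [sample_mutation_reads()], so that several callers interpret the same
#' data); a call is emitted when the sampled target VAF reaches the
#' caller's threshold (with at least one variant read), minus random misses
#' at the profile's false-negative rate. False positives are added as a
#' Poisson process at the profile's per-Mb rate, placed preferentially on
#' common-SNP positions when a `common_snp` track is supplied (weight
#' `fp_snp_enrichment`). Every emitted call carries simulated per-tissue
#' depths and VAFs.
#'
#' @param mixture a `CloneMixture`.
#' @param profile a [caller_profile()].
#' @param config a [sim_config()].
#' @param tracks optional track list (used for SNP-enriched FP placement).
#' @param tissue affected-tissue label for the emitted calls.
#' @param reads optional shared reads from [sample_mutation_reads()];
#'   `NULL` draws fresh reads for this caller alone.
#' @param artifacts optional shared artifacts from [simulate_artifacts()]:
#'   each is called whenever its apparent VAF reaches the caller's threshold
#'   (minus fn-rate misses). The mixture's hidden germline variants are
#'   likewise miscalled as somatic by every caller (their blood evidence is
#'   absent from the shared data).
#' @param seed optional integer seed.
#' @return a `CallSet`; its attribute `truth` holds the paired truth-set
#'   data frame (`chrom`, `pos`) of all planted somatic mutations.
#' @export
emulate_caller <- function(mixture, profile, config, tracks = NULL,
                           tissue = "lower_lobe", reads = NULL,
                           artifacts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(mixture, "CloneMixture"),
            inherits(profile, "CallerProfile"))
  truth <- somatic_truth(mixture)
  bases <- c("A", "C", "G", "T")
  if (is.null(reads)) reads <- sample_mutation_reads(mixture, config)

  rows <- list()
  if (nrow(truth) > 0L) {
    stopifnot(nrow(reads) == nrow(truth))
    rt <- data.frame(chrom = reads$chrom, pos = reads$pos,
                     depth = reads$depth_target, alt_count = reads$alt_target,
                     vaf = reads$vaf_target)
    rr <- data.frame(depth = reads$depth_reference,
                     alt_count = reads$alt_reference)
    called <- !is.na(rt$vaf) & rt$vaf >= profile$vaf_call_threshold &
      rt$alt_count >= 1L &
      stats::runif(nrow(truth)) >= profile$fn_rate
    if (any(called)) {
      ref <- sample(bases, sum(called), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      rows$tp <- data.frame(
        chrom = truth$chrom[called], pos = truth$pos[called],
        ref = ref, alt = alt,
        vaf_target = rt$vaf[called],
        vaf_reference = ifelse(rr$depth[called] > 0,
                               rr$alt_count[called] / rr$depth[called], 0),
        depth_target = rt$depth[called], depth_reference = rr$depth[called],
        functional_class = "other"
      )
    }
  }

  # shared data artifacts: apparent VAF lives in the data, so the same
  # artifact passes every caller whose threshold it reaches
  if (!is.null(artifacts) && nrow(artifacts) > 0L) {
    hit <- artifacts$strength >= profile$vaf_call_threshold &
      stats::runif(nrow(artifacts)) >= profile$fn_rate
    if (any(hit)) {
      k <- sum(hit)
      a_depth <- rdepth(k, config$depth_target_mean, config$dispersion)
      a_depth_r <- rdepth(k, config$depth_reference_mean, config$dispersion)
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      rows$artifact <- data.frame(
        chrom = artifacts$chrom[hit], pos = artifacts$pos[hit],
        ref = ref, alt = alt,
        vaf_target = round(artifacts$strength[hit] * a_depth) /
          pmax(a_depth, 1),
        vaf_reference = 0,
        depth_target = a_depth, depth_reference = a_depth_r,
        functional_class = "other"
      )
    }
  }

  # hidden germline variants: heterozygous in truth, but the blood evidence
  # is absent from the shared data, so every caller miscalls them as somatic
  hg <- mixture$germline[mixture$germline$hidden, , drop = FALSE]
  if (nrow(hg) > 0L) {
    miss <- stats::runif(nrow(hg)) < profile$fn_rate
    hg <- hg[!miss, , drop = FALSE]
  }
  if (nrow(hg) > 0L) {
    k <- nrow(hg)
    h_depth <- rdepth(k, config$depth_target_mean, config$dispersion)
    h_alt <- stats::rbinom(k, h_depth, 0.5)
    # substandard blood coverage is what hid the variant
    h_depth_r <- rdepth(k, min(6, config$depth_reference_mean),
                        config$dispersion)
    keep <- h_depth > 0 & (h_alt / pmax(h_depth, 1)) >=
      profile$vaf_call_threshold
    if (any(keep)) {
      k <- sum(keep)
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      rows$hidden_germline <- data.frame(
        chrom = hg$chrom[keep], pos = hg$pos[keep], ref = ref, alt = alt,
        vaf_target = h_alt[keep] / h_depth[keep],
        vaf_reference = 0,
        depth_target = h_depth[keep], depth_reference = h_depth_r[keep],
        functional_class = "other"
      )
    }
  }

  n_fp <- stats::rpois(1L, profile$fp_rate_per_mb * config$genome_length / 1e6)
  if (n_fp > 0L) {
    snp_pos <- integer(0)
    if (!is.null(tracks) && !is.null(tracks$common_snp)) {
      gr <- tracks$common_snp$gr
      snp_pos <- GenomicRanges::start(gr)[as.character(
        GenomicRanges::seqnames(gr)) == norm_chrom(config$chrom)]
    }
    n_snp <- length(snp_pos)
    p_snp <- if (n_snp > 0L) {
      profile$fp_snp_enrichment * n_snp /
        (profile$fp_snp_enrichment * n_snp + (config$genome_length - n_snp))
    } else 0
    on_snp <- stats::runif(n_fp) < p_snp
    fp_pos <- integer(n_fp)
    if (any(on_snp)) fp_pos[on_snp] <- sample(snp_pos, sum(on_snp), replace = TRUE)
    if (any(!on_snp)) fp_pos[!on_snp] <- sample.int(config$genome_length,
                                                    sum(!on_snp))
    fp_depth <- rdepth(n_fp, config$depth_target_mean, config$dispersion)
    fp_vaf <- stats::runif(n_fp, profile$vaf_call_threshold,
                           min(1, profile$vaf_call_threshold + 0.35))
    fp_depth_r <- rdepth(n_fp, config$depth_reference_mean, config$dispersion)
    ref <- sample(bases, n_fp, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    rows$fp <- data.frame(
      chrom = config$chrom, pos = fp_pos, ref = ref, alt = alt,
      vaf_target = ifelse(fp_depth > 0, round(fp_vaf * fp_depth) / pmax(fp_depth, 1),
                          0),
      vaf_reference = 0,
      depth_target = fp_depth, depth_reference = fp_depth_r,
      functional_class = "other"
    )
  }

  calls <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character())
  }
  cs <- suppressMessages(call_set(calls, subject = mixture$subject,
                                  tissue = tissue, caller = profile$name))
  attr(cs, "truth") <- truth[, c("chrom", "pos")]
  cs
}

#' Simulate amplicon verification pileups
#'
#' One observation per candidate position x sample (every subject's blood
#' and target tissue), at very high depth: depth is drawn around
#' `pileup_depth_mean` and the variant read count is binomial at the
#' mixture-implied VAF of that sample at that position.
#'
#' @param mixtures named list of `CloneMixture`s (names = subjects).
#' @param candidates data frame with columns `chrom`, `pos`.
#' @param config a [sim_config()].
#' @param target_tissue label for the non-blood sample.
#' @param seed optional integer seed.
#' @return data frame `subject`, `tissue`, `chrom`, `pos`, `depth`,
#'   `alt_count`, `vaf`.
#' @export
simulate_pileups <- function(mixtures, candidates, config,
                             target_tissue = "lower_lobe", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(candidates) > 0L)
  out <- list()
  for (subj in names(mixtures)) {
    mx <- mixtures[[subj]]
    for (tis in c("blood", target_tissue)) {
      side <- if (tis == "blood") "reference" else "target"
      r <- simulate_reads(mx, candidates$chrom, candidates$pos, tissue = side,
                          depth_mean = config$pileup_depth_mean,
                          dispersion = config$dispersion,
                          error_rate = config$error_rate)
      out[[paste(subj, tis)]] <- data.frame(
        subject = subj, tissue = tis, chrom = r$chrom, pos = r$pos,
        depth = r$depth, alt_count = r$alt_count, vaf = r$vaf
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a truth set of somatic positions as TSV
#' @param truth data frame with columns `chrom`, `pos`.
#' @param path file path.
#' @return `path` invisibly / the truth data frame.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth[, c("chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer"))
}
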