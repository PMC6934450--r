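test_that("expected VAF follows the clone-fraction/2 rule", {
  mx <- single_clone_mixture(1.0, n_mut = 3, n_germ = 2, seed = 5)
  muts <- somatic_truth(mx)
  expect_equal(expected_vaf(mx, muts$chrom, muts$pos, "target"),
               rep(0.5, 3))  # f = 1, het
  expect_equal(expected_vaf(mx, muts$chrom, muts$pos, "reference"),
               rep(0, 3))    # somatic: absent from blood

  # f = 0.30 puts the expected VAF exactly at the 0.15 caller threshold
  mx2 <- single_clone_mixture(0.30, n_mut = 2, seed = 6)
  muts2 <- somatic_truth(mx2)
  expect_equal(expected_vaf(mx2, muts2$chrom, muts2$pos, "target"),
               rep(0.15, 2))

  # germline variants: het 0.5 / hom 1.0 in both tissues
  mx3 <- single_clone_mixture(0.4, n_mut = 1, n_germ = 3, seed = 7)
  g <- mx3$germline
  for (tis in c("target", "reference")) {
    expect_equal(expected_vaf(mx3, g$chrom, g$pos, tis), rep(0.5, 3))
  }
  mx4 <- single_clone_mixture(0.4, n_mut = 1, n_germ = 2,
                              germ_zygosity = "hom", seed = 8)
  expect_equal(expected_vaf(mx4, mx4$germline$chrom, mx4$germline$pos,
                            "reference"), rep(1, 2))
})

test_that("clone mixtures validate fractions and position disjointness", {
  expect_error(
    clone_mixture("s01", list(list(fraction = 0.5, mutations = data.frame(
      chrom = "1", pos = 1L, zygosity = "het"))),
      infiltrate_fraction = 0.4),
    "sum to 1"
  )
  g <- data.frame(chrom = "1", pos = 10L, zygosity = "het")
  expect_error(
    clone_mixture("s01", list(list(fraction = 1, mutations = data.frame(
      chrom = "1", pos = 10L, zygosity = "het"))), germline = g),
    "disjoint"
  )
})

test_that("simulate_mixture is deterministic under a seed", {
  cfg <- sim_config(genome_length = 1e5, seed = 3)
  a <- simulate_mixture(cfg, subject = "s01", seed = 21)
  b <- simulate_mixture(cfg, subject = "s01", seed = 21)
  expect_identical(a, b)
  c <- simulate_mixture(cfg, subject = "s01", seed = 22)
  expect_false(identical(somatic_truth(a)$pos, somatic_truth(c)$pos))
  fr <- vapply(a$clones, `[[`, numeric(1), "fraction")
  expect_equal(sum(fr) + a$infiltrate_fraction, 1, tolerance = 1e-9)
})

test_that("read simulation respects degenerate expected VAFs", {
  mx <- single_clone_mixture(0.4, n_mut = 2, n_germ = 2,
                             germ_zygosity = "hom", seed = 9)
  # no variant anywhere: alt_count always 0
  clean_pos <- setdiff(seq_len(100), c(somatic_truth(mx)$pos, mx$germline$pos))
  r0 <- simulate_reads(mx, "1", clean_pos[1:50], depth_mean = 50, seed = 1)
  expect_true(all(r0$alt_count == 0L))
  # hom germline: expected VAF 1 in blood, alt_count equals depth
  r1 <- simulate_reads(mx, mx$germline$chrom, mx$germline$pos,
                       tissue = "reference", depth_mean = 50, seed = 2)
  expect_true(all(r1$alt_count == r1$depth))
})

test_that("alt counts at fixed depth follow the exact binomial law", {
  # germline het (expected VAF 0.5) at fixed depth 20, 1e4 draws,
  # chi-square GOF against Binomial(20, 0.5) at alpha = 0.01
  mx <- single_clone_mixture(0.5, n_mut = 1, n_germ = 1, seed = 10)
  g <- mx$germline
  r <- simulate_reads(mx, rep(g$chrom, 1e4), rep(g$pos, 1e4),
                      tissue = "reference", depth_mean = 20,
                      dispersion = 0, seed = 33)
  expect_true(all(r$depth == 20L))
  # bin counts 0..20 with tails pooled to keep expected counts > 5
  bins <- c(0:5, 6:14, 15:20)
  obs <- tabulate(pmin(pmax(r$alt_count, 5L), 15L) - 4L, nbins = 11L)
  p <- dbinom(0:20, 20, 0.5)
  exp_p <- c(sum(p[1:6]), p[7:15], sum(p[16:21]))
  gof <- suppressWarnings(chisq.test(obs, p = exp_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("mean simulated VAF tracks f/2 within 3 standard errors", {
  mx <- single_clone_mixture(0.4, n_mut = 1, seed = 12)
  mut <- somatic_truth(mx)
  r <- simulate_reads(mx, rep(mut$chrom, 1000), rep(mut$pos, 1000),
                      depth_mean = 30, seed = 13)
  v <- r$vaf[!is.na(r$vaf)]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.20), 3 * se)
})

test_that("a fully clonal mixture with exact callers yields exactly its mutations", {
  mx <- single_clone_mixture(1.0, n_mut = 10, seed = 14)
  cfg <- sim_config(genome_length = 1e5, depth_target_mean = 60)
  pr <- caller_profile("exact", vaf_call_threshold = 0.15,
                       fp_rate_per_mb = 0, fn_rate = 0)
  cs <- emulate_caller(mx, pr, cfg, seed = 15)
  expect_equal(nrow(cs), 10L)
  expect_setequal(cs$pos, somatic_truth(mx)$pos)
  expect_equal(attr(cs, "truth")$pos, somatic_truth(mx)$pos)
})

test_that("subthreshold clones produce no calls at high depth (brushing regime)", {
  # every clone fraction < 2 x threshold => expected VAF < threshold;
  # at high depth the sampled VAF concentrates below it
  mx <- clone_mixture(
    "s01",
    clones = lapply(c(0.25, 0.25, 0.2, 0.2), function(f) list(
      fraction = f,
      mutations = data.frame(chrom = "1",
                             pos = sample.int(1e5, 5),
                             zygosity = "het"))),
    infiltrate_fraction = 0.1, genome_length = 1e5
  )
  cfg <- sim_config(genome_length = 1e5, depth_target_mean = 5000)
  pr <- caller_profile("exact", vaf_call_threshold = 0.15,
                       fp_rate_per_mb = 0, fn_rate = 0)
  cs <- emulate_caller(mx, pr, cfg, seed = 16)
  expect_equal(nrow(cs), 0L)
})

test_that("permissive and restrictive callers differ ~10-fold in FP counts", {
  # mixtures without somatic mutations: all calls are false positives;
  # Poisson rates 1.0 vs 0.1 per Mb on 5 Mb, totalled over 20 seeds
  cfg <- sim_config(genome_length = 5e6)
  mx <- clone_mixture("s01", clones = list(list(
    fraction = 0.9,
    mutations = data.frame(chrom = character(), pos = integer(),
                           zygosity = character()))),
    infiltrate_fraction = 0.1, genome_length = 5e6)
  perm <- caller_profile("perm", fp_rate_per_mb = 1.0)
  rest <- caller_profile("rest", fp_rate_per_mb = 0.1)
  n_perm <- n_rest <- 0L
  for (s in 1:20) {
    n_perm <- n_perm + nrow(emulate_caller(mx, perm, cfg, seed = 100 + s))
    n_rest <- n_rest + nrow(emulate_caller(mx, rest, cfg, seed = 200 + s))
  }
  # expected 100 vs 10; accept a broad band around the 10x ratio
  expect_gt(n_perm / max(n_rest, 1), 4)
  expect_lt(n_perm / max(n_rest, 1), 25)
})

test_that("false positives are enriched on common-SNP positions", {
  cfg <- sim_config(genome_length = 1e6)
  tracks <- simulate_tracks(cfg, seed = 44)
  mx <- clone_mixture("s01", clones = list(list(
    fraction = 1,
    mutations = data.frame(chrom = character(), pos = integer(),
                           zygosity = character()))),
    genome_length = 1e6)
  pr <- caller_profile("perm", fp_rate_per_mb = 50, fp_snp_enrichment = 10)
  cs <- suppressMessages(emulate_caller(mx, pr, cfg, tracks = tracks, seed = 45))
  frac_on_snp <- mean(overlaps(tracks$common_snp, cs$chrom, cs$pos))
  # ~0.5% of the genome at 10x weight -> expected ~4.8% of FPs on SNPs
  expect_gt(frac_on_snp, 0.015)
})

test_that("simulated tracks hit their nominal genome fractions", {
  cfg <- sim_config(genome_length = 1e6)
  tracks <- simulate_tracks(cfg, seed = 17)
  frac <- function(tr) track_coverage_bp(tr) / cfg$genome_length
  expect_lt(abs(frac(tracks[["repeat"]]) - 0.55), 0.02)
  expect_lt(abs(frac(tracks$mappability_unique) - 0.77), 0.02)
  expect_lt(abs(frac(tracks$common_snp) - 0.005), 0.002)
  expect_lt(abs(frac(tracks$all_snp) - 0.05), 0.005)
  # common SNPs are a subset of all SNPs
  common_pos <- GenomicRanges::start(tracks$common_snp$gr)
  expect_true(all(overlaps(tracks$all_snp, "1", common_pos)))
})

test_that("pileups reflect mixture-implied VAFs at high depth", {
  g <- data.frame(chrom = "1", pos = 100L, zygosity = "het")
  mx_carrier <- clone_mixture(
    "s01",
    clones = list(list(fraction = 0.2, mutations = data.frame(
      chrom = "1", pos = 500L, zygosity = "het"))),
    germline = g, infiltrate_fraction = 0.8, genome_length = 1e4
  )
  mx_other <- clone_mixture(
    "s02",
    clones = list(list(fraction = 0.2, mutations = data.frame(
      chrom = "1", pos = 900L, zygosity = "het"))),
    infiltrate_fraction = 0.8, genome_length = 1e4
  )
  cfg <- sim_config(genome_length = 1e4, pileup_depth_mean = 2e4)
  cand <- data.frame(chrom = "1", pos = c(100L, 500L))
  pu <- simulate_pileups(list(s01 = mx_carrier, s02 = mx_other), cand, cfg,
                         seed = 18)
  get <- function(s, t, p) pu$vaf[pu$subject == s & pu$tissue == t & pu$pos == p]
  # germline het: ~0.5 in both tissues of the carrier
  expect_lt(abs(get("s01", "blood", 100L) - 0.5), 0.02)
  expect_lt(abs(get("s01", "lower_lobe", 100L) - 0.5), 0.02)
  # clone-private at f = 0.2: ~0.10 in target, ~0 in blood
  expect_lt(abs(get("s01", "lower_lobe", 500L) - 0.10), 0.02)
  expect_equal(get("s01", "blood", 500L), 0)
  # non-carrier subject: reference everywhere (error rate 0)
  expect_equal(get("s02", "lower_lobe", 500L), 0)
  expect_equal(get("s02", "blood", 100L), 0)
})

test_that("pileup VAF regressed on f/2 recovers slope 1 within 0.05", {
  set.seed(19)
  fr <- rep(1 / 60, 50)  # 50 clones, plus infiltrate
  clones <- lapply(seq_along(fr), function(i) list(
    fraction = fr[i],
    mutations = data.frame(chrom = "1", pos = 1000L + i, zygosity = "het")
  ))
  # vary fractions: rescale a Dirichlet draw to sum 0.9
  g <- rgamma(50, 1) + 0.2
  fr <- g / sum(g) * 0.9
  for (i in 1:50) clones[[i]]$fraction <- fr[i]
  mx <- clone_mixture("s01", clones, infiltrate_fraction = 0.1,
                      genome_length = 1e4)
  cfg <- sim_config(genome_length = 1e4, pileup_depth_mean = 1e4)
  cand <- data.frame(chrom = "1", pos = 1000L + 1:50)
  pu <- simulate_pileups(list(s01 = mx), cand, cfg, seed = 20)
  target <- pu[pu$tissue == "lower_lobe", ]
  target <- target[order(target$pos), ]
  slope <- coef(lm(target$vaf ~ 0 + I(fr / 2)))[[1]]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("identical seeds give byte-identical simulator outputs", {
  cfg <- sim_config(genome_length = 1e5, depth_target_mean = 40)
  pr <- caller_profile("perm", fp_rate_per_mb = 2)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  mx1 <- simulate_mixture(cfg, list(fractions = c(0.5, 0.4),
                                    infiltrate_fraction = 0.1,
                                    muts_per_clone = 5, n_germline = 10),
                          seed = 77)
  mx2 <- simulate_mixture(cfg, list(fractions = c(0.5, 0.4),
                                    infiltrate_fraction = 0.1,
                                    muts_per_clone = 5, n_germline = 10),
                          seed = 77)
  write_vcf(emulate_caller(mx1, pr, cfg, seed = 78), f1, seed = 78)
  write_vcf(emulate_caller(mx2, pr, cfg, seed = 78), f2, seed = 78)
  expect_identical(readLines(f1), readLines(f2))
})
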