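test_that("classify_vaf reproduces the decision matrix", {
  expect_equal(classify_vaf(0.5, 5000), "heterozygous")
  expect_equal(classify_vaf(0.004, 20000), "reference")
  expect_equal(classify_vaf(0.10, 2000), "subclonal")
  expect_equal(classify_vaf(0.10, 300), "indeterminate")
  expect_equal(classify_vaf(0.03, 20000), "indeterminate")
  expect_equal(classify_vaf(0.95, 5000), "homozygous")
  expect_equal(classify_vaf(0.5, 0), "no_data")
})

test_that("classify_vaf partitions the VAF x depth plane (boundary grid)", {
  vafs <- c(0, 0.0099, 0.01, 0.049, 0.05, 0.1, 0.199, 0.20, 0.5,
            0.80, 0.801, 1)
  depths <- c(1L, 300L, 1000L, 1001L, 20000L)
  grid <- expand.grid(vaf = vafs, depth = depths)
  cls <- classify_vaf(grid$vaf, grid$depth)
  expect_true(all(cls %in% c("reference", "subclonal", "heterozygous",
                             "homozygous", "indeterminate")))
  expect_equal(length(cls), nrow(grid))  # total function: one class each
  # boundary semantics
  expect_equal(classify_vaf(0.01, 20000), "indeterminate")  # not "below 1%"
  expect_equal(classify_vaf(0.05, 1001), "subclonal")
  expect_equal(classify_vaf(0.05, 1000), "indeterminate")   # needs depth > 1000
  expect_equal(classify_vaf(0.20, 100), "heterozygous")
  expect_equal(classify_vaf(0.80, 100), "heterozygous")     # 80% inclusive
  expect_equal(classify_vaf(0.801, 100), "homozygous")
  expect_equal(classify_vaf(0.199, 1001), "subclonal")
})

test_that("adjudication resolves indeterminates against the other samples", {
  obs <- data.frame(
    subject = c("s01", "s02", "s03", "s04"),
    tissue = "blood",
    vaf = c(0.03, 0.031, 0.029, 0.030),
    depth = 20000L
  )
  obs$class <- classify_vaf(obs$vaf, obs$depth)
  res <- adjudicate(obs)
  # everyone shows ~3%: shared background, resolves to reference
  expect_true(all(res$class == "reference"))
  expect_true(all(res$resolved))

  obs2 <- obs
  obs2$vaf <- c(0.03, 0.001, 0.0005, 0.001)
  obs2$class <- classify_vaf(obs2$vaf, obs2$depth)
  res2 <- adjudicate(obs2)
  # elevated only in s01: supports the variant
  expect_equal(res2$class[1], "subclonal")
  expect_true(all(res2$class[-1] == "reference"))

  solo <- obs[1, ]
  res3 <- adjudicate(solo)
  expect_equal(res3$class, "indeterminate")
  expect_false(res3$resolved)
})

test_that("outcomes follow the verification category definitions", {
  mk <- function(brush, blood, others = character(0)) {
    df <- data.frame(
      subject = c("s01", "s01", rep(sprintf("o%02d", seq_along(others)), each = 1)),
      tissue = c("lower_lobe", "blood", rep("lower_lobe", length(others))),
      class = c(brush, blood, others)
    )
    assign_outcome(df, "s01")
  }
  expect_equal(mk("subclonal", "reference", c("reference", "reference")),
               "confirmed_somatic")
  expect_equal(mk("heterozygous", "heterozygous"), "germline_polymorphism")
  expect_equal(mk("subclonal", "subclonal"), "subclonal_shared")
  expect_equal(mk("reference", "reference"), "absent")
  expect_equal(mk("subclonal", "reference", c("subclonal")), "subclonal_shared")
  expect_equal(mk("no_data", "reference"), "unclear")
  expect_equal(mk("indeterminate", "reference"), "unclear")
  # missing blood observation
  solo <- data.frame(subject = "s01", tissue = "lower_lobe",
                     class = "subclonal")
  expect_equal(assign_outcome(solo, "s01"), "unclear")
})

test_that("candidate selection satisfies all constraints on the main example", {
  calls <- make_tiered_calls(n_per_tier_eligible = 40, n_subjects = 12,
                             n_forced = 4, n_chry = 9, seed = 2)
  sel <- select_candidates(calls, n_per_tier = 30, seed = 5)
  expect_equal(nrow(sel$candidates), 90L)
  expect_equal(check_selection_constraints(sel, calls, 30), character(0))
})

test_that("a tier with exactly the quota is selected in full for any seed", {
  calls <- make_tiered_calls(n_per_tier_eligible = 30, n_subjects = 6,
                             n_forced = 0, n_chry = 0)
  for (s in c(1, 99)) {
    sel <- select_candidates(calls, n_per_tier = 30, seed = s)
    high <- sel$candidates[sel$candidates$tier == "high", ]
    expect_setequal(high$pos, calls$pos[calls$tier == "high"])
  }
})

test_that("selection is deterministic under a seed and warns on short tiers", {
  calls <- make_tiered_calls(seed = 3)
  s1 <- select_candidates(calls, seed = 11)
  s2 <- select_candidates(calls, seed = 11)
  expect_identical(s1$candidates, s2$candidates)
  s3 <- select_candidates(calls, seed = 12)
  expect_false(identical(s1$candidates$pos, s3$candidates$pos))

  small <- make_tiered_calls(n_per_tier_eligible = 10, n_subjects = 5,
                             n_forced = 0, n_chry = 0)
  w <- capture_warnings(sel <- select_candidates(small, n_per_tier = 30,
                                                 seed = 1))
  expect_length(w, 3L)  # one per short tier
  expect_true(all(grepl("quota", w)))
  expect_equal(nrow(sel$candidates), 30L)  # all 10 per tier
})

test_that("a subject with only chrY calls triggers a warning, not an error", {
  calls <- make_tiered_calls(n_per_tier_eligible = 35, n_subjects = 4,
                             n_forced = 0, n_chry = 0)
  calls <- rbind(calls, data.frame(chrom = "Y", pos = 123L, subject = "s99",
                                   tier = "high", functional_class = "other"))
  expect_warning(sel <- select_candidates(calls, seed = 7), "s99")
  expect_false("s99" %in% sel$candidates$subject)
})

test_that("extrapolation scales confirmed fractions to tier totals", {
  ex <- extrapolate(c(1, 0, 0), c(28, 29, 28), c(156, 711, 784))
  expect_equal(ex$estimated_true_total, 156 / 28, tolerance = 1e-12)
  expect_gt(ex$fp_fraction, 0.99)

  all_conf <- extrapolate(c(5, 5), c(5, 5), c(100, 100))
  expect_equal(all_conf$fp_fraction, 0)
  none <- extrapolate(c(0, 0), c(5, 5), c(100, 100))
  expect_equal(none$fp_fraction, 1)

  # scale equivariance
  ex2 <- extrapolate(c(1, 0, 0), c(28, 29, 28), 2 * c(156, 711, 784))
  expect_equal(ex2$estimated_true_total, 2 * ex$estimated_true_total)
  expect_equal(ex2$fp_fraction, ex$fp_fraction)

  expect_error(extrapolate(c(0, 0), c(5, 0), c(100, 50)), "undefined")
  expect_error(extrapolate(c(6), c(5), c(100)), "exceed")
})

test_that("outcome table column sums equal tested counts per tier", {
  outcomes <- data.frame(
    tier = rep(c("high", "medium", "low"), times = c(28, 29, 28)),
    outcome = c(
      rep(c("confirmed_somatic", "subclonal_shared", "germline_polymorphism",
            "unclear", "absent"), times = c(1, 5, 0, 1, 21)),
      rep(c("confirmed_somatic", "subclonal_shared", "germline_polymorphism",
            "unclear", "absent"), times = c(0, 1, 1, 6, 21)),
      rep(c("confirmed_somatic", "subclonal_shared", "germline_polymorphism",
            "unclear", "absent"), times = c(0, 4, 9, 3, 12))
    )
  )
  ot <- outcome_table(outcomes)
  expect_equal(unname(colSums(ot$counts)), c(28, 29, 28))
  expect_equal(unname(ot$tested), c(28, 29, 28))
  expect_equal(sum(ot$counts), nrow(outcomes))
})

test_that("end-to-end verification recovers planted candidate types", {
  # 4 subjects; target subject s01 carries: a germline het variant, a
  # clone-private mutation (f in [0.1, 0.35]), and a clean position (the
  # planted "caller false positive"); other subjects carry nothing there.
  set.seed(13)
  n_ok <- c(germline = 0L, somatic = 0L, absent = 0L)
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    f <- runif(1, 0.1, 0.35)
    g <- data.frame(chrom = "1", pos = 100L, zygosity = "het")
    carrier <- clone_mixture(
      "s01",
      clones = list(list(fraction = f, mutations = data.frame(
        chrom = "1", pos = 500L, zygosity = "het"))),
      germline = g, infiltrate_fraction = 1 - f, genome_length = 1e4
    )
    others <- lapply(c("s02", "s03", "s04"), function(s) {
      clone_mixture(s, clones = list(list(
        fraction = 0.5,
        mutations = data.frame(chrom = character(), pos = integer(),
                               zygosity = character()))),
        infiltrate_fraction = 0.5, genome_length = 1e4)
    })
    names(others) <- c("s02", "s03", "s04")
    mixtures <- c(list(s01 = carrier), others)
    cand <- data.frame(
      chrom = "1", pos = c(100L, 500L, 900L), subject = "s01",
      tier = c("low", "high", "medium")
    )
    cfg <- sim_config(genome_length = 1e4, pileup_depth_mean = 1e4)
    pu <- simulate_pileups(mixtures, cand[, c("chrom", "pos")], cfg,
                           seed = 1300 + r)
    out <- verify_candidates(cand, pu)
    n_ok["germline"] <- n_ok["germline"] +
      (out$outcome[out$pos == 100L] == "germline_polymorphism")
    n_ok["somatic"] <- n_ok["somatic"] +
      (out$outcome[out$pos == 500L] == "confirmed_somatic")
    n_ok["absent"] <- n_ok["absent"] +
      (out$outcome[out$pos == 900L] == "absent")
  }
  expect_gte(n_ok[["germline"]], ceiling(0.95 * n_rep))
  expect_gte(n_ok[["somatic"]], ceiling(0.90 * n_rep))
  expect_equal(n_ok[["absent"]], n_rep)
})

test_that("candidates without pileup coverage are dropped with a message", {
  mx <- single_clone_mixture(0.5, n_mut = 1, n_germ = 1, seed = 15)
  cfg <- sim_config(genome_length = 1e5, pileup_depth_mean = 5000)
  cand <- data.frame(chrom = "1", pos = c(somatic_truth(mx)$pos, 99999L),
                     subject = "s01", tier = "high")
  pu <- simulate_pileups(list(s01 = mx), cand[1, c("chrom", "pos")], cfg,
                         seed = 16)
  expect_message(out <- verify_candidates(cand, pu), "dropped")
  expect_equal(nrow(out), 1L)
})
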