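test_that("side assignment follows the strand-resolved cut geometry", {
  tgt <- tibble::tibble(chrom = "chr1", start = 1000L, strand = "+")
  e <- make_ends("chr1", c(1017L, 1016L, 1016L, 1010L, 1017L),
                 c("+", "+", "-", "+", "-"))
  a <- assign_side(e, tgt)
  expect_identical(a$side, c("proximal", "proximal", "distal", "outside",
                             "outside"))
  expect_identical(a$boundary_label[1:3], c(17L, 16L, 17L))

  ## minus-strand target: mirror image
  tgt2 <- tibble::tibble(chrom = "chr1", start = 1000L, strand = "-")
  e2 <- make_ends("chr1", c(1002L, 1003L, 1005L), c("-", "+", "-"))
  a2 <- assign_side(e2, tgt2)
  expect_identical(a2$side, c("proximal", "distal", "proximal"))
  expect_identical(a2$boundary_label, c(17L, 17L, 14L))
})

test_that("scission profiles compute both blunt-rate forms", {
  tgt <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                        pam = "AGG")
  lab_pos <- function(lab) 100L + lab
  p1 <- make_pileup("chr1", lab_pos(17L), "+", 8L)
  r1 <- scission_profile(tgt, p1, min_proximal = 8L)
  expect_equal(r1$blunt_fraction, 1)
  expect_equal(r1$log2_blunt_rate, log2(9 / 1))
  expect_true(r1$computable && r1$eligible)

  p2 <- make_pileup("chr1", lab_pos(c(17L, 16L)), "+", 4L)
  r2 <- scission_profile(tgt, p2, min_proximal = 8L)
  expect_equal(r2$blunt_fraction, 0.5)
  expect_equal(r2$log2_blunt_rate, 0)

  p3 <- make_pileup("chr1", lab_pos(16L), "+", 8L)
  r3 <- scission_profile(tgt, p3, min_proximal = 8L)
  expect_equal(r3$blunt_fraction, 0)
  expect_equal(r3$log2_blunt_rate, log2(1 / 9))

  ## zero proximal signal: flagged, not an error
  r4 <- scission_profile(tgt, empty_pileup())
  expect_false(r4$computable)
  expect_true(is.na(r4$blunt_fraction))

  ## below min_proximal: computable but ineligible
  expect_false(scission_profile(tgt, p2, min_proximal = 16L)$eligible)

  ## non-NGG targets are excluded from profile analysis
  tgt_nag <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                            pam = "AAG")
  expect_message(out <- scission_profile(tgt_nag, p1), "non-NGG")
  expect_equal(nrow(out), 0L)
})

test_that("site classes follow the 33/66% staggered-fraction bounds", {
  expect_equal(as.character(classify_site(c(0.90, 0.50, 0.10))),
               c("blunt", "middle", "staggered"))
  ## left-closed boundaries
  expect_equal(as.character(classify_site(1 - 1 / 3)), "middle")
  expect_equal(as.character(classify_site(1 - 2 / 3)), "staggered")
  expect_equal(as.character(classify_site(1)), "blunt")
  expect_equal(as.character(classify_site(0)), "staggered")
})

test_that("blunt fraction and pseudocount-free log2 ratio are equivalent", {
  for (f in c(0.2, 1 / 3, 0.5, 0.8, 0.9)) {
    expect_equal(log2(f / (1 - f)), qlogis(f) / log(2), tolerance = 1e-12)
  }
  expect_equal(log2(0.5 / 0.5), 0)
  expect_equal(log2(0.2 / 0.8), -2)  # 80% staggered <=> log2 ratio -2
})

test_that("overhang distribution recovers the generator parameters", {
  tgt <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                        pam = "AGG")
  all_blunt <- scission_profile(tgt, make_pileup("chr1", 117L, "+", 30L))
  d <- overhang_distribution(all_blunt)
  expect_equal(d$fraction[d$structure == "blunt"], 1)
  expect_equal(sum(d$fraction), 1)

  ## 60/40 blunt / 1-nt overhang from the generator, within sampling error
  cfg <- sim_config(seed = 41, chrom_length = 5000L, n_guides = 1,
                    offtargets_per_guide = 0, depth_per_site = 1500L,
                    overhang_length_probs = c(1, 0, 0), noise_rate = 0,
                    pcr_duplicate_rate = 0)
  sim <- gen_genome(cfg)
  sim$truth$true_blunt_fraction <- 0.6
  ends <- sim_break_ends(sim$truth, sim$genome, cfg)
  prof <- scission_profile(sim$truth, dedup_ends(ends, max_umi_mismatch = -1L))
  d2 <- overhang_distribution(prof)
  tol <- 4 * sqrt(0.6 * 0.4 / 1500)
  expect_lt(abs(d2$fraction[d2$structure == "blunt"] - 0.6), tol)
  expect_lt(abs(d2$fraction[d2$structure == "5p_overhang_1nt"] - 0.4), tol)
  expect_equal(sum(d2$fraction), 1)
})

test_that("footprint inference maps labels to signed overhangs", {
  expect_equal(infer_footprint(c(17L, 14L, 19L)), c(0L, 3L, -2L))
  tgt <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+")
  expect_equal(footprint_from_stacks(tgt, 100L + 16L, 100L + 16L), 1L)
  expect_error(footprint_from_stacks(tgt, 117L, 999L), "distal")
})

test_that("footprints are recovered exactly at zero noise", {
  cfg <- sim_config(seed = 42, chrom_length = 30000L, n_guides = 7,
                    offtargets_per_guide = 3, depth_per_site = 30L,
                    noise_rate = 0, pcr_duplicate_rate = 0)
  sim <- gen_genome(cfg)
  planted <- rep_len(-3:3, nrow(sim$truth))
  sim$truth$fixed_overhang <- planted
  ends <- sim_break_ends(sim$truth, sim$genome, cfg)
  prof <- scission_profile(sim$truth, dedup_ends(ends), require_ngg = FALSE)
  expect_identical(site_footprint(prof), planted)
})

test_that("outside-signal test uses the Poisson control comparison", {
  tgt <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                        pam = "AGG")
  prof0 <- scission_profile(tgt, make_pileup("chr1", 117L, "+", 30L))
  r0 <- outside_signal_test(prof0, empty_pileup(), size_ratio = 1)
  expect_equal(r0$outside_pvalue, 1)

  prof20 <- scission_profile(tgt, make_pileup("chr1", c(117L, 115L), "+",
                                              c(30L, 20L)))
  r20 <- outside_signal_test(prof20, empty_pileup(), size_ratio = 1)
  expect_equal(r20$outside_pvalue, poisson_tail(20, 1), tolerance = 1e-12)

  prof30 <- scission_profile(tgt, make_pileup("chr1", c(117L, 115L), "+",
                                              c(30L, 30L)))
  r30 <- outside_signal_test(prof30, empty_pileup(), size_ratio = 1)
  expect_lt(r30$outside_pvalue, r20$outside_pvalue)
})

test_that("blunt rate vs mismatch recovers the planted trend", {
  sim_profiles <- function(penalty, n_per = 60L, depth = 100L, seed = 51) {
    withr::with_seed(seed, {
      purrr::map_dfr(0:4, function(m) {
        p <- plogis(qlogis(0.8) - log(2) * penalty * m)
        x <- rbinom(n_per, depth, p)
        tibble::tibble(n_mismatches = m, prox_14 = 0L, prox_15 = 0L,
                       prox_16 = depth - x, prox_17 = x, prox_18 = 0L,
                       prox_19 = 0L, prox_20 = 0L,
                       proximal_total = depth, computable = TRUE,
                       eligible = TRUE, blunt_fraction = x / depth)
      })
    })
  }
  ## mismatch-independent generator: slope indistinguishable from zero
  null_fit <- bluntrate_vs_mismatch(sim_profiles(0))
  g0 <- glance(null_fit)
  se <- summary(null_fit$fit)$coefficients[2, 2]
  expect_lt(abs(g0$slope), 3 * se)

  ## penalised generator: negative correlation, strata near planted values
  fit <- bluntrate_vs_mismatch(sim_profiles(0.5))
  g <- glance(fit)
  expect_lt(g$pearson_r, -0.3)
  expect_lt(g$slope, 0)
  strata <- tidy(fit)
  for (m in 0:4) {
    planted <- plogis(qlogis(0.8) - log(2) * 0.5 * m)
    expect_lt(abs(strata$mean_blunt_fraction[strata$n_mismatches == m] -
                    planted),
              4 * sqrt(planted * (1 - planted) / (60 * 100)) + 0.02)
  }
  ## single stratum: slope undefined but flagged
  single <- bluntrate_vs_mismatch(sim_profiles(0)[1:60, ])
  expect_true(single$single_stratum)
  expect_true(is.na(glance(single)$slope))
})

test_that("estimated blunt fractions sit inside the binomial 99% CI", {
  cfg <- sim_config(seed = 52, chrom_length = 60000L, n_guides = 10,
                    offtargets_per_guide = 9, depth_per_site = 100L,
                    noise_rate = 0)
  sim <- gen_genome(cfg)
  sim$truth$true_blunt_fraction <- rep_len(seq(0.1, 0.9, 0.1),
                                           nrow(sim$truth))
  ends <- sim_break_ends(sim$truth, sim$genome, cfg)
  prof <- scission_profile(sim$truth,
                           dedup_ends(ends, max_umi_mismatch = -1L))
  ok <- mapply(function(x, n, p) {
    ci <- binom.test(x, n, conf.level = 0.99)$conf.int
    p >= ci[1] && p <= ci[2]
  }, prof$prox_17, prof$proximal_total, sim$truth$true_blunt_fraction)
  expect_gte(mean(ok), 0.97)  # 100 sites; the 500-site run is in acceptance
})
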