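test_that("the mutation-count model controls dispersion as configured", {
  # degenerate mixture (single component) is pure Poisson: dispersion ~ 1
  cfg1 <- sim_config(n_strains = 1000, count_means = c(23.9, 23.9),
                     count_weights = c(1, 0), n_causal = 0)
  coh <- simulate_ems_cohort(cfg1, seed = 5)
  counts <- tabulate(coh$strain, 1000)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.85); expect_lt(disp, 1.15)

  # default overdispersed mixture triggers the dispersion test
  cfg2 <- sim_config(n_strains = 200, n_causal = 0)
  coh2 <- simulate_ems_cohort(cfg2, seed = 6)
  counts2 <- tabulate(coh2$strain, 200)
  r <- poisson_dispersion_test(counts2, n_resamples = 2000, seed = 7)
  expect_lt(r$p, 0.01)

  # seeded generation is exactly reproducible
  expect_identical(simulate_ems_cohort(cfg2, seed = 9),
                   simulate_ems_cohort(cfg2, seed = 9))
})

test_that("cohort tables respect the configured spectrum and genome", {
  cfg <- sim_config(n_strains = 300)
  coh <- simulate_ems_cohort(cfg, seed = 10)
  expect_true(all(coh$pos >= 1))
  expect_true(all(coh$pos <= cfg$genome[coh$chrom]))
  snv <- coh[coh$mtype == "SNV", ]
  spec <- classify_spectrum(coh)
  expect_equal(sum(spec), nrow(coh))
  # ~96.3% of SNVs are G:C -> A:T
  expect_lt(abs(spec[["GC_to_AT"]] / nrow(snv) - 0.963), 0.02)
  # ~2.7% indels, ~69.4% coding
  expect_lt(abs(mean(coh$mtype == "indel") - 0.027), 0.01)
  expect_lt(abs(mean(coh$region == "coding") - 0.694), 0.02)
  # exactly one causal mutation per strain by default
  expect_true(all(tapply(coh$causal, coh$strain, sum) == 1L))
})

test_that("meiosis follows the Haldane map at its limits", {
  cfg <- sim_config(n_spores = 4000, coverage = 100)
  # two mutations at zero distance are always co-inherited
  m0 <- data.frame(id = c("a", "b"), chrom = "chrI", pos = c(1000L, 1000L),
                   effect = c(0, 0), causal = FALSE)
  bc0 <- simulate_cross_and_bulks(m0, cfg, seed = 21)
  expect_equal(bc0$freq_low[1], bc0$freq_low[2])
  expect_equal(bc0$freq_high[1], bc0$freq_high[2])
  # far apart on one chromosome: effectively unlinked (r -> 0.5)
  mfar <- data.frame(id = c("a", "b"), chrom = "chrI",
                     pos = c(1L, 3000000L), effect = c(0, 0), causal = FALSE)
  set.seed(22)
  cors <- replicate(8, {
    bc <- simulate_cross_and_bulks(mfar, cfg, seed = sample.int(1e6, 1))
    bc$freq_low[1] - 0.5
  })
  expect_lt(abs(mean(cors)), 0.05)  # no systematic co-segregation signal
})

test_that("a neutral unlinked mutation sits near 0.5 in both bulks", {
  cfg <- sim_config(n_spores = 20000, coverage = 105)
  m <- data.frame(id = "a", chrom = "chrI", pos = 100000L, effect = 0,
                  causal = FALSE)
  set.seed(31)
  signs <- replicate(12, {
    bc <- simulate_cross_and_bulks(m, cfg, seed = sample.int(1e6, 1))
    r <- signed_association(bc$low_ref, bc$low_alt, bc$high_ref, bc$high_alt)
    c(bc$freq_low, bc$freq_high, r$sign)
  })
  expect_lt(abs(mean(signs[1, ]) - 0.5), 0.02)
  expect_lt(abs(mean(signs[2, ]) - 0.5), 0.02)
  expect_lt(abs(mean(signs[3, ])), 0.8)  # signs not systematically one-sided
})

test_that("truncation selection separates the causal allele between bulks", {
  cfg <- sim_config(n_spores = 8000, coverage = 100)
  m <- data.frame(id = c("causal", "neutral"),
                  chrom = c("chrI", "chrV"), pos = c(100000L, 200000L),
                  effect = c(3, 0), causal = c(TRUE, FALSE))
  set.seed(41)
  dd <- replicate(10, {
    bc <- simulate_cross_and_bulks(m, cfg, seed = sample.int(1e6, 1))
    abs(bc$freq_high[1] - bc$freq_low[1])
  })
  expect_gt(mean(dd), 0.5)   # 3-SD effect with 2.5% tails: strong separation
})

test_that("plate wells compose expression, gradient, noise and baseline", {
  cfg <- sim_config(row_gradient = 0, col_gradient = 0, sigma_within = 0,
                    sigma_between = 0, autofluorescence = 0.02)
  sim <- simulate_plate_experiment(c(s = 1.3), cfg, seed = 51)
  w <- sim$wells
  expect_equal(w$value[w$strain_id == "s"], rep(1.32, 4))
  expect_equal(unique(w$value[w$is_control]), 1.02)
  expect_equal(unique(w$value[w$is_autofluorescence]), 0.02)
  expect_equal(dim(sim$panel), c(146L, 4L))
  # (plate, row, col) unique
  expect_false(any(duplicated(w[, c("plate_id", "row", "col")])))
  # panel has more between-position than within-position spread by default
  cfg2 <- sim_config()
  sim2 <- simulate_plate_experiment(c(s = 1), cfg2, seed = 52)
  lp <- log(sim2$panel)
  v_between <- var(rowMeans(lp))
  v_within <- mean(apply(lp, 1, var))
  expect_gt(v_between, v_within / 2)  # sdlog ratio sqrt(2) in expectation
  expect_identical(simulate_plate_experiment(c(s = 1), cfg2, seed = 53),
                   simulate_plate_experiment(c(s = 1), cfg2, seed = 53))
})

test_that("competition counts follow the configured ratio dynamics", {
  cfg <- sim_config()
  tp <- simulate_competition_assay(1, cfg, seed = 61)
  w <- competitive_fitness(tp$generations, tp$yfp_count, tp$gfp_count)
  expect_lt(abs(w - 1), 0.02)
  # more events, less estimator spread
  est <- function(events, seeds) {
    cfg2 <- sim_config(competition_events = events)
    vapply(seeds, function(s) {
      tp <- simulate_competition_assay(0.9, cfg2, seed = s)
      competitive_fitness(tp$generations, tp$yfp_count, tp$gfp_count)
    }, numeric(1))
  }
  s_lo <- sd(est(300, 101:130))
  s_hi <- sd(est(20000, 101:130))
  expect_gt(s_lo, s_hi)
  expect_identical(simulate_competition_assay(0.8, cfg, seed = 62),
                   simulate_competition_assay(0.8, cfg, seed = 62))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(bulk_fraction = 0.6), "bulk_fraction")
  expect_error(sim_config(nonsense_field = 1), "unknown")
  expect_error(sim_config(p_indel = 1.5))
  cfg <- sim_config(count_weights = c(2, 2))
  expect_equal(cfg$count_weights, c(0.5, 0.5))  # weights normalized
})
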