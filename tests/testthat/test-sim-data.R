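test_that("marker generation is reproducible and respects the missing rate", {
  cfg <- sim_config(n_entries = 30, n_markers = 200, seed = 7)
  m1 <- generate_markers(cfg)
  m2 <- generate_markers(cfg)
  expect_identical(m1, m2)
  expect_false(anyNA(m1))
  expect_true(all(m1 %in% 0:2))
  cfg2 <- sim_config(n_entries = 30, n_markers = 200, seed = 7,
                     missing_rate = 0.2)
  mm <- generate_markers(cfg2)
  expect_gt(mean(is.na(mm)), 0.15)
  expect_lt(mean(is.na(mm)), 0.25)
})

test_that("per-marker allele frequencies follow the binomial sampling model", {
  cfg <- sim_config(n_entries = 200, n_markers = 2000, seed = 3,
                    allele_freq_range = c(0.1, 0.9))
  m <- generate_markers(cfg)
  phat <- colMeans(m) / 2
  # recover the drawn p_j stream and standardize the deviations
  set.seed(cfg$seed)
  p <- runif(cfg$n_markers, 0.1, 0.9)
  z <- (phat - p) / sqrt(p * (1 - p) / (2 * cfg$n_entries))
  expect_lt(mean(abs(z) > 4), 2e-3)
  expect_lt(max(abs(z)), 6)
})

test_that("degenerate allele frequency ranges are rejected", {
  expect_error(sim_config(allele_freq_range = c(0, 0.5)), "allele_freq_range")
  expect_error(sim_config(allele_freq_range = c(0.9, 0.1)), "allele_freq_range")
})

test_that("true effects have the configured genomic covariance structure", {
  cfg0 <- sim_config(n_entries = 12, n_markers = 300, sigma2_g = 0, seed = 5)
  m <- generate_markers(cfg0)
  tr0 <- generate_true_effects(m, cfg0)
  expect_true(all(tr0$true_gbv == 0))
  cfg1 <- sim_config(n_entries = 12, n_markers = 300, sigma2_gy = 0, seed = 5)
  tr1 <- generate_true_effects(m, cfg1)
  expect_true(all(tr1$true_gby == 0))

  # sample covariance of u_g over replicate draws approximates K sigma2_g
  N <- 10; reps <- 2000; s2g <- 2
  U <- matrix(NA_real_, reps, N)
  K <- NULL
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_entries = N, n_markers = 400, sigma2_g = s2g,
                      sigma2_gy = 0, seed = 1000 + i)
    mk <- generate_markers(sim_config(n_entries = N, n_markers = 400,
                                      seed = 999))
    tr <- generate_true_effects(mk, cfg)
    if (is.null(K)) K <- tr$K
    U[i, ] <- tr$true_gbv
  }
  emp <- cov(U)
  tgt <- K * s2g
  se <- sqrt((outer(diag(tgt), diag(tgt)) + tgt^2) / reps)
  expect_lt(max(abs(emp - tgt) / se), 5)
})

test_that("phenotypes reduce to the mean when all variances are zero", {
  cfg <- sim_config(n_entries = 8, n_years = 1, n_markers = 50, mu = 100,
                    sigma2_y = 0, sigma2_g = 0, sigma2_gy = 0, sigma2_l = 0,
                    sigma2_t = 0, sigma2_gt = 0, sigma2_gl = 0, sigma2_ls = 0,
                    sigma2_lsr = 0, sigma2_lsrb = 0,
                    residual_variances = 1e-12, seed = 2)
  ph <- generate_phenotypes(generate_true_effects(generate_markers(cfg), cfg),
                            cfg)
  expect_equal(ph$yield, rep(100, nrow(ph)), tolerance = 1e-4)
})

test_that("full testing produces entries x reps x locations x testers plots per year", {
  cfg <- sim_config(n_entries = 10, n_years = 1, n_locations = 3, n_reps = 2,
                    n_testers = 2, n_trials_per_location = 1, n_markers = 50,
                    seed = 4)
  ph <- generate_phenotypes(generate_true_effects(generate_markers(cfg), cfg),
                            cfg)
  expect_equal(nrow(ph), 10 * 2 * 3 * 2)
  expect_identical(generate_phenotypes(
    generate_true_effects(generate_markers(cfg), cfg), cfg), ph)
})

test_that("with only residual variance the yield variance matches it", {
  cfg <- sim_config(n_entries = 60, n_years = 1, n_markers = 50, mu = 0,
                    sigma2_y = 0, sigma2_g = 0, sigma2_gy = 0, sigma2_l = 0,
                    sigma2_t = 0, sigma2_gt = 0, sigma2_gl = 0, sigma2_ls = 0,
                    sigma2_lsr = 0, sigma2_lsrb = 0,
                    residual_variances = 6, n_locations = 2,
                    n_trials_per_location = 1, seed = 9)
  ph <- generate_phenotypes(generate_true_effects(generate_markers(cfg), cfg),
                            cfg)
  expect_equal(var(ph$yield), 6, tolerance = 0.6)
})

test_that("selection strictly reduces entry counts along a cycle", {
  cfg <- sim_config(n_entries = 50, n_markers = 100,
                    selection_fractions = c(0.4, 0.5), seed = 6)
  bp <- sim_breeding_program(cfg, n_cycles = 2)
  for (cy in 1:2) {
    n1 <- length(unique(bp$plots$entry[bp$plots$cycle == cy &
                                         bp$plots$stage == "GCA1"]))
    n2 <- length(unique(bp$plots$entry[bp$plots$cycle == cy &
                                         bp$plots$stage == "GCA2"]))
    n3 <- length(unique(bp$plots$entry[bp$plots$cycle == cy &
                                         bp$plots$stage == "GCA3"]))
    expect_lt(n2, n1); expect_lt(n3, n2); expect_gte(n3, 2)
  }
  # default advancement is by true GBV: GCA2 set is the top fraction
  e1 <- unique(bp$plots$entry[bp$plots$cycle == 1 & bp$plots$stage == "GCA1"])
  e2 <- unique(bp$plots$entry[bp$plots$cycle == 1 & bp$plots$stage == "GCA2"])
  top <- names(sort(bp$truth$true_gbv[e1], decreasing = TRUE))[seq_along(e2)]
  expect_setequal(e2, top)
})

test_that("sparse testing covers a fraction of entries per location", {
  cfg <- sim_config(n_entries = 40, n_years = 1, n_markers = 50,
                    coverage = 0.5, n_trials_per_location = 1, seed = 8)
  ph <- generate_phenotypes(generate_true_effects(generate_markers(cfg), cfg),
                            cfg)
  per_loc <- tapply(ph$entry, ph$location, function(e) length(unique(e)))
  expect_true(all(per_loc == 20))
  expect_gt(length(unique(ph$entry)), 20)
})
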