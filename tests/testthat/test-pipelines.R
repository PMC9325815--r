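test_that("dataset assembly filters stages, years and checks", {
  toy <- expand.grid(year = paste0("Y", 1:5), stage = c("GCA1", "GCA2"),
                     entry = c("a", "b"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  toy$location <- "L1"; toy$trial <- "S1"; toy$rep <- "R1"
  toy$block <- "B1"; toy$tester <- "T1"; toy$yield <- 1
  toy$check <- toy$entry == "b"
  toy$cycle <- 1L
  my <- assemble_dataset(toy, "MY")
  expect_setequal(unique(my$year), paste0("Y", 1:4))
  expect_true(all(my$stage == "GCA1"))
  expect_false(any(my$entry == "b"))         # checks removed
  cyc <- assemble_dataset(toy, "CYC")
  expect_setequal(unique(cyc$stage), c("GCA1", "GCA2"))
  expect_false(any(cyc$entry == "b"))
  expect_error(assemble_dataset(toy[toy$stage == "GCA2", ], "MY"), "empty")
})

test_that("stage-1 means reduce to simple entry means without nuisance variation", {
  cfg <- sim_config(n_entries = 12, n_years = 1, n_locations = 1,
                    n_testers = 1, n_trials_per_location = 1, n_markers = 100,
                    sigma2_y = 0, sigma2_l = 0, sigma2_t = 0, sigma2_gt = 0,
                    sigma2_gl = 0, sigma2_ls = 0, sigma2_lsr = 0,
                    sigma2_lsrb = 0, residual_variances = 2, seed = 41)
  sm <- sim_met(cfg)
  m <- fit_stage1_year(sm$plots, "Y1", fix = c(lsr = 0, lsrb = 0))
  simple <- tapply(sm$plots$yield, sm$plots$entry, mean)
  expect_equal(m$adjusted_mean, as.numeric(simple[m$entry]), tolerance = 1e-6)
  expect_true(all(m$weight > 0))
})

test_that("stage-1 EBLUEs equal least-squares adjusted means on a balanced RCBD", {
  # single location, single tester, homogeneous residual: complete blocks
  set.seed(42)
  q <- 10; r <- 3
  d <- expand.grid(entry = sprintf("E%02d", 1:q), rep = paste0("R", 1:r),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$year <- "Y1"; d$location <- "L1"; d$trial <- "S1"; d$tester <- "T1"
  d$block <- d$rep                      # one block per replicate
  d$yield <- rnorm(q)[factor(d$entry)] + rnorm(r)[factor(d$rep)] +
    rnorm(nrow(d), 0, 0.7)
  m <- fit_stage1_year(d, "Y1")
  ls <- lm(yield ~ entry + rep, d)
  grid <- data.frame(entry = sort(unique(d$entry)))
  lsmean <- vapply(grid$entry, function(e)
    mean(predict(ls, data.frame(entry = e, rep = paste0("R", 1:r)))), 0)
  expect_equal(m$adjusted_mean, unname(lsmean), tolerance = 1e-6)
})

test_that("stage 2 requires at least two years", {
  sm <- tiny_met(N = 10, years = 1, P = 100, seed = 43)
  m <- fit_stage1_year(sm$plots, "Y1")
  expect_error(fit_stage2(m, sm$truth$K), "single year")
})

test_that("two-stage and single-stage fits agree on balanced data", {
  sm <- tiny_met(N = 35, years = 1, P = 300, seed = 44)
  K <- sm$truth$K
  m <- fit_stage1_year(sm$plots, "Y1")
  # single-year genomic fit on the weighted means (no year terms)
  m$entry <- factor(m$entry)
  f2 <- reml_fit(adjusted_mean ~ 1, ~ gbv(entry), m, kinship = K,
                 weights = m$variance, fix_residual = TRUE)
  f1 <- fit_current_year_apparent(sm$plots, K)
  expect_equal(varcomp(f2)$estimate[1], apparent_variance(f1),
               tolerance = 0.15 * max(1, apparent_variance(f1)))
  expect_gt(cor(f2$blups[["gbv(entry)"]], f1$blups[["gbv(entry)"]]), 0.99)
})

test_that("apparent-fit estimates are invariant to entry relabeling", {
  sm <- tiny_met(N = 14, years = 1, P = 150, seed = 45)
  d <- sm$plots
  f1 <- fit_current_year_apparent(d, sm$truth$K)
  relab <- setNames(sprintf("Z%02d", 14:1), sort(unique(d$entry)))
  d2 <- transform(d, entry = relab[entry])
  K2 <- sm$truth$K
  rownames(K2) <- colnames(K2) <- relab[rownames(K2)]
  f2 <- fit_current_year_apparent(d2, K2)
  # agreement is limited by the REML stopping tolerance, not exact algebra:
  # relabeling permutes K and changes the iteration path
  expect_equal(apparent_variance(f2), apparent_variance(f1),
               tolerance = 2e-3)
  expect_equal(unname(sort(f2$blups[["gbv(entry)"]])),
               unname(sort(f1$blups[["gbv(entry)"]])), tolerance = 2e-3)
})

test_that("the rho refit shrinks the apparent GBLUPs by exactly rho", {
  sm <- tiny_met(N = 20, years = 1, P = 200, seed = 46)
  ap <- fit_current_year_apparent(sm$plots, sm$truth$K)
  for (rho in c(0.3, 0.75, 1)) {
    rf <- adjust_and_refit(sm$plots, sm$truth$K, ap, rho)
    expect_equal(rf$ghat, rho * ap$blups[["gbv(entry)"]], tolerance = 1e-8)
    expect_identical(rf$adjustment$sigma2_g_adj + rf$adjustment$sigma2_gy_adj,
                     rf$adjustment$sigma2_g_tilde)
  }
  expect_error(adjust_and_refit(sm$plots, sm$truth$K, ap, 0), "rho")
  expect_error(adjust_and_refit(sm$plots, sm$truth$K, ap, 1.1), "rho")
})

test_that("common-entry selection is the exact stage intersection", {
  cfg <- sim_config(n_entries = 30, n_markers = 100,
                    selection_fractions = c(0.4, 0.5), seed = 47)
  bp <- sim_breeding_program(cfg, n_cycles = 1)
  plots <- bp$plots
  # add a late entry present only in GCA2
  late <- plots[plots$stage == "GCA2", ][1:4, ]
  late$entry <- "LATE01"
  plots <- rbind(plots, late)
  sel <- select_common_entries(plots, 1)
  e1 <- unique(plots$entry[plots$stage == "GCA1"])
  e2 <- unique(plots$entry[plots$stage == "GCA2"])
  expect_setequal(unique(sel$entry), intersect(e1, e2))
  expect_false("LATE01" %in% sel$entry)
  expect_setequal(unique(sel$stage), c("GCA1", "GCA2"))
  expect_error(select_common_entries(plots[plots$stage == "GCA1", ], 1),
               "no common entries")
})

test_that("the two-year single-stage model recovers generating components", {
  # common-entry two-year panel so that truth is controlled
  devs_g <- devs_gy <- ses_g <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(n_entries = 90, n_years = 2, n_locations = 2,
                      n_trials_per_location = 1, n_markers = 600,
                      sigma2_g = 1.3, sigma2_gy = 0.45,
                      residual_variances = c(4, 5), seed = 500 + i)
    sm <- sim_met(cfg)
    sm$plots$stage <- ifelse(sm$plots$year == "Y1", "GCA1", "GCA2")
    sm$plots$cycle <- 1L
    g2 <- fit_gca2_cycle(select_common_entries(sm$plots, 1), sm$truth$K)
    devs_g[i] <- g2$sigma2_g - 1.3
    devs_gy[i] <- g2$sigma2_gy - 0.45
    vc <- varcomp(g2$fit)
    ses_g[i] <- vc$se[vc$component == "gbv(entry)"]
  }
  expect_lt(abs(mean(devs_g)), 3 * mean(ses_g, na.rm = TRUE))
  expect_lt(abs(mean(devs_gy)), 0.45)
})

test_that("year-label swap leaves the two-year fit invariant", {
  cfg <- sim_config(n_entries = 40, n_years = 2, n_locations = 2,
                    n_trials_per_location = 1, n_markers = 300,
                    residual_variances = c(4, 4), seed = 48)
  sm <- sim_met(cfg)
  sm$plots$stage <- ifelse(sm$plots$year == "Y1", "GCA1", "GCA2")
  sm$plots$cycle <- 1L
  f1 <- fit_gca2_cycle(sm$plots, sm$truth$K)
  swapped <- transform(sm$plots, year = ifelse(year == "Y1", "Y2", "Y1"),
                       stage = ifelse(year == "Y1", "GCA2", "GCA1"))
  f2 <- fit_gca2_cycle(swapped, sm$truth$K)
  expect_equal(f2$sigma2_g, f1$sigma2_g, tolerance = 1e-5)
  expect_equal(f2$sigma2_gy, f1$sigma2_gy, tolerance = 1e-5)
})
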