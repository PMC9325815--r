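test_that("design construction: intercept, incidence and genomic blocks", {
  d <- oneway_data(q = 4, r = 2)
  des <- build_design(y ~ 1, ~entry, d)
  expect_equal(unname(as.matrix(des$X)), matrix(1, 8, 1), ignore_attr = TRUE)
  Z <- des$terms$entry$Z
  expect_equal(dim(Z), c(8L, 4L))
  expect_true(all(Matrix::rowSums(Z) == 1))

  sm <- tiny_met(N = 10, years = 2, P = 100, seed = 3)
  means <- data.frame(entry = rep(rownames(sm$markers), 2),
                      year = rep(c("Y1", "Y2"), each = 10),
                      adjusted_mean = rnorm(20))
  des2 <- build_design(adjusted_mean ~ 1, ~ year + gbv(entry) +
                         gbv_by(entry, year), means, kinship = sm$truth$K)
  tm <- des2$terms[["gbv(entry):year"]]
  expect_equal(tm$type, "gbv_by")
  # per-year blocks: the factor of K_j reproduces the year's kinship
  for (j in 1:2) {
    L <- tm$map[[j]]
    expect_equal(L %*% t(L), sm$truth$K, ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  expect_error(build_design(adjusted_mean ~ 1, ~ gbv(entry), means,
                            kinship = sm$truth$K[1:5, 1:5]),
               "absent from the kinship")
})

test_that("MME solution matches the dense GLS/BLUP oracle exactly", {
  set.seed(21)
  sm <- tiny_met(N = 12, years = 1, P = 200, seed = 21)
  K <- sm$truth$K
  d <- sm$plots[sm$plots$year == "Y1", ]
  d$entry <- factor(d$entry)
  s2g <- 1.7; s2t <- 0.6; s2eA <- 1.2; s2eB <- 2.4
  fit <- reml_fit(yield ~ 1, ~ gbv(entry) + tester, d, kinship = K,
                  residual = ~location,
                  fix = c("gbv(entry)" = s2g, tester = s2t,
                          "units@L1" = s2eA, "units@L2" = s2eB))
  X <- matrix(1, nrow(d), 1)
  Zg <- model.matrix(~ 0 + entry, d)
  Zt <- model.matrix(~ 0 + factor(tester), d)
  Z <- cbind(Zg, Zt)
  G <- as.matrix(Matrix::bdiag(K * s2g, diag(s2t, 2)))
  R <- diag(ifelse(d$location == "L1", s2eA, s2eB))
  or <- blup_oracle(d$yield, X, Z, G, R)
  expect_equal(unname(fit$beta), or$beta, tolerance = 1e-8)
  expect_equal(unname(fit$blups[["gbv(entry)"]]), or$u[1:12],
               tolerance = 1e-8)
  expect_equal(unname(pev(fit, "gbv(entry)")), unname(or$C[1:12, 1:12]),
               tolerance = 1e-8)
})

test_that("with no random terms the fit reduces to ordinary least squares", {
  d <- oneway_data(q = 5, r = 3, seed = 2)
  fit <- reml_fit(y ~ entry, NULL, d, tol_loglik = 1e-12, tol_par = 1e-8)
  ols <- lm(y ~ entry, d)
  expect_equal(fit$beta, coef(ols), tolerance = 1e-8)
  expect_equal(varcomp(fit)$estimate, summary(ols)$sigma^2, tolerance = 1e-6)
})

test_that("balanced one-way GBLUP matches the closed-form shrinkage factor", {
  q <- 15; r <- 4; s2g <- 2.5; s2e <- 1.5
  d <- oneway_data(q = q, r = r, s2g = s2g, s2e = s2e, seed = 3)
  fit <- reml_fit(y ~ 1, ~entry, d, fix = c(entry = s2g, units = s2e))
  lam <- r * s2g / (r * s2g + s2e)
  ybar <- tapply(d$y, d$entry, mean)
  expect_equal(unname(fit$blups$entry), as.numeric(lam * (ybar - mean(ybar))),
               tolerance = 1e-8)
})

test_that("a huge plug-in genetic variance recovers GLS mean deviations", {
  d <- oneway_data(q = 8, r = 5, seed = 4)
  fit <- reml_fit(y ~ 1, ~entry, d, fix = c(entry = 1e8, units = 2))
  ybar <- tapply(d$y, d$entry, mean)
  expect_equal(unname(fit$blups$entry), as.numeric(ybar - mean(ybar)),
               tolerance = 1e-4)
})

test_that("REML equals the ANOVA moment estimator on balanced one-way data", {
  d <- oneway_data(q = 30, r = 6, s2g = 4, s2e = 2, seed = 5)
  fit <- reml_fit(y ~ 1, ~entry, d)
  a <- anova(lm(y ~ entry, d))
  msb <- a$`Mean Sq`[1]; mse <- a$`Mean Sq`[2]
  expect_equal(varcomp(fit)$estimate[1], (msb - mse) / 6, tolerance = 1e-5)
  expect_equal(varcomp(fit)$estimate[2], mse, tolerance = 1e-5)
})

test_that("REML agrees with lme4 on unbalanced crossed data", {
  skip_if_not_installed("lme4")
  set.seed(6)
  d <- expand.grid(a = gl(8, 1), b = gl(6, 1), r = 1:3)
  d <- d[-sample(nrow(d), 30), ]
  d$y <- rnorm(8)[d$a] + rnorm(6)[d$b] + rnorm(nrow(d))
  fit <- reml_fit(y ~ 1, ~ a + b, d)
  lf <- lme4::lmer(y ~ 1 + (1 | a) + (1 | b), d, REML = TRUE)
  vc <- lme4::VarCorr(lf)
  expect_equal(fit$logREML, as.numeric(logLik(lf)), tolerance = 1e-5)
  expect_equal(varcomp(fit)$estimate[varcomp(fit)$component == "a"],
               unname(unlist(vc)["a"]), tolerance = 1e-4)
  expect_equal(varcomp(fit)$estimate[varcomp(fit)$component == "units"],
               unname(attr(vc, "sc"))^2, tolerance = 1e-4)
})

test_that("components held fixed are returned unchanged and flagged", {
  d <- oneway_data(q = 10, r = 3, seed = 7)
  fit <- reml_fit(y ~ 1, ~entry, d, fix = c(entry = 1.0))
  vc <- varcomp(fit)
  expect_equal(vc$estimate[vc$component == "entry"], 1.0)
  expect_true(vc$fixed[vc$component == "entry"])
  expect_true(is.na(vc$se[vc$component == "entry"]))
  expect_false(vc$fixed[vc$component == "units"])
})

test_that("REML is equivariant under response rescaling", {
  d <- oneway_data(q = 12, r = 4, seed = 8)
  f1 <- reml_fit(y ~ 1, ~entry, d)
  d2 <- transform(d, y = 10 * y)
  f2 <- reml_fit(y ~ 1, ~entry, d2)
  expect_equal(varcomp(f2)$estimate, 100 * varcomp(f1)$estimate,
               tolerance = 1e-4)
})

test_that("re-solving at identical plug-in components reproduces the BLUPs", {
  sm <- tiny_met(N = 15, years = 1, P = 200, seed = 9)
  d <- sm$plots
  fit <- fit_current_year_apparent(d, sm$truth$K)
  th <- setNames(varcomp(fit)$estimate, varcomp(fit)$component)
  rerun <- fit_current_year_apparent(d, sm$truth$K, fix = th)
  expect_equal(rerun$blups[["gbv(entry)"]], fit$blups[["gbv(entry)"]],
               tolerance = 1e-8)
  expect_equal(rerun$beta, fit$beta, tolerance = 1e-8)
})

test_that("aliased fixed-effect columns are dropped deterministically", {
  d <- oneway_data(q = 6, r = 2, seed = 10)
  d$dup <- as.numeric(d$entry == "E01")   # aliased with the entry dummies
  fit <- reml_fit(y ~ entry + dup, NULL, data = d)
  expect_true("dup" %in% fit$dropped)
  expect_false("dup" %in% names(fit$beta))
})

test_that("a variance that is truly zero lands on the boundary and is flagged", {
  set.seed(11)
  d <- data.frame(grp = gl(20, 5), y = rnorm(100))  # no group signal
  fit <- reml_fit(y ~ 1, ~grp, d)
  vc <- varcomp(fit)
  expect_true(vc$boundary[vc$component == "grp"])
  expect_equal(vc$estimate[vc$component == "grp"], 0)
  expect_true(is.na(vc$se[vc$component == "grp"]))
})

test_that("non-convergence raises an informative error", {
  d <- oneway_data(q = 25, r = 4, seed = 12)
  expect_error(reml_fit(y ~ 1, ~entry, d, max_iter = 1,
                        tol_loglik = 1e-14, init = c(entry = 50, units = 50)),
               "converge")
})

test_that("unconditional variance of BLUPs equals D - C over replicate data", {
  # replicate-data Monte Carlo of var(ghat) against M = D - C on a small
  # one-location design with plugged-in true components
  N <- 8; reps <- 4000; s2g <- 2; s2e <- 1
  sm <- tiny_met(N = N, years = 1, P = 150, seed = 13)
  K <- sm$truth$K
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)))
  d <- expand.grid(entry = rownames(K), rep = 1:3)
  fit0 <- reml_fit(y ~ 1, ~ gbv(entry), transform(d, y = 0), kinship = K,
                   fix = c("gbv(entry)" = s2g, units = s2e),
                   keep_design = TRUE)
  C <- pev(fit0, "gbv(entry)")
  M <- K * s2g - C
  Zg <- model.matrix(~ 0 + entry, d)
  set.seed(14)
  G <- matrix(NA_real_, reps, N)
  for (i in seq_len(reps)) {
    g <- drop(L %*% rnorm(N)) * sqrt(s2g)
    y <- 5 + drop(Zg %*% g) + rnorm(nrow(d), 0, sqrt(s2e))
    G[i, ] <- refit_response(fit0, y)$blups[["gbv(entry)"]]
  }
  emp <- cov(G)
  se <- sqrt((outer(diag(M), diag(M)) + M^2) / reps)
  expect_lt(max(abs(emp - M) / se), 5)
})
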