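# The four analysis workflows: per-year stage-1 adjusted means, stage-2
# genomic model for the long-term variance ratio, the current-year apparent
# fit with its rho-adjustment rerun, and the two-year single-stage model for
# the second trial stage.

# disambiguate the nested design factors: trial within location, replicate
# within trial, block within replicate
add_nesting <- function(plots) {
  plots$ls <- interaction(plots$location, plots$trial, drop = TRUE,
                          sep = ":", lex.order = TRUE)
  plots$lsr <- interaction(plots$location, plots$trial, plots$rep,
                           drop = TRUE, sep = ":", lex.order = TRUE)
  plots$lsrb <- interaction(plots$location, plots$trial, plots$rep,
                            plots$block, drop = TRUE, sep = ":",
                            lex.order = TRUE)
  plots
}

check_plot_table <- function(plots, need = c("year", "location", "trial",
                                             "rep", "block", "tester",
                                             "entry", "yield")) {
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  invisible(plots)
}

#' Assemble the historical dataset for long-term rho estimation
#'
#' Two assemblies of the same plot table: `"MY"` keeps only first-stage
#' (GCA1) records of the requested years; `"CYC"` combines all stages of
#' all (complete and partial) cycles.  Check entries (flagged in the
#' logical `check` column) are removed in both.
#'
#' @param plots plot-level phenotype table.
#' @param mode `"MY"` or `"CYC"`.
#' @param years years to keep for `"MY"` (default: all but the most recent
#'   year present, which is the current selection year).
#' @return the filtered table.
#' @export
assemble_dataset <- function(plots, mode = c("MY", "CYC"), years = NULL) {
  mode <- match.arg(mode)
  check_plot_table(plots)
  if (!is.null(plots$check)) plots <- plots[!plots$check, , drop = FALSE]
  if (mode == "MY") {
    yrs <- sort(unique(as.character(plots$year)))
    if (is.null(years)) years <- yrs[-length(yrs)]
    plots <- plots[plots$stage == "GCA1" &
                     as.character(plots$year) %in% as.character(years), ,
                   drop = FALSE]
  }
  if (!nrow(plots)) stop("empty selection after ", mode, " assembly")
  droplevels(plots)
}

#' Stage 1: per-year adjusted entry means
#'
#' Fits the plot-level model of one year with fixed entry effects (so the
#' adjusted means are GLS estimates, EBLUEs, avoiding double shrinkage)
#' and random tester, location, entry-by-tester, entry-by-location, trial
#' within location, replicate and incomplete-block effects, with
#' location-specific residual variances.  Returns the entry means together
#' with Smith weights derived from their estimated covariance matrix.
#'
#' @param plots plot table (one or more years).
#' @param year the year to analyze.
#' @param weight_variant `"inverse_cov_diag"` (default: diagonal of the
#'   inverse of the EBLUE covariance matrix) or `"diag_inverse"` (inverse
#'   of its diagonal).
#' @param ... passed to [reml_fit()].
#' @return data frame (`entry`, `year`, `adjusted_mean`, `weight`,
#'   `variance`) with the stage-1 `"remlmm"` fit as attribute `"fit"`.
#' @export
fit_stage1_year <- function(plots, year,
                            weight_variant = c("inverse_cov_diag",
                                               "diag_inverse"), ...) {
  weight_variant <- match.arg(weight_variant)
  check_plot_table(plots)
  d <- droplevels(plots[as.character(plots$year) == as.character(year), ,
                        drop = FALSE])
  if (!nrow(d)) stop("no plots for year ", year)
  d <- add_nesting(d)
  d$entry <- factor(d$entry)
  # degenerate single-tester / single-location data: drop empty terms
  keep <- c(nlevels(factor(d$tester)) > 1, nlevels(factor(d$location)) > 1,
            nlevels(factor(d$tester)) > 1, nlevels(factor(d$location)) > 1,
            nlevels(d$ls) > nlevels(factor(d$location)), TRUE, TRUE)
  labs <- c("tester", "location", "entry:tester", "entry:location",
            "ls", "lsr", "lsrb")[keep]
  rand <- stats::as.formula(paste("~", paste(labs, collapse = " + ")))
  resid <- if (nlevels(factor(d$location)) > 1) ~location else ~1
  fit <- reml_fit(yield ~ entry, rand, d, residual = resid, ...)
  lev <- levels(d$entry)
  # entry means mu + beta_i as estimable functions of the fixed effects
  A <- matrix(0, length(lev), length(fit$beta),
              dimnames = list(lev, names(fit$beta)))
  A[, "(Intercept)"] <- 1
  cn <- paste0("entry", lev)
  dropped_entries <- lev[cn %in% fit$dropped]   # aliased with design factors
  for (i in seq_along(lev)) if (cn[i] %in% colnames(A)) A[i, cn[i]] <- 1
  est <- drop(A %*% fit$beta)
  Phi <- A %*% fit$fixed_cov %*% t(A)
  Phi <- (Phi + t(Phi)) / 2
  wts <- switch(weight_variant,
                inverse_cov_diag = diag(solve(Phi)),
                diag_inverse = 1 / diag(Phi))
  out <- data.frame(entry = lev, year = as.character(year),
                    adjusted_mean = est, weight = wts, variance = 1 / wts,
                    stringsAsFactors = FALSE)
  if (length(dropped_entries)) {
    warning("entries confounded with design factors dropped from means: ",
            paste(dropped_entries, collapse = ", "))
    out <- out[!out$entry %in% dropped_entries, , drop = FALSE]
  }
  attr(out, "fit") <- fit
  out
}

#' Stage 2: genomic model on multi-year adjusted means
#'
#' Fits `adjusted_mean = mu + year + gbv + gbv_by_year + e` with
#' \eqn{var(gbv) = K\sigma^2_g}, block-diagonal per-year kinship for the
#' GBV-by-year term (one common variance), and the residual fixed at the
#' Smith-weight variances from stage 1.  Returns the variance components,
#' the long-term ratio \eqn{\rho = \sigma^2_g/(\sigma^2_g+\sigma^2_{gy})}
#' and its delta-method standard error.
#'
#' @param means stacked output of [fit_stage1_year()] over >= 2 years.
#' @param K kinship covering every entry in `means`.
#' @param year_effect model the year main effect as `"random"` (default)
#'   or `"fixed"`.
#' @param ... passed to [reml_fit()].
#' @return list of class `"stage2_fit"`: `fit`, `rho`, `se_rho`,
#'   `sigma2_g`, `sigma2_gy`.
#' @export
fit_stage2 <- function(means, K, year_effect = c("random", "fixed"), ...) {
  year_effect <- match.arg(year_effect)
  if (length(unique(means$year)) < 2)
    stop("rho is not identifiable from a single year: use the current-year ",
         "apparent fit and a long-term rho instead")
  means$entry <- factor(means$entry)
  means$year <- factor(means$year)
  fx <- if (year_effect == "fixed") adjusted_mean ~ year else adjusted_mean ~ 1
  rd <- if (year_effect == "fixed") ~ gbv(entry) + gbv_by(entry, year) else
    ~ year + gbv(entry) + gbv_by(entry, year)
  fit <- reml_fit(fx, rd, means, kinship = K, weights = means$variance,
                  fix_residual = TRUE, ...)
  vc <- fit$components
  s2g <- vc$estimate[vc$component == "gbv(entry)"]
  s2gy <- vc$estimate[vc$component == "gbv(entry):year"]
  rho <- rho_from_components(s2g, s2gy)
  nm <- c("gbv(entry)", "gbv(entry):year")
  se <- if (!is.null(fit$ai_inverse) && all(nm %in% rownames(fit$ai_inverse)))
    se_rho_delta(s2g, s2gy, fit$ai_inverse[nm, nm]) else NA_real_
  structure(list(fit = fit, rho = rho, se_rho = se, sigma2_g = s2g,
                 sigma2_gy = s2gy), class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf(
    "stage-2 genomic fit: sigma2_g %.4f, sigma2_gy %.4f, rho %.3f (SE %.3f)\n",
    x$sigma2_g, x$sigma2_gy, x$rho, x$se_rho))
  invisible(x)
}

#' Current-year single-stage fit of the apparent genomic variance
#'
#' The stage-1 plot model with the fixed entry effect replaced by a random
#' GBV with covariance \eqn{K\sigma^2_{\tilde g}}.  Because a single year
#' cannot separate GBV from GBV-by-year effects, the genomic variance of
#' this fit is the apparent variance
#' \eqn{\sigma^2_{\tilde g} = \sigma^2_g + \sigma^2_{gy}}.
#'
#' @param plots single-year plot table.
#' @param K kinship covering the entries.
#' @param ... passed to [reml_fit()].
#' @return the `"remlmm"` fit; the apparent variance is the
#'   `"gbv(entry)"` component.
#' @export
fit_current_year_apparent <- function(plots, K, ...) {
  check_plot_table(plots)
  if (length(unique(plots$year)) != 1L)
    stop("apparent fit expects a single year of data")
  d <- add_nesting(droplevels(plots))
  d$entry <- factor(d$entry)
  labs <- c("tester", "location", "entry:tester", "entry:location",
            "ls", "lsr", "lsrb")
  keep <- c(nlevels(factor(d$tester)) > 1, nlevels(factor(d$location)) > 1,
            nlevels(factor(d$tester)) > 1, nlevels(factor(d$location)) > 1,
            nlevels(d$ls) > nlevels(factor(d$location)), TRUE, TRUE)
  rand <- stats::as.formula(paste("~ gbv(entry) +",
                                  paste(labs[keep], collapse = " + ")))
  resid <- if (nlevels(factor(d$location)) > 1) ~location else ~1
  reml_fit(yield ~ 1, rand, d, kinship = K, residual = resid, ...)
}

#' Apparent variance of a current-year fit
#' @param apparent_fit result of [fit_current_year_apparent()].
#' @return the apparent genomic variance.
#' @export
apparent_variance <- function(apparent_fit) {
  vc <- varcomp(apparent_fit)
  vc$estimate[vc$component == "gbv(entry)"]
}

#' Rerun the current-year model with the rho-split variance components
#'
#' Step 3 and 4 of the current-year assessment: the apparent variance is
#' split as \eqn{\sigma^2_g = \rho \sigma^2_{\tilde g}} and
#' \eqn{\sigma^2_{gy} = (1-\rho) \sigma^2_{\tilde g}}, and the single-year
#' model is re-solved *once* (no variance update) with two
#' kinship-structured random terms sharing the entry incidence matrix --
#' the GBV main effect and a GBV-by-year effect whose design matrix equals
#' the GBV one -- and every variance held fixed at its prespecified value.
#' The effect is increased shrinkage of the GBV BLUPs: with shared
#' incidence and proportional covariances,
#' \eqn{BLUP(u_g) = \rho \, BLUP(u_{\tilde g})} exactly.
#'
#' @param plots single-year plot table.
#' @param K kinship matrix.
#' @param apparent_fit result of [fit_current_year_apparent()] on the same
#'   data.
#' @param rho long-term ratio in (0, 1\].
#' @return list of class `"rho_refit"`: the rerun `"remlmm"` fit (`fit`),
#'   the `adjustment` (a [rho_adjust()] object), GBLUPs `ghat` of the GBV
#'   main effect and their PEV matrix `C`.
#' @export
adjust_and_refit <- function(plots, K, apparent_fit, rho) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  check_plot_table(plots)
  d <- add_nesting(droplevels(plots))
  d$entry <- factor(d$entry)
  d$year <- factor(d$year)
  adj <- rho_adjust(apparent_variance(apparent_fit), rho)
  vc <- varcomp(apparent_fit)
  fixv <- stats::setNames(vc$estimate, vc$component)
  fixv["gbv(entry)"] <- adj$sigma2_g_adj
  fixv <- c(fixv, "gbv(entry):year" = adj$sigma2_gy_adj)
  labs <- vc$component[!grepl("^gbv|^units", vc$component)]
  rand <- stats::as.formula(paste(
    "~ gbv(entry) + gbv_by(entry, year) +", paste(labs, collapse = " + ")))
  resid <- if (any(grepl("^units@", vc$component))) ~location else ~1
  fit <- reml_fit(yield ~ 1, rand, d, kinship = K, residual = resid,
                  fix = fixv)
  ghat <- fit$blups[["gbv(entry)"]]
  C <- pev(fit, "gbv(entry)")
  structure(list(fit = fit, adjustment = adj, ghat = ghat, C = C),
            class = "rho_refit")
}

#' @export
print.rho_refit <- function(x, ...) {
  print(x$adjustment)
  cat("GBLUPs of", length(x$ghat), "entries; mean PEV",
      format(mean(diag(x$C)), digits = 4), "\n")
  invisible(x)
}

#' Common entries of the first two trial stages of a cycle
#'
#' Keeps the GCA1 and GCA2 records of the entries present in both stages
#' of the given cycle (dropped-out entries contribute nothing to the
#' genetic variance that applies to the second stage); checks are removed.
#'
#' @param plots plot table with `cycle` and `stage` columns.
#' @param cycle cycle label.
#' @return the filtered two-stage table.
#' @export
select_common_entries <- function(plots, cycle) {
  check_plot_table(plots)
  d <- plots[plots$cycle == cycle & plots$stage %in% c("GCA1", "GCA2"), ,
             drop = FALSE]
  if (!is.null(d$check)) d <- d[!d$check, , drop = FALSE]
  e1 <- unique(d$entry[d$stage == "GCA1"])
  e2 <- unique(d$entry[d$stage == "GCA2"])
  common <- intersect(e1, e2)
  if (!length(common))
    stop("no common entries between GCA1 and GCA2 in cycle ", cycle)
  droplevels(d[d$entry %in% common, , drop = FALSE])
}

#' Single-stage genomic model for the second trial stage of a cycle
#'
#' Fits the two-year plot-level model in which tester, location,
#' entry-by-tester, entry-by-location, trial, replicate and block effects
#' are nested within years with year-specific variances (mimicking the
#' year-wise analysis), the GBV main effect has covariance
#' \eqn{K\sigma^2_g}, the GBV-by-year term block-diagonal per-year kinship
#' with a common variance, and year-location-specific residual variances.
#'
#' @param plots output of [select_common_entries()] (exactly two years).
#' @param K kinship matrix.
#' @param year_effect `"random"` (default) or `"fixed"` year main effect;
#'   with few years the random-year variance is often estimated at the
#'   zero boundary.
#' @param ... passed to [reml_fit()].
#' @return list of class `"gca2_fit"`: `fit`, `sigma2_g`, `sigma2_gy`,
#'   `rho`, GBLUPs `ghat` and PEV `C` of the GBV main effect.
#' @export
fit_gca2_cycle <- function(plots, K, year_effect = c("random", "fixed"),
                           ...) {
  year_effect <- match.arg(year_effect)
  check_plot_table(plots)
  d <- add_nesting(droplevels(plots))
  d$entry <- factor(d$entry)
  d$year <- factor(d$year)
  if (nlevels(d$year) != 2L)
    stop("expected exactly the two years of a GCA1/GCA2 pair")
  labs <- c("at(location, year)", "at(tester, year)",
            "at(entry:tester, year)", "at(entry:location, year)",
            "at(ls, year)", "at(lsr, year)", "at(lsrb, year)")
  keep <- c(nlevels(factor(d$location)) > 1, nlevels(factor(d$tester)) > 1,
            nlevels(factor(d$tester)) > 1, nlevels(factor(d$location)) > 1,
            nlevels(d$ls) > nlevels(factor(d$location)), TRUE, TRUE)
  rand <- paste("~ gbv(entry) + gbv_by(entry, year) +",
                paste(labs[keep], collapse = " + "))
  fx <- yield ~ 1
  if (year_effect == "fixed") fx <- yield ~ year else
    rand <- paste(rand, "+ year")
  fit <- reml_fit(fx, stats::as.formula(rand), d, kinship = K,
                  residual = ~ year:location, ...)
  vc <- fit$components
  s2g <- vc$estimate[vc$component == "gbv(entry)"]
  s2gy <- vc$estimate[vc$component == "gbv(entry):year"]
  structure(list(fit = fit, sigma2_g = s2g, sigma2_gy = s2gy,
                 rho = if (s2g + s2gy > 0)
                   rho_from_components(s2g, s2gy) else NA_real_,
                 ghat = fit$blups[["gbv(entry)"]],
                 C = pev(fit, "gbv(entry)")), class = "gca2_fit")
}

#' @export
print.gca2_fit <- function(x, ...) {
  cat(sprintf(
    "two-year single-stage genomic fit: sigma2_g %.4f, sigma2_gy %.4f (N = %d)\n",
    x$sigma2_g, x$sigma2_gy, length(x$ghat)))
  invisible(x)
}
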