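#' Configuration for the synthetic trial-network generator
#'
#' Collects the design dimensions and variance components used to emulate a
#' testcross multi-environment trial network: several years, locations with
#' alpha-design trials (replicates subdivided into incomplete blocks), two
#' testers, marker-derived genomic breeding values (GBV), kinship-structured
#' GBV-by-year effects, and location-specific residual variances.  Defaults
#' are yield-like (dt/ha scale) with variance magnitudes typical of hybrid
#' rye testcross trials.
#'
#' @param n_entries entries per cycle cohort (first element is the entry
#'   count of the first trial stage; later elements, if given, override the
#'   counts implied by `selection_fractions`).
#' @param n_years number of years (for [sim_met()], all entries are tested
#'   in every year).
#' @param n_locations,n_trials_per_location,n_reps,n_testers design counts.
#' @param block_size approximate plots per incomplete block within a
#'   replicate.
#' @param n_markers,allele_freq_range,missing_rate marker panel settings;
#'   per-marker allele frequencies are drawn uniformly from
#'   `allele_freq_range`.
#' @param mu trait mean (trait units).
#' @param sigma2_y,sigma2_g,sigma2_gy year, GBV and GBV-by-year variances.
#' @param sigma2_l,sigma2_t,sigma2_gt,sigma2_gl,sigma2_ls,sigma2_lsr,sigma2_lsrb
#'   variances of location, tester, entry-by-tester, entry-by-location,
#'   trial-within-location, replicate and incomplete-block effects (all
#'   nested within year).
#' @param residual_variances per-location residual variances, recycled over
#'   locations.
#' @param selection_fractions fractions (0, 1] of entries advanced between
#'   successive trial stages of a cycle.
#' @param coverage fraction of entries tested per location (1 = full
#'   testing; below 1 emulates sparse testing by random entry subsets).
#' @param seed integer seed making every generated object reproducible.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_entries = 300, n_years = 4, n_locations = 3,
                       n_trials_per_location = 2, n_reps = 2, n_testers = 2,
                       block_size = 15, n_markers = 2000,
                       allele_freq_range = c(0.1, 0.9), missing_rate = 0,
                       mu = 100, sigma2_y = 20, sigma2_g = 2, sigma2_gy = 1.4,
                       sigma2_l = 10, sigma2_t = 1, sigma2_gt = 0.3,
                       sigma2_gl = 0.5, sigma2_ls = 2, sigma2_lsr = 1,
                       sigma2_lsrb = 1, residual_variances = c(8, 10, 12),
                       selection_fractions = c(0.3, 0.3), coverage = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  vars <- grep("^sigma2", names(cfg), value = TRUE)
  if (any(unlist(cfg[vars]) < 0)) stop("variances must be >= 0")
  if (any(residual_variances <= 0)) stop("residual variances must be > 0")
  if (any(selection_fractions <= 0 | selection_fractions > 1))
    stop("selection fractions must lie in (0, 1]")
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0)
    stop("allele_freq_range must be an increasing pair within (0, 1)")
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  stopifnot(n_entries >= 2, n_markers >= 1, n_years >= 1, n_locations >= 1,
            n_trials_per_location >= 1, n_reps >= 1, n_testers >= 1)
  structure(cfg, class = "sim_config")
}

#' Generate a biallelic marker panel
#'
#' Dosages are drawn per marker as Binomial(2, p_j) with p_j uniform in the
#' configured allele-frequency range, so entries are unrelated and in
#' Hardy-Weinberg proportions.  An optional missingness mask is applied at
#' `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param n_entries optional override of the number of entries.
#' @param entry_ids optional entry labels.
#' @return dosage matrix (entries x markers) with `NA` for masked calls.
#' @export
generate_markers <- function(config, n_entries = config$n_entries,
                             entry_ids = NULL) {
  set.seed(config$seed)
  N <- n_entries; P <- config$n_markers
  p <- runif(P, config$allele_freq_range[1], config$allele_freq_range[2])
  M <- vapply(p, function(pj) rbinom(N, 2L, pj), numeric(N))
  if (config$missing_rate > 0)
    M[runif(length(M)) < config$missing_rate] <- NA
  rownames(M) <- if (is.null(entry_ids)) sprintf("E%04d", seq_len(N)) else entry_ids
  colnames(M) <- sprintf("M%05d", seq_len(P))
  M
}

#' Generate true genetic effects
#'
#' True GBVs are built as \eqn{u_g = Q_c v} with marker effects
#' \eqn{v \sim N(0, \sigma^2_g / c)} under the VanRaden scaling, so that
#' \eqn{var(u_g) = K \sigma^2_g} exactly.  GBV-by-year effects are drawn
#' independently per year from \eqn{MVN(0, K \sigma^2_{gy})}.
#'
#' @param markers dosage matrix without missing values (impute first).
#' @param config a [sim_config()].
#' @param n_years override of the number of years.
#' @return list with `true_gbv` (named vector), `true_gby` (entries x
#'   years), `marker_effects`, and the kinship `K` used.
#' @export
generate_true_effects <- function(markers, config, n_years = config$n_years) {
  if (ncol(markers) < 1) stop("at least one marker required")
  markers <- impute_missing(markers)
  K <- vanraden_kinship(markers)
  cc <- attr(K, "c")
  set.seed(config$seed + 1L)
  v <- rnorm(ncol(markers), 0, sqrt(config$sigma2_g / cc))
  p <- colMeans(markers) / 2
  Qc <- sweep(markers, 2L, 2 * p, `-`)
  u <- drop(Qc %*% v)
  names(u) <- rownames(markers)
  gby <- matrix(0, nrow(markers), n_years,
                dimnames = list(rownames(markers), paste0("Y", seq_len(n_years))))
  if (config$sigma2_gy > 0) {
    ek <- eigen(K, symmetric = TRUE)
    L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), nrow(K))
    gby[] <- L %*% matrix(rnorm(nrow(K) * n_years, 0, sqrt(config$sigma2_gy)),
                          nrow(K), n_years)
  }
  list(true_gbv = u, true_gby = gby, marker_effects = v, K = K)
}

#' Generate plot-level phenotypes for one or more years
#'
#' Lays out, for every year and location, `n_trials_per_location`
#' alpha-design-like trials (entries split into trial series, each trial
#' with `n_reps` complete replicates subdivided into incomplete blocks of
#' about `block_size` plots) crossed with the testers, then builds plot
#' yields as the sum of the configured effects, all drawn independently per
#' year (nuisance factors are nested within years) plus the entry's true
#' GBV and its GBV-by-year deviation.  Residual standard deviations are
#' location-specific.
#'
#' @param truth output of [generate_true_effects()].
#' @param config a [sim_config()].
#' @param entries entry ids to test (default: all entries in `truth`).
#' @param years integer vector of year indices (columns of `true_gby`).
#' @param stage,cycle labels stored on the generated rows.
#' @param seed seed for layout and effect draws (default derived from the
#'   config seed and the first year).
#' @return a data frame with columns cycle, stage, year, location, trial,
#'   rep, block, tester, entry, check, yield.
#' @export
generate_phenotypes <- function(truth, config, entries = names(truth$true_gbv),
                                years = seq_len(ncol(truth$true_gby)),
                                stage = "GCA1", cycle = 1L, seed = NULL) {
  if (length(entries) < 2) stop("need at least 2 entries")
  if (is.null(seed)) seed <- config$seed + 1000L + years[1]
  set.seed(seed)
  out <- vector("list", length(years))
  for (w in seq_along(years)) {
    yr <- years[w]
    year_eff <- rnorm(1, 0, sqrt(config$sigma2_y))
    loc_ids <- paste0("L", seq_len(config$n_locations))
    loc_eff <- setNames(rnorm(length(loc_ids), 0, sqrt(config$sigma2_l)), loc_ids)
    tes_ids <- paste0("T", seq_len(config$n_testers))
    tes_eff <- setNames(rnorm(length(tes_ids), 0, sqrt(config$sigma2_t)), tes_ids)
    gt_eff <- matrix(rnorm(length(entries) * length(tes_ids), 0,
                           sqrt(config$sigma2_gt)),
                     length(entries), length(tes_ids),
                     dimnames = list(entries, tes_ids))
    gl_eff <- matrix(rnorm(length(entries) * length(loc_ids), 0,
                           sqrt(config$sigma2_gl)),
                     length(entries), length(loc_ids),
                     dimnames = list(entries, loc_ids))
    res_sd <- sqrt(rep_len(config$residual_variances, length(loc_ids)))
    # entries are split once per year into trial series tested at every location
    series <- split(sample(entries),
                    rep_len(seq_len(config$n_trials_per_location), length(entries)))
    rows <- vector("list", 0L)
    for (loc in loc_ids) {
      tested <- if (config$coverage < 1) {
        n_cov <- max(2L, ceiling(config$coverage * length(entries)))
        sample(entries, n_cov)
      } else entries
      for (tr in seq_along(series)) {
        ent_tr <- intersect(series[[tr]], tested)
        if (length(ent_tr) < 2) next
        ls_eff <- rnorm(1, 0, sqrt(config$sigma2_ls))
        for (r in seq_len(config$n_reps)) {
          lsr_eff <- rnorm(1, 0, sqrt(config$sigma2_lsr))
          plots <- expand.grid(entry = ent_tr, tester = tes_ids,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
          n_blk <- max(1L, round(nrow(plots) / config$block_size))
          blk <- sample(rep_len(seq_len(n_blk), nrow(plots)))
          blk_eff <- rnorm(n_blk, 0, sqrt(config$sigma2_lsrb))
          e <- rnorm(nrow(plots), 0, res_sd[match(loc, loc_ids)])
          yield <- config$mu + year_eff + loc_eff[loc] + tes_eff[plots$tester] +
            truth$true_gbv[plots$entry] + truth$true_gby[plots$entry, yr] +
            gt_eff[cbind(plots$entry, plots$tester)] +
            gl_eff[cbind(plots$entry, loc)] +
            ls_eff + lsr_eff + blk_eff[blk] + e
          rows[[length(rows) + 1L]] <- data.frame(
            cycle = cycle, stage = stage, year = paste0("Y", yr),
            location = loc, trial = paste0("S", tr), rep = paste0("R", r),
            block = paste0("B", blk), tester = plots$tester,
            entry = plots$entry, check = FALSE, yield = unname(yield),
            stringsAsFactors = FALSE)
        }
      }
    }
    out[[w]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a common-entry multi-year trial panel
#'
#' Convenience wrapper: markers, true effects, and `n_years` of plot data
#' for the same entry set, as used for long-term variance-ratio estimation.
#'
#' @param config a [sim_config()].
#' @return list with `markers`, `truth` (incl. kinship `K`), and `plots`.
#' @export
sim_met <- function(config) {
  markers <- generate_markers(config)
  truth <- generate_true_effects(markers, config)
  plots <- generate_phenotypes(truth, config)
  list(markers = markers, truth = truth, plots = plots, config = config)
}

#' Simulate a multi-cycle breeding program
#'
#' Each cycle starts with a fresh cohort of `n_entries` testcross entries in
#' its first trial stage (GCA1); a fraction of them (default: ranked on true
#' GBV, so that truth is controlled) advances to GCA2 the following year and
#' again to GCA3.  Cycle `c` occupies years `c`, `c + 1`, `c + 2`.
#'
#' @param config a [sim_config()]; `selection_fractions` controls the
#'   advanced fractions and `n_cycles` the number of cohorts.
#' @param n_cycles number of cycles started.
#' @param criterion ranking used for advancement: true GBV (default) or the
#'   phenotypic entry mean of the preceding stage.
#' @return list with `markers`, `truth`, `plots` (all cycles and stages
#'   stacked) and `config`.
#' @export
sim_breeding_program <- function(config, n_cycles = 3,
                                 criterion = c("true_gbv", "phenotype")) {
  criterion <- match.arg(criterion)
  stages <- c("GCA1", "GCA2", "GCA3")
  n_stages <- min(length(config$selection_fractions) + 1L, length(stages))
  n_years <- n_cycles + n_stages - 1L
  N_total <- config$n_entries * n_cycles
  markers <- generate_markers(config, n_entries = N_total)
  truth <- generate_true_effects(markers, config, n_years = n_years)
  cohorts <- split(rownames(markers), rep(seq_len(n_cycles), each = config$n_entries))
  plots <- vector("list", 0L)
  for (cyc in seq_len(n_cycles)) {
    ents <- cohorts[[cyc]]
    for (s in seq_len(n_stages)) {
      yr <- cyc + s - 1L
      if (yr > n_years) break
      ph <- generate_phenotypes(truth, config, entries = ents, years = yr,
                                stage = stages[s], cycle = cyc,
                                seed = config$seed + 5000L + 100L * cyc + s)
      plots[[length(plots) + 1L]] <- ph
      if (s < n_stages) {
        frac <- config$selection_fractions[s]
        n_keep <- max(2L, floor(frac * length(ents)))
        if (n_keep < 2) stop("selection fraction leaves fewer than 2 entries")
        score <- if (criterion == "true_gbv") truth$true_gbv[ents] else
          tapply(ph$yield, ph$entry, mean)[ents]
        ents <- names(sort(score, decreasing = TRUE))[seq_len(n_keep)]
      }
    }
  }
  plots <- do.call(rbind, plots)
  rownames(plots) <- NULL
  list(markers = markers, truth = truth, plots = plots, config = config)
}
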