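#' End-to-end current-year (GCA1) selection-response assessment
#'
#' Runs the full current-year workflow: assemble the historical data
#' (`"MY"` or `"CYC"`), fit stage-1 adjusted means per year, fit the
#' stage-2 genomic model to estimate the long-term ratio \eqn{\rho},
#' fit the current-year apparent model, split and refit with the
#' \eqn{\rho}-adjusted components, build and factor \eqn{\Omega}, and
#' simulate the selection probabilities.
#'
#' @param plots plot table holding historical years and the current year.
#' @param K kinship covering all entries involved.
#' @param mode historical assembly, `"MY"` or `"CYC"`.
#' @param current_year label of the selection year (default: most recent
#'   year present).
#' @param rho optional plug-in \eqn{\rho}, skipping the historical fits.
#' @param S,seed,percent_grid,m_list simulation settings, see
#'   [simulate_selection()].
#' @param year_effect year main effect in stage 2, `"random"` or
#'   `"fixed"`.
#' @param verbose print stage progress.
#' @return list of class `"gca1_assessment"`: `stage2` (with `rho`,
#'   `se_rho`), `apparent`, `refit` (incl. the exact variance split),
#'   `omega`, `sim` (a `"selection_sim"`), and bookkeeping (`mode`,
#'   `current_year`, `seed`).
#' @export
run_gca1_assessment <- function(plots, K, mode = c("MY", "CYC"),
                                current_year = NULL, rho = NULL,
                                S = 10000, seed = 1L, percent_grid = 1:100,
                                m_list = c(1, 5, 10, 15, 20),
                                year_effect = "random", verbose = FALSE) {
  mode <- match.arg(mode)
  check_plot_table(plots)
  yrs <- sort(unique(as.character(plots$year)))
  if (is.null(current_year)) current_year <- yrs[length(yrs)]
  say <- function(...) if (verbose) message("[", mode, "] ", ...)
  stage2 <- NULL
  if (is.null(rho)) {
    hist <- plots[as.character(plots$year) != as.character(current_year), ,
                  drop = FALSE]
    hist <- assemble_dataset(hist, mode,
                             years = unique(as.character(hist$year)))
    say("stage 1: ", length(unique(hist$year)), " years")
    means <- do.call(rbind, lapply(sort(unique(as.character(hist$year))),
                                   function(y) fit_stage1_year(hist, y)))
    say("stage 2 on ", nrow(means), " entry-year means")
    stage2 <- fit_stage2(means, K, year_effect = year_effect)
    rho <- stage2$rho
    say(sprintf("rho = %.3f (SE %.3f)", rho, stage2$se_rho))
  }
  cur <- droplevels(plots[as.character(plots$year) ==
                            as.character(current_year) &
                            plots$stage == "GCA1", , drop = FALSE])
  if (!is.null(cur$check)) cur <- cur[!cur$check, , drop = FALSE]
  if (!nrow(cur)) stop("no current-year GCA1 plots for ", current_year)
  say("current-year apparent fit (", length(unique(cur$entry)), " entries)")
  apparent <- fit_current_year_apparent(cur, K)
  refit <- adjust_and_refit(cur, K, apparent, rho)
  ent <- names(refit$ghat)
  om <- factor_omega(build_omega(K[ent, ent],
                                 refit$adjustment$sigma2_g_adj, refit$C))
  say("simulating S = ", S, " draws (", om$method, ")")
  sim <- simulate_selection(om, S = S, seed = seed,
                            percent_grid = percent_grid, m_list = m_list)
  structure(list(mode = mode, current_year = current_year, stage2 = stage2,
                 rho = rho, apparent = apparent, refit = refit, omega = om,
                 sim = sim, seed = seed), class = "gca1_assessment")
}

#' @export
print.gca1_assessment <- function(x, ...) {
  cat("Current-year (GCA1) selection-response assessment, mode", x$mode, "\n")
  if (!is.null(x$stage2)) print(x$stage2)
  print(x$refit$adjustment)
  print(x$sim)
  invisible(x)
}

#' End-to-end second-stage (GCA2) assessment per cycle
#'
#' For each requested cycle: restrict to the entries common to the first
#' two trial stages, fit the two-year single-stage genomic model, build
#' and factor \eqn{\Omega} from its GBV variance and PEV matrix, and
#' simulate the selection probabilities.
#'
#' @param plots plot table with `cycle`/`stage` columns (e.g. from
#'   [sim_breeding_program()]).
#' @param K kinship matrix.
#' @param cycles cycle labels to assess (default: all with both stages).
#' @inheritParams run_gca1_assessment
#' @return named list (one element per cycle) of class
#'   `"gca2_assessment"`; each element holds `gca2` (the fit), `omega`,
#'   `sim`, and the common-entry count `N` with its binomial
#'   Monte-Carlo standard error scale `mc_se_max = 0.5/sqrt(S)`.
#' @export
run_gca2_assessment <- function(plots, K, cycles = NULL, S = 10000,
                                seed = 1L, percent_grid = 1:100,
                                m_list = c(1, 5, 10, 15, 20),
                                year_effect = "random", verbose = FALSE) {
  check_plot_table(plots)
  if (is.null(cycles)) {
    tab <- unique(plots[, c("cycle", "stage")])
    cycles <- sort(unique(tab$cycle[tab$stage == "GCA2"]))
    cycles <- intersect(cycles, tab$cycle[tab$stage == "GCA1"])
  }
  out <- lapply(cycles, function(cy) {
    if (verbose) message("[GCA2] cycle ", cy)
    d <- select_common_entries(plots, cy)
    g2 <- fit_gca2_cycle(d, K, year_effect = year_effect)
    ent <- names(g2$ghat)
    if (g2$sigma2_g <= 0) {
      warning("cycle ", cy, ": GBV variance estimated at the zero boundary; ",
              "no simulation possible")
      return(list(cycle = cy, gca2 = g2, omega = NULL, sim = NULL,
                  N = length(ent), mc_se_max = 0.5 / sqrt(S)))
    }
    om <- factor_omega(build_omega(K[ent, ent], g2$sigma2_g, g2$C))
    sim <- simulate_selection(om, S = S, seed = seed + as.integer(
      factor(cy, levels = cycles)), percent_grid = percent_grid,
      m_list = m_list)
    list(cycle = cy, gca2 = g2, omega = om, sim = sim,
         N = length(ent), mc_se_max = 0.5 / sqrt(S))
  })
  names(out) <- paste0("cycle_", cycles)
  structure(out, class = "gca2_assessment")
}

#' @export
print.gca2_assessment <- function(x, ...) {
  cat("Second-stage (GCA2) selection-response assessment:\n")
  for (el in x) {
    cat("\n-- cycle", el$cycle, "(", el$N, "common entries )\n")
    print(el$gca2)
    if (is.null(el$sim))
      cat("   GBV variance at zero boundary: no simulation\n")
    else
      cat(sprintf("   mean corr(g, ghat) %.3f; max MC SE %.4f\n",
                  el$sim$corr_value, el$mc_se_max))
  }
  invisible(x)
}
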