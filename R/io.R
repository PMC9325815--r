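# Plain-text interchange: tidy phenotype CSV, genotype CSV (entries in
# rows, NA = missing), labelled square matrices for K and C, JSON fit
# reports.

#' Read a plot-level phenotype table
#'
#' @param path CSV/TSV file with columns year, location, trial, rep,
#'   block, tester, entry, yield (plus optional cycle, stage, check).
#' @param sep field separator (guessed from the extension by default).
#' @return data frame ready for the pipeline functions.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  check_plot_table(d)
  if (is.null(d$check)) d$check <- FALSE
  if (is.null(d$stage)) d$stage <- "GCA1"
  if (is.null(d$cycle)) d$cycle <- 1L
  d
}

#' Read a genotype dosage matrix
#'
#' @param path CSV/TSV with entry ids in the first column and one column
#'   per marker; dosages 0/1/2, empty or NA = missing.
#' @inheritParams read_phenotypes
#' @return numeric matrix (entries x markers).
#' @export
read_genotypes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.csv(path, sep = sep, check.names = FALSE,
                       stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  as_marker_matrix(m)
}

#' Write / read a labelled square matrix (kinship, PEV) as CSV
#'
#' The entry labels are carried both as header and as first column, and
#' validated on reading.
#'
#' @param x square matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(nrow(x) == ncol(x), !is.null(rownames(x)))
  d <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path)
  m
}

#' Serialize a fit report to JSON
#'
#' Components (estimate, SE, flags), log restricted likelihood, and --
#' when present -- rho with its delta-method SE.
#'
#' @param fit a `"remlmm"`, `"stage2_fit"` or `"gca2_fit"` object.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list()
  core <- if (inherits(fit, "remlmm")) fit else fit$fit
  rep$components <- varcomp(core)
  rep$logREML <- core$logREML
  rep$converged <- core$converged
  rep$iterations <- core$iterations
  if (!is.null(core$ai_inverse)) rep$ai_inverse <- core$ai_inverse
  if (inherits(fit, c("stage2_fit", "gca2_fit"))) {
    rep$rho <- fit$rho
    rep$sigma2_g <- fit$sigma2_g
    rep$sigma2_gy <- fit$sigma2_gy
    if (!is.null(fit$se_rho)) rep$se_rho <- fit$se_rho
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write phenotype, marker and truth tables of a simulated dataset
#'
#' @param sim output of [sim_met()] or [sim_breeding_program()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$plots, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  g <- data.frame(entry = rownames(sim$markers),
                  as.data.frame(sim$markers, check.names = FALSE),
                  check.names = FALSE)
  utils::write.csv(g, file.path(dir, "genotypes.csv"), row.names = FALSE)
  tr <- data.frame(entry = names(sim$truth$true_gbv),
                   true_gbv = unname(sim$truth$true_gbv),
                   as.data.frame(sim$truth$true_gby, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
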