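#' Marker quality control
#'
#' Drops markers that are monomorphic, have minor allele frequency below
#' `maf_min`, or exceed `max_missing` missing calls.  Allele frequencies are
#' computed from the non-missing calls of the analyzed entry set.
#'
#' @param markers numeric matrix of allele dosages in \{0, 1, 2\} with `NA`
#'   for missing calls; rows are entries (rownames = entry ids), columns are
#'   markers.
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\].
#' @param max_missing maximum tolerated fraction of missing calls per
#'   marker, in \[0, 1\].
#' @return the filtered marker matrix, with a `"qc"` attribute listing the
#'   number of markers dropped per rule (`monomorphic`, `low_maf`,
#'   `missing`) and the number retained.
#' @examples
#' m <- rbind(a = c(0, 2, 2), b = c(2, 2, 0), c = c(1, 2, NA))
#' filter_markers(m, maf_min = 0.05, max_missing = 0.5)
#' @export
filter_markers <- function(markers, maf_min = 0.05, max_missing = 0.10) {
  markers <- as_marker_matrix(markers)
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  miss_frac <- colMeans(is.na(markers))
  p <- colMeans(markers, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA                       # fully-missing marker
  maf <- pmin(p, 1 - p)
  drop_missing <- miss_frac > max_missing | is.na(p)
  drop_mono    <- !drop_missing & maf == 0
  drop_maf     <- !drop_missing & !drop_mono & maf < maf_min
  keep <- !(drop_missing | drop_mono | drop_maf)
  if (!any(keep)) {
    binding <- c(missing = sum(drop_missing), monomorphic = sum(drop_mono),
                 low_maf = sum(drop_maf))
    stop("all markers dropped by QC (binding rule: ",
         names(binding)[which.max(binding)], ")")
  }
  out <- markers[, keep, drop = FALSE]
  attr(out, "qc") <- list(n_in = ncol(markers), n_retained = sum(keep),
                          monomorphic = sum(drop_mono), low_maf = sum(drop_maf),
                          missing = sum(drop_missing),
                          maf_min = maf_min, max_missing = max_missing)
  out
}

#' Mean imputation of missing marker calls
#'
#' Replaces each missing dosage by the marker mean \eqn{2\hat p_j} computed
#' from the observed calls.
#'
#' @inheritParams filter_markers
#' @return the marker matrix with no missing values.
#' @export
impute_missing <- function(markers) {
  markers <- as_marker_matrix(markers)
  if (!anyNA(markers)) return(markers)
  mu <- colMeans(markers, na.rm = TRUE)
  if (anyNA(mu)) stop("marker(s) with no observed calls; filter first")
  idx <- which(is.na(markers), arr.ind = TRUE)
  markers[idx] <- mu[idx[, 2L]]
  markers
}

#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{K = Q_c Q_c' / c} where `Q` is centred per marker by
#' \eqn{2\hat p_j} and \eqn{c = 2 \sum_j \hat p_j (1 - \hat p_j)}
#' (VanRaden's first method).  Rows of `K` sum to zero by construction;
#' alternative scalings change only the paired variance component, not the
#' resulting BLUPs.
#'
#' @inheritParams filter_markers
#' @return an N x N symmetric relationship matrix with entry ids as
#'   dimnames and the scaling constant as attribute `"c"`.
#' @examples
#' m <- rbind(a = c(0, 0), b = c(2, 2))
#' vanraden_kinship(m)   # [[2, -2], [-2, 2]]
#' @export
vanraden_kinship <- function(markers) {
  markers <- as_marker_matrix(markers)
  if (anyNA(markers)) stop("missing marker calls; impute_missing() first")
  p <- colMeans(markers) / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc <= 0) stop("all markers monomorphic: VanRaden scaling constant is 0")
  Qc <- sweep(markers, 2L, 2 * p, `-`)
  K <- tcrossprod(Qc) / cc
  K <- (K + t(K)) / 2
  attr(K, "c") <- cc
  K
}

# Validate and coerce a dosage matrix (entries x markers).
as_marker_matrix <- function(markers) {
  markers <- as.matrix(markers)
  if (!is.numeric(markers)) stop("marker matrix must be numeric 0/1/2 dosages")
  rng <- range(markers, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)   # imputed means are allowed, codes are not
    stop("marker dosages must lie in [0, 2] (codes 0/1/2, NA missing)")
  if (is.null(rownames(markers)))
    rownames(markers) <- paste0("E", seq_len(nrow(markers)))
  if (is.null(colnames(markers)))
    colnames(markers) <- paste0("M", seq_len(ncol(markers)))
  if (anyDuplicated(rownames(markers))) stop("duplicated entry ids")
  if (anyDuplicated(colnames(markers))) stop("duplicated marker ids")
  markers
}
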