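# Design construction for the mixed-model engine.
#
# The random-term grammar accepts a one-sided formula whose terms are either
# plain (possibly interacted) factors, fitted iid, or one of the specials
#   gbv(fac)            kinship-structured effect, var = K sigma2
#   gbv_by(fac, by)     block-diagonal per level of `by`, blocks K_j sigma2
#                       with K_j the kinship of the fac levels present in
#                       that `by` level (a GBV-by-year term)
#   at(fac, by)         iid effect of fac nested in `by` with a separate
#                       variance per level of `by`
# Kinship-structured terms are reparameterized through a factor L of K
# (Cholesky when K is positive definite, eigen with clipped spectrum
# otherwise), so the engine only ever sees identity priors; BLUPs and the
# prediction-error-variance block are mapped back through L.

ind_matrix <- function(f) {
  f <- droplevels(as.factor(f))
  if (anyNA(f)) stop("NA in a model factor")
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# lower-triangular-ish factor of a PSD matrix: L with L L' = A
psd_factor <- function(A, tol = 1e-8) {
  L <- tryCatch(t(chol(A)), error = function(e) NULL)
  if (!is.null(L)) return(list(L = L, rank = ncol(A), clipped = 0L))
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lmax <- max(ea$values, 0)
  if (any(ea$values < -tol * max(lmax, 1)))
    stop("matrix has eigenvalue below -tol: not positive semi-definite")
  keep <- ea$values > tol * max(lmax, 1)
  if (!any(keep)) stop("matrix is numerically zero")
  L <- ea$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ea$values[keep]), sum(keep))
  rownames(L) <- rownames(A)
  list(L = L, rank = sum(keep), clipped = sum(!keep))
}

get_kinship <- function(kinship, name = NULL) {
  if (is.matrix(kinship)) return(kinship)
  if (is.list(kinship)) {
    if (is.null(name)) {
      if (length(kinship) == 1L) return(kinship[[1L]])
      stop("several kinship matrices supplied; name one in the term, e.g. gbv(entry, K = \"K1\")")
    }
    if (!name %in% names(kinship)) stop("kinship matrix '", name, "' not supplied")
    return(kinship[[name]])
  }
  stop("no kinship matrix supplied for a gbv() term")
}

sub_kinship <- function(K, levels) {
  missing <- setdiff(levels, rownames(K))
  if (length(missing))
    stop("entries absent from the kinship matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  K[levels, levels, drop = FALSE]
}

term_iid <- function(label, data) {
  cols <- strsplit(label, ":", fixed = TRUE)[[1L]]
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("random term column(s) not in data: ", paste(miss, collapse = ", "))
  f <- if (length(cols) == 1L) data[[cols]] else
    interaction(data[cols], drop = TRUE, sep = ":", lex.order = TRUE)
  Z <- ind_matrix(f)
  list(name = label, type = "iid", Z = Z, q = ncol(Z),
       u_names = colnames(Z), comp_groups = rep(1L, ncol(Z)),
       comp_names = label, map = NULL)
}

term_gbv <- function(fac_name, data, kinship, kname = NULL) {
  f <- droplevels(as.factor(data[[fac_name]]))
  K <- sub_kinship(get_kinship(kinship, kname), levels(f))
  fk <- psd_factor(K)
  Z <- ind_matrix(f) %*% fk$L
  nm <- paste0("gbv(", fac_name, ")")
  list(name = nm, type = "gbv", Z = methods::as(Z, "CsparseMatrix"), q = ncol(fk$L),
       u_names = levels(f), comp_groups = rep(1L, ncol(fk$L)),
       comp_names = nm, map = fk$L, K = K, factor_col = fac_name)
}

term_gbv_by <- function(fac_name, by_name, data, kinship, kname = NULL) {
  f <- droplevels(as.factor(data[[fac_name]]))
  by <- droplevels(as.factor(data[[by_name]]))
  Kfull <- get_kinship(kinship, kname)
  blocks <- vector("list", nlevels(by))
  maps <- vector("list", nlevels(by))
  u_names <- character(0)
  n <- nrow(data)
  for (j in seq_len(nlevels(by))) {
    lev <- levels(by)[j]
    rows <- which(by == lev)
    fj <- droplevels(f[rows])
    Kj <- sub_kinship(Kfull, levels(fj))
    fk <- psd_factor(Kj)
    Zj <- Matrix::sparseMatrix(i = rows, j = as.integer(fj), x = 1,
                               dims = c(n, nlevels(fj))) %*% fk$L
    blocks[[j]] <- methods::as(Zj, "CsparseMatrix")
    maps[[j]] <- fk$L
    u_names <- c(u_names, paste0(levels(fj), ":", lev))
  }
  Z <- do.call(cbind, blocks)
  nm <- paste0("gbv(", fac_name, "):", by_name)
  list(name = nm, type = "gbv_by", Z = Z, q = ncol(Z),
       u_names = u_names, comp_groups = rep(1L, ncol(Z)),
       comp_names = nm, map = maps, by_levels = levels(by),
       factor_col = fac_name, by_col = by_name)
}

term_at <- function(fac_label, by_name, data) {
  cols <- strsplit(fac_label, ":", fixed = TRUE)[[1L]]
  f <- if (length(cols) == 1L) data[[cols]] else
    interaction(data[cols], drop = TRUE, sep = ":", lex.order = TRUE)
  f <- droplevels(as.factor(f))
  by <- droplevels(as.factor(data[[by_name]]))
  fb <- interaction(f, by, drop = TRUE, sep = ":", lex.order = FALSE)
  # order columns by `by` level so each variance component is contiguous
  lev_by_col <- vapply(strsplit(levels(fb), ":", fixed = TRUE),
                       function(s) s[length(s)], character(1))
  ord <- order(match(lev_by_col, levels(by)))
  Z <- ind_matrix(fb)[, ord, drop = FALSE]
  groups <- match(lev_by_col[ord], levels(by))
  nm <- paste0(fac_label, "@", levels(by))
  list(name = paste0("at(", fac_label, ", ", by_name, ")"), type = "at",
       Z = Z, q = ncol(Z), u_names = colnames(Z), comp_groups = groups,
       comp_names = nm, map = NULL)
}

parse_random_term <- function(label, data, kinship) {
  expr <- str2lang(label)
  if (is.call(expr) && as.character(expr[[1L]]) %in% c("gbv", "gbv_by", "at")) {
    fun <- as.character(expr[[1L]])
    args <- as.list(expr)[-1L]
    kname <- if (!is.null(args$K)) as.character(args$K) else NULL
    args$K <- NULL
    if (fun == "gbv")
      return(term_gbv(deparse(args[[1L]]), data, kinship, kname))
    if (fun == "gbv_by")
      return(term_gbv_by(deparse(args[[1L]]), deparse(args[[2L]]), data,
                         kinship, kname))
    return(term_at(deparse(args[[1L]]), deparse(args[[2L]]), data))
  }
  term_iid(label, data)
}

#' Build mixed-model design matrices
#'
#' Constructs the fixed-effect matrix `X` (aliased columns dropped in
#' column order) and the random-effect incidence matrices of the term
#' grammar described in [reml_fit()].
#'
#' @inheritParams reml_fit
#' @return a list with the response `y`, `X`, dropped column names,
#'   per-term design objects, residual group factor and known weights.
#' @export
build_design <- function(fixed, random = NULL, data, kinship = NULL,
                         residual = ~1, weights = NULL) {
  data <- as.data.frame(data)
  mf_vars <- all.vars(fixed)
  if (!all(mf_vars %in% names(data)))
    stop("fixed-formula column(s) not in data: ",
         paste(setdiff(mf_vars, names(data)), collapse = ", "))
  y <- eval(fixed[[2L]], data)
  if (anyNA(y)) stop("NA in response")
  for (v in all.vars(fixed[[3L]]))
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  X <- stats::model.matrix(stats::as.formula(
    paste("~", deparse(fixed[[3L]], width.cutoff = 500L))), data)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    # greedy left-to-right: keep the earliest full-rank column subset
    keep <- qrX$pivot[seq_len(qrX$rank)]
    keep <- sort(keep)
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("fixed-effect design has rank 0")
  terms_list <- list()
  if (!is.null(random)) {
    tl <- attr(stats::terms(random, keep.order = TRUE), "term.labels")
    terms_list <- lapply(tl, parse_random_term, data = data, kinship = kinship)
    nm <- vapply(terms_list, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("duplicated random terms")
    names(terms_list) <- nm
  }
  rgrp <- NULL
  rv <- if (is.null(residual)) character(0) else all.vars(residual)
  if (length(rv)) {
    if (!all(rv %in% names(data)))
      stop("residual grouping column(s) not in data")
    rgrp <- droplevels(interaction(data[rv], drop = TRUE, sep = ":",
                                   lex.order = TRUE))
  }
  if (!is.null(weights)) {
    if (length(weights) != length(y)) stop("weights must match rows")
    if (any(weights <= 0)) stop("weights (residual variances) must be > 0")
  }
  list(y = as.numeric(y), X = X, dropped = dropped, terms = terms_list,
       rgrp = rgrp, weights = weights, n = length(y))
}
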