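#' Joint covariance of true breeding values and their BLUPs
#'
#' Assembles the \eqn{2N \times 2N} covariance
#' \deqn{\Omega = \begin{bmatrix} D & M \\ M & M \end{bmatrix}}
#' of the joint multivariate-normal distribution of \eqn{(g, \hat g)},
#' where \eqn{D = K \sigma^2_g} is the unconditional variance of the true
#' GBVs, \eqn{C = var(\hat g - g)} is the prediction error variance from
#' the inverse mixed-model-equation coefficient matrix, and
#' \eqn{M = var(\hat g) = D - C}.  `M` is symmetrized as
#' \eqn{(M + M')/2} before assembly.
#'
#' @param K kinship matrix of the N candidate entries.
#' @param sigma2_g genomic variance (> 0).
#' @param C prediction error variance matrix conformable with `K` (use
#'   [pev()] on a fit).
#' @return list of class `"omega"` with `D`, `C`, `M`, `Omega`, `N` and
#'   entry labels.
#' @export
build_omega <- function(K, sigma2_g, C) {
  K <- as.matrix(K); C <- as.matrix(C)
  if (!all(dim(K) == dim(C))) stop("K and C dimensions differ")
  if (sigma2_g <= 0) stop("sigma2_g must be > 0")
  if (!is.null(rownames(K)) && !is.null(rownames(C)) &&
      !identical(rownames(K), rownames(C)))
    stop("entry labels of K and C disagree")
  D <- K * sigma2_g
  M <- D - C
  M <- (M + t(M)) / 2
  Omega <- rbind(cbind(D, M), cbind(M, M))
  structure(list(D = D, C = C, M = M, Omega = Omega, N = nrow(K),
                 entries = rownames(K), Gamma = NULL, method = NULL,
                 clipped_eigenvalues = 0L), class = "omega")
}

#' Factor the joint covariance: Omega = Gamma Gamma'
#'
#' Attempts a Cholesky factorization; when \eqn{\Omega} is not positive
#' definite (it is singular by construction whenever `C = 0`), falls back
#' to an eigendecomposition with eigenvalues in
#' \eqn{[-10^{-8}\lambda_{max}, 0]} clipped to zero and
#' \eqn{\Gamma = U \sqrt{\Lambda^+}}.  An eigenvalue more negative than the
#' tolerance indicates an invalid prediction-error-variance matrix and is
#' an error.
#'
#' @param omega an `"omega"` object from [build_omega()], or a symmetric
#'   matrix.
#' @param tol relative eigenvalue tolerance.
#' @return the `"omega"` object with `Gamma`, `method` (`"cholesky"` or
#'   `"svd"`) and `clipped_eigenvalues` filled in.
#' @export
factor_omega <- function(omega, tol = 1e-8) {
  if (is.matrix(omega)) {
    O <- omega
    omega <- structure(list(Omega = O, N = nrow(O) / 2), class = "omega")
  }
  O <- omega$Omega
  if (max(abs(O - t(O))) > 1e-8 * max(1, max(abs(O))))
    stop("Omega must be symmetric")
  G <- tryCatch(t(chol(O)), error = function(e) NULL)
  if (!is.null(G)) {
    omega$Gamma <- G
    omega$method <- "cholesky"
    omega$clipped_eigenvalues <- 0L
    return(omega)
  }
  eo <- eigen((O + t(O)) / 2, symmetric = TRUE)
  lmax <- max(eo$values, 0)
  if (any(eo$values < -tol * max(lmax, 1)))
    stop("Omega has an eigenvalue below -", format(tol),
         " * scale: the C matrix is not a valid PEV matrix")
  clipped <- sum(eo$values < 0 | (eo$values >= 0 & eo$values < tol * lmax * 0))
  lam <- pmax(eo$values, 0)
  omega$Gamma <- eo$vectors %*% diag(sqrt(lam), length(lam))
  omega$method <- "svd"
  omega$clipped_eigenvalues <- sum(eo$values < 0)
  omega
}
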