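#' Long-term fraction of genomic variance: rho
#'
#' \eqn{\rho = \sigma^2_g / (\sigma^2_g + \sigma^2_{gy})}, the fraction of
#' the apparent genomic variance attributable to the GBV main effect rather
#' than its year interaction, estimated from long-term multi-year data.
#'
#' @param sigma2_g,sigma2_gy GBV and GBV-by-year variance components
#'   (both >= 0, not both zero).
#' @return rho in \[0, 1\] at full precision.
#' @examples
#' rho_from_components(1.960, 1.406)  # 0.582 to 3 dp
#' @export
rho_from_components <- function(sigma2_g, sigma2_gy) {
  stopifnot(is.numeric(sigma2_g), is.numeric(sigma2_gy))
  if (sigma2_g < 0 || sigma2_gy < 0) stop("variances must be >= 0")
  if (sigma2_g + sigma2_gy <= 0) stop("rho undefined: both variances zero")
  sigma2_g / (sigma2_g + sigma2_gy)
}

#' Delta-method standard error of rho
#'
#' \eqn{SE(\rho) = \sqrt{d' V d}} with gradient
#' \eqn{d = (\sigma^2_{gy}, -\sigma^2_g)' / (\sigma^2_g + \sigma^2_{gy})^2}
#' and `V` the 2 x 2 asymptotic covariance of the two variance estimates
#' (from the inverse average-information matrix).
#'
#' @inheritParams rho_from_components
#' @param V 2 x 2 covariance matrix of `(sigma2_g, sigma2_gy)`.
#' @return standard error of rho.
#' @export
se_rho_delta <- function(sigma2_g, sigma2_gy, V) {
  V <- as.matrix(V)
  stopifnot(all(dim(V) == c(2, 2)))
  V <- (V + t(V)) / 2
  if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values <
          -1e-8 * max(1, max(abs(V)))))
    stop("covariance matrix of the variance estimates is not PSD")
  s <- sigma2_g + sigma2_gy
  if (s <= 0) stop("rho undefined: both variances zero")
  d <- c(sigma2_gy, -sigma2_g) / s^2
  sqrt(max(0, drop(t(d) %*% V %*% d)))
}

#' Asymptotic correlation between two variance component estimates
#'
#' \eqn{V_{ab} / \sqrt{V_{aa} V_{bb}}} from the inverse average-information
#' matrix of a fit.  When either estimate has zero asymptotic variance (for
#' example a boundary estimate) the correlation is reported as 0 with
#' attribute `"flag" = "zero-variance"`.
#'
#' @param fit a `"remlmm"` object, or a covariance matrix with named rows.
#' @param term_a,term_b component names.
#' @return correlation in \[-1, 1\] (possibly flagged).
#' @export
asymptotic_correlation <- function(fit, term_a, term_b) {
  V <- if (inherits(fit, "remlmm")) fit$ai_inverse else as.matrix(fit)
  if (is.null(V)) stop("no average-information covariance available")
  present <- if (is.numeric(c(term_a, term_b)))
    all(c(term_a, term_b) <= nrow(V)) else
      all(c(term_a, term_b) %in% rownames(V))
  if (!present) {
    out <- 0
    attr(out, "flag") <- "zero-variance"
    return(out)
  }
  vaa <- V[term_a, term_a]; vbb <- V[term_b, term_b]
  if (vaa <= 0 || vbb <= 0) {
    out <- 0
    attr(out, "flag") <- "zero-variance"
    return(out)
  }
  V[term_a, term_b] / sqrt(vaa * vbb)
}

#' Split an apparent genomic variance using rho
#'
#' The single-year fit confounds GBV and GBV-by-year effects in one
#' apparent variance \eqn{\sigma^2_{\tilde g} = \sigma^2_g + \sigma^2_{gy}}.
#' Multiplying by a long-term \eqn{\rho} and \eqn{1 - \rho} recovers the
#' two components; the decomposition is exact by construction.
#'
#' @param sigma2_g_tilde apparent genomic variance of the current year.
#' @param rho long-term ratio in (0, 1\].
#' @return list with `sigma2_g_tilde`, `rho`, `sigma2_g_adj`,
#'   `sigma2_gy_adj`, of class `"rho_adjustment"`.
#' @examples
#' rho_adjust(3.069, rho_from_components(1.960, 1.406))
#' @export
rho_adjust <- function(sigma2_g_tilde, rho) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  if (sigma2_g_tilde < 0) stop("apparent variance must be >= 0")
  g <- rho * sigma2_g_tilde
  structure(list(sigma2_g_tilde = sigma2_g_tilde, rho = rho,
                 sigma2_g_adj = g, sigma2_gy_adj = sigma2_g_tilde - g),
            class = "rho_adjustment")
}

#' @export
print.rho_adjustment <- function(x, ...) {
  cat(sprintf(
    "apparent genomic variance %.4f split by rho = %.4f:\n  sigma2_g  %.4f\n  sigma2_gy %.4f\n",
    x$sigma2_g_tilde, x$rho, x$sigma2_g_adj, x$sigma2_gy_adj))
  invisible(x)
}
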