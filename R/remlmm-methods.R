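#' Variance component table of a fit
#'
#' @param fit a `"remlmm"` object.
#' @return data frame with columns `component`, `estimate`, `se`, `fixed`
#'   (held constant during estimation) and `boundary` (estimate pinned at
#'   the zero bound; its SE is not reported).
#' @export
varcomp <- function(fit) {
  stopifnot(inherits(fit, "remlmm"))
  fit$components
}

#' Prediction error variance matrix of a genomic term
#'
#' Returns \eqn{C = var(\hat u - u)} for a `gbv()` term (the genetic block
#' of the inverse mixed-model-equation coefficient matrix, mapped back
#' through the kinship factor), or the per-group list of blocks for a
#' `gbv_by()` term.
#'
#' @param fit a `"remlmm"` object.
#' @param term term name as in `names(ranef(fit))`; defaults to the first
#'   genomic term.
#' @return labelled symmetric matrix (or list of them for `gbv_by`).
#' @export
pev <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "remlmm"))
  if (!length(fit$pev_blocks)) stop("fit has no genomic term")
  if (is.null(term)) term <- names(fit$pev_blocks)[1L]
  pb <- fit$pev_blocks[[term]]
  if (is.null(pb)) stop("no prediction-error-variance block for term '",
                        term, "'")
  if (pb$type == "gbv") {
    C <- pb$map %*% pb$Minv %*% t(pb$map)
    C <- (C + t(C)) / 2
    dimnames(C) <- list(pb$u_names, pb$u_names)
    return(C)
  }
  lapply(pb$blocks, function(b) {
    C <- b$map %*% b$Minv %*% t(b$map)
    (C + t(C)) / 2
  })
}

#' Random-effect predictions (BLUPs)
#'
#' @param object a `"remlmm"` object.
#' @param ... unused.
#' @return named list of BLUP vectors, one per random term.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.remlmm <- function(object, ...) object$blups

#' @export
coef.remlmm <- function(object, ...) object$beta

#' @export
vcov.remlmm <- function(object, ...) object$fixed_cov

#' @export
logLik.remlmm <- function(object, ...) {
  structure(object$logREML, df = sum(!object$components$fixed) +
              object$p_x, class = "logLik")
}

#' @export
fitted.remlmm <- function(object, ...) object$fitted

#' @export
residuals.remlmm <- function(object, ...) object$residuals

#' @export
print.remlmm <- function(x, ...) {
  cat("Linear mixed model fit by AI-REML (selresp)\n")
  cat("  observations:", x$n, "  fixed-effect columns:", x$p_x)
  if (length(x$dropped)) cat("  (", length(x$dropped), "aliased dropped )")
  cat("\n  logREML:", format(x$logREML, digits = 7),
      "  iterations:", x$iterations, "\n\nVariance components:\n")
  tab <- x$components
  tab$estimate <- signif(tab$estimate, 5)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.remlmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.remlmm")
}

#' @export
print.summary.remlmm <- function(x, ...) {
  print(x$fit)
  b <- x$fit$beta
  se <- sqrt(diag(x$fit$fixed_cov))
  cat("\nFixed effects (first 10):\n")
  print(utils::head(data.frame(estimate = signif(b, 5),
                               se = signif(se, 3)), 10))
  invisible(x)
}
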