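#' Fit a linear mixed model by average-information REML
#'
#' Henderson mixed-model-equation based REML for the trial models used in
#' genomic prediction: arbitrary crossed/nested iid random factors,
#' kinship-structured genomic terms, genomic-by-group terms with
#' block-diagonal per-group kinship, group-specific variances, and a
#' residual that is homogeneous, heterogeneous by group, or fixed at known
#' diagonal weights.  Variance components are estimated by the
#' average-information algorithm with step halving and an EM fallback, under
#' the REML non-negativity constraint (estimates pinned near zero are
#' flagged as boundary).  Any subset of components can be held fixed; with
#' all components fixed the call reduces to a single solve of the mixed
#' model equations at the plugged-in values.
#'
#' Random terms are given as a one-sided formula combining
#' \describe{
#'   \item{`fac` or `a:b`}{iid effect, one variance.}
#'   \item{`gbv(fac)`}{genomic effect with covariance `K * sigma2`; `K` is
#'     taken from `kinship` (use `gbv(fac, K = "name")` with a named list).}
#'   \item{`gbv_by(fac, by)`}{genomic-by-group interaction: block diagonal
#'     over the levels of `by`, each block the kinship of the `fac` levels
#'     observed in that group, sharing one variance.}
#'   \item{`at(fac, by)`}{iid effect of `fac` nested in `by` with a
#'     separate variance per level of `by`.}
#' }
#' Kinship terms are handled through a factor `L` with `L L' = K` (Cholesky
#' for positive-definite `K`, otherwise an eigendecomposition with small
#' eigenvalues clipped at zero), which avoids `K^{-1}` and gives identical
#' BLUPs for singular `K`.
#'
#' @param fixed two-sided formula for the response and fixed effects,
#'   e.g. `yield ~ entry`.  Aliased fixed-effect columns are dropped
#'   deterministically (earliest full-rank subset of columns is kept) and
#'   reported in the fit.
#' @param random one-sided formula of random terms (see Details), or `NULL`.
#' @param data data frame holding all referenced columns.
#' @param kinship a kinship matrix, or a named list of them, covering every
#'   level of the factors used in `gbv()`/`gbv_by()` terms (levels missing
#'   from the matrix are an error).
#' @param residual one-sided formula of grouping factors for heterogeneous
#'   residual variances (e.g. `~location`); `~1` for homogeneous.
#' @param weights optional vector of known residual variances (one per
#'   observation).  With `fix_residual = TRUE` the residual is fully fixed
#'   at these values (Smith-weight style); otherwise they act as known
#'   multipliers of the estimated group variances.
#' @param fix_residual logical; fix the residual variance(s) at 1 (times
#'   `weights`).
#' @param fix named numeric vector of variance components to hold fixed at
#'   the given values (names as printed by [varcomp()]).
#' @param init optional named numeric vector of starting values.
#' @param max_iter,tol_loglik,tol_par convergence control: iteration cap
#'   (models with near-unidentifiable variance ridges can need hundreds of
#'   small steps), threshold on successive REML log-likelihood changes, and
#'   on the largest relative parameter change of the last accepted step
#'   (components at the zero bound excluded).  The scaled score is recorded
#'   in the iteration trace but does not gate stopping: at a zero boundary
#'   it tends to a non-zero constant.
#' @param keep_design keep the assembled design and Cholesky factor in the
#'   fit, enabling [refit_response()].
#' @param verbose print the iteration trace.
#' @return an object of class `"remlmm"`; see [varcomp()], [pev()],
#'   [ranef.remlmm()], and the usual `coef`, `vcov`, `logLik`, `summary`
#'   methods.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = gl(10, 4), y = rnorm(40) + rep(rnorm(10), each = 4))
#' fit <- reml_fit(y ~ 1, ~g, d)
#' varcomp(fit)
#' @export
reml_fit <- function(fixed, random = NULL, data, kinship = NULL,
                     residual = ~1, weights = NULL, fix_residual = FALSE,
                     fix = NULL, init = NULL, max_iter = 400,
                     tol_loglik = 1e-6, tol_par = 1e-3,
                     keep_design = FALSE, verbose = FALSE) {
  cl <- match.call()
  des <- build_design(fixed, random, data, kinship, residual, weights)
  n <- des$n
  p_x <- ncol(des$X)

  # pre-scale by known residual weights so R = diag(sigma2_group)
  w <- if (is.null(des$weights)) rep(1, n) else des$weights
  sw <- sqrt(w)
  ys <- des$y / sw
  Wsp <- methods::as(cbind(
    methods::as(Matrix::Matrix(des$X, sparse = TRUE), "generalMatrix"),
    do.call(cbind, c(lapply(des$terms, `[[`, "Z"), list(deparse.level = 0)))
  ), "CsparseMatrix")
  Wsp <- Wsp / sw
  p_tot <- ncol(Wsp)

  # residual groups
  rgrp <- if (is.null(des$rgrp)) factor(rep("units", n)) else des$rgrp
  grp_rows <- split(seq_len(n), rgrp)
  grp_names <- if (is.null(des$rgrp)) "units" else
    paste0("units@", levels(rgrp))
  n_grp <- length(grp_rows)

  # cached per-group cross products (dense when affordable: the iteration
  # cost is then dominated by the Cholesky, not by sparse conversions)
  S <- lapply(grp_rows, function(r) Matrix::crossprod(Wsp[r, , drop = FALSE]))
  S_trip <- lapply(S, function(s) {
    g <- methods::as(methods::as(s, "generalMatrix"), "TsparseMatrix")
    list(i = g@i + 1L, j = g@j + 1L, x = g@x)
  })
  dense_S <- length(S) * p_tot^2 * 8 < 8e8
  Sflat <- if (dense_S)
    vapply(S, function(s) as.numeric(as.matrix(s)), numeric(p_tot^2)) else NULL
  cy <- lapply(grp_rows, function(r)
    as.numeric(Matrix::crossprod(Wsp[r, , drop = FALSE], ys[r])))
  yy <- vapply(grp_rows, function(r) sum(ys[r]^2), 0)
  n_l <- lengths(grp_rows)
  logdet_w <- sum(log(w))

  # variance components bookkeeping
  comps <- list()
  off <- p_x
  for (tm in des$terms) {
    for (g in seq_along(tm$comp_names)) {
      cols <- off + which(tm$comp_groups == g)
      comps[[length(comps) + 1L]] <- list(name = tm$comp_names[g], kind = "u",
                                          cols = cols, grp = NA_integer_)
    }
    off <- off + tm$q
  }
  for (g in seq_len(n_grp))
    comps[[length(comps) + 1L]] <- list(name = grp_names[g], kind = "e",
                                        cols = integer(0), grp = g)
  cnames <- vapply(comps, `[[`, "", "name")
  n_c <- length(comps)
  if (n_c == 0L) stop("no variance components: add a random term or free residual")

  vy <- stats::var(ys)
  floor_v <- 1e-10 * max(vy, .Machine$double.eps)
  theta <- rep(vy / (n_c + 1), n_c)
  fixed_c <- rep(FALSE, n_c)
  for (k in seq_len(n_c)) if (comps[[k]]$kind == "e" && fix_residual) {
    theta[k] <- 1; fixed_c[k] <- TRUE
  }
  if (!is.null(init)) {
    m <- match(names(init), cnames)
    if (anyNA(m)) stop("unknown component in init: ",
                       paste(names(init)[is.na(m)], collapse = ", "))
    theta[m] <- pmax(init, floor_v)
  }
  if (!is.null(fix)) {
    m <- match(names(fix), cnames)
    if (anyNA(m)) stop("unknown component in fix: ",
                       paste(names(fix)[is.na(m)], collapse = ", "))
    if (any(fix < 0)) stop("fixed components must be >= 0")
    theta[m] <- pmax(fix, floor_v)
    fixed_c[m] <- TRUE
  }
  free <- which(!fixed_c)

  prior_cols <- lapply(comps, `[[`, "cols")
  grp_of_comp <- vapply(comps, `[[`, 1L, "grp")
  q_k <- lengths(prior_cols)
  grp_idx_row <- as.integer(rgrp)           # group of each observation

  resid_comp_of_grp <- vapply(seq_len(n_grp), function(g)
    which(grp_of_comp == g)[1L], 1L)

  assemble_M <- function(th) {
    s2e <- th[resid_comp_of_grp]
    M <- if (dense_S) {
      Mv <- Sflat %*% (1 / s2e)
      dim(Mv) <- c(p_tot, p_tot)
      Mv
    } else {
      Ssum <- S[[1L]] / s2e[1L]
      if (n_grp > 1L) for (g in 2L:n_grp) Ssum <- Ssum + S[[g]] / s2e[g]
      as.matrix(Ssum)
    }
    for (k in seq_len(n_c)) if (comps[[k]]$kind == "u") {
      cols <- prior_cols[[k]]
      M[cbind(cols, cols)] <- M[cbind(cols, cols)] + 1 / th[k]
    }
    rhs <- Reduce(`+`, Map(`/`, cy, as.list(s2e)))
    list(M = M, rhs = rhs, s2e = s2e)
  }

  eval_ll <- function(th, need_inv = FALSE) {
    am <- assemble_M(th)
    U <- tryCatch(chol(am$M), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    b <- backsolve(U, backsolve(U, am$rhs, transpose = TRUE))
    yPy <- sum(yy / am$s2e) - sum(b * am$rhs)
    logdetM <- 2 * sum(log(diag(U)))
    logdetG <- sum(ifelse(vapply(comps, `[[`, "", "kind") == "u",
                          q_k * log(th), 0))
    logdetR <- logdet_w + sum(n_l * log(am$s2e))
    ll <- -0.5 * ((n - p_x) * log(2 * pi) + logdetR + logdetG + logdetM + yPy)
    out <- list(ll = ll, U = U, b = b, yPy = yPy, s2e = am$s2e)
    if (need_inv) out$Minv <- chol2inv(U)
    out
  }

  # score and AI matrix at a full evaluation
  score_ai <- function(th, ev) {
    es <- ys - as.numeric(Wsp %*% ev$b)
    ee <- vapply(grp_rows, function(r) sum(es[r]^2), 0)
    diagMinv <- diag(ev$Minv)
    score <- numeric(n_c)
    trMS <- numeric(n_grp)
    for (g in seq_len(n_grp)) {
      tp <- S_trip[[g]]
      trMS[g] <- sum(ev$Minv[cbind(tp$i, tp$j)] * tp$x)
    }
    for (k in seq_len(n_c)) {
      if (comps[[k]]$kind == "u") {
        cols <- prior_cols[[k]]
        trC <- sum(diagMinv[cols])
        uu <- sum(ev$b[cols]^2)
        score[k] <- -0.5 * ((q_k[k] - trC / th[k]) / th[k] - uu / th[k]^2)
      } else {
        g <- comps[[k]]$grp
        trP <- n_l[g] / th[k] - trMS[g] / th[k]^2
        score[k] <- -0.5 * (trP - ee[g] / th[k]^2)
      }
    }
    # AI over free components
    if (length(free)) {
      Fm <- matrix(0, n, length(free))
      for (jj in seq_along(free)) {
        k <- free[jj]
        if (comps[[k]]$kind == "u") {
          cols <- prior_cols[[k]]
          Fm[, jj] <- as.numeric(Wsp[, cols, drop = FALSE] %*%
                                   ev$b[cols]) / th[k]
        } else {
          r <- grp_rows[[comps[[k]]$grp]]
          Fm[r, jj] <- es[r] / th[k]
        }
      }
      G1 <- Fm / ev$s2e[grp_idx_row]
      T1 <- as.matrix(Matrix::crossprod(Wsp, G1))
      H <- backsolve(ev$U, backsolve(ev$U, T1, transpose = TRUE))
      PF <- G1 - (as.matrix(Wsp %*% H)) / ev$s2e[grp_idx_row]
      AI <- 0.5 * crossprod(Fm, PF)
      AI <- (AI + t(AI)) / 2
    } else AI <- matrix(0, 0, 0)
    em <- numeric(n_c)   # EM update targets
    for (k in seq_len(n_c)) {
      if (comps[[k]]$kind == "u") {
        cols <- prior_cols[[k]]
        em[k] <- (sum(ev$b[cols]^2) + sum(diagMinv[cols])) / q_k[k]
      } else {
        g <- comps[[k]]$grp
        em[k] <- (ee[g] + trMS[g]) / n_l[g]
      }
    }
    list(score = score, AI = AI, em = em, es = es, ee = ee)
  }

  trace <- NULL
  boundary_tol <- 1e-6 * max(vy, .Machine$double.eps)
  if (length(free) == 0L) {
    ev <- eval_ll(theta, need_inv = TRUE)
    if (is.null(ev)) stop("singular mixed-model coefficient matrix")
    sa <- score_ai(theta, ev)
    iter <- 0L; converged <- TRUE
  } else {
    ev <- eval_ll(theta, need_inv = TRUE)
    if (is.null(ev)) stop("singular mixed-model coefficient matrix at start")
    converged <- FALSE
    iter <- 0L
    abs_dll <- Inf
    relch <- Inf     # relative parameter change of the last accepted step
    boost <- 1       # step amplification along slow ridges
    repeat {
      iter <- iter + 1L
      sa <- score_ai(theta, ev)
      # active set: components pinned at the zero bound (tiny value, score
      # pointing further down) leave the Newton system; the scaled score
      # does not vanish at a zero boundary, so the stopping rule is the
      # log-likelihood change plus the relative parameter change
      bound_now <- free[theta[free] < boundary_tol & sa$score[free] < 0]
      if (length(bound_now)) theta[bound_now] <- floor_v
      free_act <- setdiff(free, bound_now)
      grad_norm <- if (length(free_act))
        max(abs(sa$score[free_act] * theta[free_act])) else 0
      if (verbose)
        cat(sprintf("iter %3d  logREML %.6f  grad %.2e  relch %.2e  bounded %d\n",
                    iter - 1L, ev$ll, grad_norm, relch, length(bound_now)))
      trace <- rbind(trace, c(iter = iter - 1L, logREML = ev$ll,
                              grad = grad_norm, relch = relch))
      if (abs_dll < tol_loglik &&
          (relch < tol_par || iter > max_iter / 2)) {
        converged <- TRUE
        break
      }
      if (iter > max_iter) {
        converged <- abs_dll < 10 * tol_loglik
        break
      }
      # AI step over the active components (EM for the first iteration and
      # for flat directions), tried at an amplified scale first, then the
      # plain step, then halved; EM fallback never decreases the likelihood
      if (iter == 1L || length(free_act) == 0L) {
        step <- pmax(sa$em[free_act], floor_v) - theta[free_act]
      } else {
        ia <- match(free_act, free)
        A <- sa$AI[ia, ia, drop = FALSE]
        d0 <- diag(A)
        good <- d0 > 1e-10 * max(d0, 1) & is.finite(d0)
        step <- sa$em[free_act] - theta[free_act]
        if (any(good)) {
          sg <- tryCatch(solve(A[good, good, drop = FALSE],
                               sa$score[free_act][good]),
                         error = function(e) NULL)
          if (!is.null(sg)) step[good] <- sg
        }
      }
      ok <- FALSE
      scales <- unique(c(boost, 2^-(0:25)))
      for (s in scales) {
        cand_h <- theta
        cand_h[free_act] <- pmax(theta[free_act] + s * step, floor_v)
        ev_h <- eval_ll(cand_h)
        if (!is.null(ev_h) && ev_h$ll >= ev$ll - 1e-8) { ok <- TRUE; break }
      }
      # grow the trust region only while crawling (small accepted gains at
      # full amplification); anything else resets it -- the crawl along a
      # near-flat ridge is otherwise geometric with ratio near 1
      boost <- if (ok && s == scales[1L] && ev_h$ll - ev$ll < 0.5)
        min(boost * 2, 64) else 1
      if (!ok) {
        cand_h <- theta
        cand_h[free_act] <- pmax(sa$em[free_act], floor_v)
        ev_h <- eval_ll(cand_h)
        if (is.null(ev_h) || ev_h$ll < ev$ll - 1e-8) {
          converged <- abs_dll < tol_loglik
          break
        }
      }
      abs_dll <- abs(ev_h$ll - ev$ll)
      relch <- if (length(free_act))
        max(abs(cand_h[free_act] - theta[free_act]) /
              pmax(theta[free_act], 1e-4 * vy)) else 0
      theta <- cand_h
      ev <- ev_h
      ev$Minv <- chol2inv(ev$U)
    }
    if (!converged) {
      msg <- paste0("REML did not converge in ", max_iter, " iterations")
      attr(msg, "trace") <- trace
      stop(msg)
    }
    sa <- score_ai(theta, ev)
  }

  # --- post processing -------------------------------------------------
  at_floor <- !fixed_c & theta < boundary_tol
  se <- rep(NA_real_, n_c)
  ai_inv <- NULL
  est_idx <- free[!at_floor[free]]
  if (length(est_idx)) {
    AI_est <- sa$AI[match(est_idx, free), match(est_idx, free), drop = FALSE]
    ai_inv <- tryCatch(solve(AI_est), error = function(e) NULL)
    if (!is.null(ai_inv)) {
      dimnames(ai_inv) <- list(cnames[est_idx], cnames[est_idx])
      se[est_idx] <- sqrt(pmax(diag(ai_inv), 0))
    }
  }
  theta_rep <- theta
  theta_rep[at_floor] <- 0
  components <- data.frame(component = cnames, estimate = theta_rep,
                           se = se, fixed = fixed_c, boundary = at_floor,
                           stringsAsFactors = FALSE)

  beta <- ev$b[seq_len(p_x)]
  names(beta) <- colnames(des$X)
  fixed_cov <- ev$Minv[seq_len(p_x), seq_len(p_x), drop = FALSE]
  dimnames(fixed_cov) <- list(names(beta), names(beta))

  blups <- list()
  pev_blocks <- list()
  off <- p_x
  for (tm in des$terms) {
    a <- ev$b[off + seq_len(tm$q)]
    if (tm$type == "gbv") {
      u <- drop(tm$map %*% a)
      names(u) <- tm$u_names
      idx <- off + seq_len(tm$q)
      pev_blocks[[tm$name]] <- list(type = "gbv", map = tm$map,
                                    Minv = ev$Minv[idx, idx, drop = FALSE],
                                    u_names = tm$u_names)
    } else if (tm$type == "gbv_by") {
      u <- numeric(0)
      pos <- 0L
      blocks <- list()
      for (j in seq_along(tm$map)) {
        rj <- ncol(tm$map[[j]])
        aj <- a[pos + seq_len(rj)]
        idx <- off + pos + seq_len(rj)
        blocks[[j]] <- list(map = tm$map[[j]],
                            Minv = ev$Minv[idx, idx, drop = FALSE])
        u <- c(u, drop(tm$map[[j]] %*% aj))
        pos <- pos + rj
      }
      names(u) <- tm$u_names
      pev_blocks[[tm$name]] <- list(type = "gbv_by", blocks = blocks,
                                    u_names = tm$u_names)
    } else {
      u <- a
      names(u) <- tm$u_names
    }
    blups[[tm$name]] <- u
    off <- off + tm$q
  }

  resid_s <- (ys - as.numeric(Wsp %*% ev$b)) * sw
  fit <- structure(list(
    call = cl, converged = converged, iterations = iter, logREML = ev$ll,
    components = components, ai_inverse = ai_inv, beta = beta,
    fixed_cov = fixed_cov, dropped = des$dropped, blups = blups,
    pev_blocks = pev_blocks, fitted = des$y - resid_s, residuals = resid_s,
    n = n, p_x = p_x, trace = trace,
    term_types = vapply(des$terms, `[[`, "", "type")), class = "remlmm")
  if (keep_design)
    fit$design <- list(Wsp = Wsp, U = ev$U, s2e = ev$s2e, sw = sw,
                       grp_rows = grp_rows, cy_template = NULL,
                       terms = lapply(des$terms, function(tm)
                         tm[c("name", "type", "q", "u_names", "map")]),
                       p_x = p_x, Minv = ev$Minv)
  fit
}

#' Re-solve a fitted model for a new response
#'
#' Solves the mixed model equations of a fit created with
#' `keep_design = TRUE` for a new response vector, keeping design and
#' variance components (and hence the Cholesky factor) unchanged.  Useful
#' for replicated simulation at plugged-in components.
#'
#' @param fit a `"remlmm"` fit with `keep_design = TRUE`.
#' @param y new response vector in the original row order.
#' @return list with `beta` and `blups` (per-term, mapped to effect scale).
#' @export
refit_response <- function(fit, y) {
  d <- fit$design
  if (is.null(d)) stop("fit was created without keep_design = TRUE")
  ys <- y / d$sw
  rhs <- numeric(ncol(d$Wsp))
  for (g in seq_along(d$grp_rows)) {
    r <- d$grp_rows[[g]]
    rhs <- rhs + as.numeric(Matrix::crossprod(d$Wsp[r, , drop = FALSE],
                                              ys[r])) / d$s2e[g]
  }
  b <- backsolve(d$U, backsolve(d$U, rhs, transpose = TRUE))
  beta <- b[seq_len(d$p_x)]
  names(beta) <- names(fit$beta)
  blups <- list()
  off <- d$p_x
  for (tm in d$terms) {
    a <- b[off + seq_len(tm$q)]
    u <- if (tm$type == "gbv") drop(tm$map %*% a)
    else if (tm$type == "gbv_by") {
      pos <- 0L; out <- numeric(0)
      for (j in seq_along(tm$map)) {
        rj <- ncol(tm$map[[j]])
        out <- c(out, drop(tm$map[[j]] %*% a[pos + seq_len(rj)]))
        pos <- pos + rj
      }
      out
    } else a
    names(u) <- tm$u_names
    blups[[tm$name]] <- u
    off <- off + tm$q
  }
  list(beta = beta, blups = blups)
}
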