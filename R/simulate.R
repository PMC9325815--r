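#' Simulate truncation-selection probabilities from the joint distribution
#'
#' Draws `S` replicates of \eqn{w = \Gamma z}, \eqn{z \sim N(0, I_{2N})},
#' splits each draw into true breeding values `g` (first N elements) and
#' GBLUPs `ghat` (last N), and estimates, for every selected-count `n` in
#' `n_grid` and every `m` in `m_list`, the probability that the top-`n`
#' entries ranked on `ghat` contain the `m` truly best entries ranked on
#' `g`.  Per-replicate Pearson correlations of values and of ranks are
#' averaged across replicates (a pooled variant is also reported).
#'
#' Ranking ties are broken by entry index; under the continuous model they
#' occur with probability zero, so the deterministic rule only pins down
#' reproducibility.  "Best" means largest by default (yield-type traits);
#' set `minimize = TRUE` for traits where low is good.
#'
#' @param omega an `"omega"` object; factored with [factor_omega()] on the
#'   fly if needed.
#' @param S number of simulation replicates.
#' @param seed integer seed (recorded in the output).
#' @param percent_grid selected fractions of N, in percent (default 1..100).
#' @param m_list numbers of truly best entries that must be captured.
#' @param k_of_m optional relaxed criterion: success when at least `k_of_m`
#'   of the `m` truly best are inside the selected set (default: all `m`).
#' @param minimize rank smallest values as best.
#' @param chunk_size draws generated per block (memory/speed trade-off).
#' @return object of class `"selection_sim"`: `table` (long data frame
#'   with `n`, `percent_selected`, `m`, `probability`), `corr_value`,
#'   `corr_rank` (means over replicates), pooled variants, `S`, `seed`,
#'   and the factorization `method`.
#' @export
simulate_selection <- function(omega, S = 100000, seed = 1L,
                               percent_grid = 1:100,
                               m_list = c(1, 5, 10, 15, 20),
                               k_of_m = NULL, minimize = FALSE,
                               chunk_size = 2000L) {
  stopifnot(inherits(omega, "omega"), S >= 1)
  if (is.null(omega$Gamma)) omega <- factor_omega(omega)
  N <- omega$N
  if (N < 2) stop("need at least 2 entries")
  m_list <- sort(unique(as.integer(m_list)))
  m_list <- m_list[m_list >= 1 & m_list <= N]
  if (!length(m_list)) {
    tab <- data.frame(n = integer(0), percent_selected = numeric(0),
                      m = integer(0), probability = numeric(0))
    return(structure(list(table = tab, corr_value = NA_real_,
                          corr_rank = NA_real_, S = S, seed = seed,
                          method = omega$method, N = N),
                     class = "selection_sim"))
  }
  n_grid <- sort(unique(pmin(N, pmax(1L, as.integer(
    ceiling(percent_grid / 100 * N))))))
  max_m <- max(m_list)
  if (!is.null(k_of_m) && (k_of_m < 1 || k_of_m > min(m_list)))
    stop("k_of_m must lie in [1, min(m_list)]")
  set.seed(seed)
  Gamma <- omega$Gamma
  r <- ncol(Gamma)
  sgn <- if (minimize) -1 else 1
  # per-m tallies of the smallest n that yields success
  tallies <- matrix(0, N, length(m_list))
  sum_cv <- 0; sum_cr <- 0
  pool <- c(sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0, n = 0)
  seq_N <- seq_len(N)
  mu_r <- (N + 1) / 2                      # rank moments are constants
  ss_r <- sum((seq_N - mu_r)^2)
  jm_idx <- seq_along(m_list)
  done <- 0L
  while (done < S) {
    nb <- min(chunk_size, S - done)
    Wm <- sgn * (Gamma %*% matrix(rnorm(r * nb), r, nb))
    Gm <- Wm[seq_N, , drop = FALSE]
    Hm <- Wm[N + seq_N, , drop = FALSE]
    # Pearson correlations of all draws in the chunk at once
    mg <- colMeans(Gm); mh <- colMeans(Hm)
    vg <- colMeans(Gm^2) - mg^2; vh <- colMeans(Hm^2) - mh^2
    sum_cv <- sum_cv + sum((colMeans(Gm * Hm) - mg * mh) / sqrt(vg * vh))
    pool <- pool + c(sum(Gm), sum(Hm), sum(Gm^2), sum(Hm^2), sum(Gm * Hm),
                     N * nb)
    rank_h <- integer(N); rank_g <- integer(N)
    for (b in seq_len(nb)) {
      ord_g <- order(Gm[, b], decreasing = TRUE)
      ord_h <- order(Hm[, b], decreasing = TRUE)
      rank_h[ord_h] <- seq_N
      rank_g[ord_g] <- seq_N
      sum_cr <- sum_cr + (sum(rank_g * rank_h) - N * mu_r^2) / ss_r
      rr <- rank_h[ord_g[seq_len(max_m)]]
      need <- if (is.null(k_of_m)) cummax(rr)[m_list] else
        vapply(m_list, function(m) sort(rr[seq_len(m)])[min(k_of_m, m)], 0)
      tallies[cbind(need, jm_idx)] <- tallies[cbind(need, jm_idx)] + 1
    }
    done <- done + nb
  }
  cum <- apply(tallies, 2L, cumsum) / S   # P(n_needed <= n) for n = 1..N
  tab <- expand.grid(n = n_grid, m = m_list, KEEP.OUT.ATTRS = FALSE)
  tab$percent_selected <- 100 * tab$n / N
  tab$probability <- cum[cbind(tab$n, match(tab$m, m_list))]
  tab$probability[tab$n < tab$m & is.null(k_of_m)] <- 0
  tab <- tab[, c("n", "percent_selected", "m", "probability")]
  pcor <- (pool["sxy"] - pool["sx"] * pool["sy"] / pool["n"]) /
    sqrt((pool["sxx"] - pool["sx"]^2 / pool["n"]) *
         (pool["syy"] - pool["sy"]^2 / pool["n"]))
  structure(list(table = tab, corr_value = sum_cv / S, corr_rank = sum_cr / S,
                 corr_value_pooled = unname(pcor), S = S, seed = seed,
                 method = omega$method, N = N, m_list = m_list,
                 k_of_m = k_of_m), class = "selection_sim")
}

#' Draw jointly from the distribution of (g, ghat)
#'
#' Materializes `S` draws of \eqn{w = \Gamma z}: a convenience for
#' diagnostics and oracle checks at small `N`.  [simulate_selection()]
#' streams the same draws without materializing them.
#'
#' @inheritParams simulate_selection
#' @return list with matrices `g` and `ghat`, each `S` x N.
#' @export
simulate_joint <- function(omega, S = 1000, seed = 1L) {
  stopifnot(inherits(omega, "omega"), S >= 1)
  if (is.null(omega$Gamma)) omega <- factor_omega(omega)
  set.seed(seed)
  N <- omega$N
  W <- omega$Gamma %*% matrix(rnorm(ncol(omega$Gamma) * S),
                              ncol(omega$Gamma), S)
  list(g = t(W[seq_len(N), , drop = FALSE]),
       ghat = t(W[N + seq_len(N), , drop = FALSE]))
}

#' Long-format probability table of a selection simulation
#'
#' @param sim a `"selection_sim"` object.
#' @return data frame with `percent_selected`, `m`, `probability` (one row
#'   per grid point), ready for plotting or CSV export.
#' @export
probability_report <- function(sim) {
  stopifnot(inherits(sim, "selection_sim"))
  sim$table[, c("percent_selected", "m", "probability")]
}

#' @export
print.selection_sim <- function(x, ...) {
  cat("Selection-response simulation (S =", format(x$S, big.mark = ","),
      "draws, N =", x$N, "entries,", x$method, "factorization)\n")
  cat(sprintf("  mean corr(g, ghat): %.3f   mean rank corr: %.3f\n",
              x$corr_value, x$corr_rank))
  if (nrow(x$table)) {
    show <- x$table[x$table$n %in% stats::quantile(
      unique(x$table$n), c(.1, .25, .5, 1), type = 1), ]
    cat("  probability that the top-n set contains the m truly best:\n")
    print(utils::head(show, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Plot probability curves of a selection simulation
#'
#' One curve per `m`: the probability of capturing the `m` truly best
#' entries against the selected percentage of N.
#'
#' @param x a `"selection_sim"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.selection_sim <- function(x, ...) {
  tab <- x$table
  if (!nrow(tab)) stop("empty probability table")
  cols <- grDevices::hcl.colors(length(x$m_list), "Dark 3")
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 1),
                 xlab = "selected entries (% of N)",
                 ylab = "probability of capturing the m truly best", ...)
  for (j in seq_along(x$m_list)) {
    d <- tab[tab$m == x$m_list[j], ]
    graphics::lines(d$percent_selected, d$probability, col = cols[j], lwd = 2)
  }
  graphics::legend("bottomright", legend = paste("m =", x$m_list),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
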