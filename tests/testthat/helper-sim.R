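# Small fixtures, built in code.

# balanced one-way data with known entry and residual variance
oneway_data <- function(q = 12, r = 4, s2g = 3, s2e = 2, mu = 10, seed = 1) {
  set.seed(seed)
  g <- rnorm(q, 0, sqrt(s2g))
  data.frame(entry = gl(q, r, labels = sprintf("E%02d", seq_len(q))),
             y = mu + rep(g, each = r) + rnorm(q * r, 0, sqrt(s2e)),
             g_true = rep(g, each = r))
}

# small multi-year panel with kinship
tiny_met <- function(N = 40, years = 3, P = 400, seed = 1, ...) {
  cfg <- sim_config(n_entries = N, n_years = years, n_markers = P,
                    n_locations = 2, n_trials_per_location = 1,
                    block_size = 10, seed = seed,
                    residual_variances = c(4, 5), ...)
  sim_met(cfg)
}

# direct dense-matrix BLUP/GLS oracle for y = X b + Z u + e,
# var(u) = G, var(e) = R; returns GLS beta, BLUP u, and C = var(uhat - u)
blup_oracle <- function(y, X, Z, G, R) {
  V <- Z %*% G %*% t(Z) + R
  Vi <- solve(V)
  XVX <- solve(t(X) %*% Vi %*% X)
  beta <- drop(XVX %*% t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% XVX %*% t(X) %*% Vi
  u <- drop(G %*% t(Z) %*% P %*% y)
  C <- G - G %*% t(Z) %*% P %*% Z %*% G
  list(beta = beta, u = u, C = (C + t(C)) / 2)
}
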