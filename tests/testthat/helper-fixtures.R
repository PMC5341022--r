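# Fixtures and independent oracles shared across test files.

# A small hand-built monthly series; gpp is left free so tests can inject
# exact model output or arbitrary observations.
make_series <- function(n = 24, gpp = NULL, evi = NULL, lst = NULL,
                        prc = NULL, rad = NULL, snow = NULL,
                        pft = "GRA", site = "TEST") {
  dates <- seq(as.Date("2005-01-01"), by = "month", length.out = n)
  mon <- as.integer(format(dates, "%m"))
  lst <- lst %||% (12 + 12 * cos(2 * pi * (mon - 7) / 12))
  evi <- evi %||% (0.4 + 0.2 * cos(2 * pi * (mon - 7) / 12))
  gpp <- gpp %||% tggpp::predict_gpp(evi, lst, tggpp::tg_params(m = 8))
  site_series(dates, gpp, evi, lst,
              prc = prc %||% rep(60, n), rad = rad %||% rep(15, n),
              snow_flag = snow %||% rep(FALSE, n),
              site_id = site, pft = pft)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# preset whose LST cycle covers the full temperature response of the truth
# (below x_n and beyond x_o) -- the setting under which the temperature
# parameters are identifiable
recovery_preset <- function(noise_frac = 0.15) {
  pft_preset("GRA", tg_params(0, 25, 50, m = 8),
             lst_mean = 12, lst_amp = 22,
             evi_mean = 0.45, evi_amp = 0.25, noise_frac = noise_frac)
}

# Wrap raw samples as a posterior_chain so diagnostics can be unit-tested
# on chains with known, analytically understood distributions.
fake_chain <- function(samples, burn_in = 0L) {
  samples <- as.matrix(samples)
  structure(list(samples = samples, log_post = rep(0, nrow(samples)),
                 acceptance_rate = 0.3, burn_in = as.integer(burn_in),
                 proposal_scales = rep(1, ncol(samples)), seed = 1L),
            class = "posterior_chain")
}

# Brute-force enumeration oracle for Morris elementary effects: every grid
# point of the p-level unit cube that admits a +delta step in coordinate i
# contributes one EE, by direct finite difference of f. Returns per-
# parameter population mu* and sigma.
enumerate_morris <- function(f, k, p) {
  delta <- p / (2 * (p - 1))
  levels <- (0:(p - 1)) / (p - 1)
  grid <- as.matrix(expand.grid(rep(list(levels), k)))
  lapply(seq_len(k), function(i) {
    ok <- grid[, i] + delta <= 1 + 1e-9
    ee <- apply(grid[ok, , drop = FALSE], 1, function(x) {
      xp <- x; xp[i] <- xp[i] + delta
      (f(xp) - f(x)) / delta
    })
    list(mu_star = mean(abs(ee)),
         sigma = sqrt(mean((ee - mean(ee))^2)),
         n = length(ee))
  })
}

# Independent re-derivation of Johnson weights: orthogonal counterpart via
# SVD (Z = sqrt(n-1) U V'), regression by lm(), loadings by empirical
# correlation -- a different route than the package's eigendecomposition.
rwa_oracle <- function(X, y) {
  Xs <- scale(as.matrix(X)); ys <- as.numeric(scale(y))
  n <- nrow(Xs)
  sv <- svd(Xs)
  Z <- sqrt(n - 1) * sv$u %*% t(sv$v)
  beta <- unname(stats::coef(stats::lm(ys ~ Z - 1)))
  lambda <- stats::cor(Xs, Z)
  as.numeric((lambda^2) %*% beta^2)
}
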