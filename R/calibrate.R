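#' Gaussian log-likelihood of the TG model
#'
#' Log-likelihood of observed GPP under the TG model with i.i.d. Gaussian
#' observation errors. The proportionality scalar `m` is profiled out by
#' origin-constrained least squares ([fit_m()]) at every evaluation, so the
#' likelihood is a function of the three temperature parameters and the log
#' error scale only:
#' `-n/2 * log(2 * pi * sigma^2) - sum((gpp - gpp_hat)^2) / (2 * sigma^2)`
#' over unmasked months. An ordering violation returns `-Inf` (a rejected
#' state), not an error.
#'
#' @param theta numeric `c(x_n, x_o, x_m)` in degC.
#' @param log_sigma log of the Gaussian error SD (gC m^-2 day^-1 scale).
#' @param series a [site_series()] (or pooled data frame) with unmasked
#'   months to fit.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
tg_log_likelihood <- function(theta, log_sigma, series) {
  make_tg_loglik(series)(theta, log_sigma)
}

# Closure factory: precomputes the unmasked observation vectors once so the
# MCMC inner loop pays only for the LST scaling and residuals.
#' @noRd
make_tg_loglik <- function(series) {
  pooled <- pool_series(series)
  keep <- !pooled$masked & is.finite(pooled$gpp) & is.finite(pooled$evi) &
    is.finite(pooled$lst)
  if (!any(keep)) tg_abort("no usable months.", "tggpp_error_no_data")
  g <- pooled$gpp[keep]
  evi_s <- pmax(pooled$evi[keep] - 0.1, 0)
  lst <- pooled$lst[keep]
  n <- length(g)
  function(theta, log_sigma) {
    x_n <- theta[1]; x_o <- theta[2]; x_m <- theta[3]
    if (!(x_n < x_o && x_o < x_m)) return(-Inf)
    ls <- pmax(pmin((lst - x_n) / (x_o - x_n), (x_m - lst) / (x_m - x_o)), 0)
    p <- evi_s * ls
    sp <- sum(p * p)
    m <- if (sp > 0) max(sum(p * g) / sp, 0) else 0
    res <- g - m * p
    s2 <- exp(2 * log_sigma)
    -0.5 * n * log(2 * pi * s2) - sum(res * res) / (2 * s2)
  }
}

#' Log-prior for TG calibration
#'
#' Uniform (flat) priors: 0 up to a constant inside the per-parameter
#' ranges with valid strict ordering, `-Inf` outside or on an ordering
#' violation. The error scale is sampled as `log sigma` with a wide uniform
#' prior on `[log(0.01), log(100)]`.
#'
#' @inheritParams tg_log_likelihood
#' @param ranges a [param_ranges()] for `(x_n, x_o, x_m)`.
#' @param log_sigma_range length-2 numeric bounds for `log_sigma`.
#' @return 0 or `-Inf`.
#' @export
tg_log_prior <- function(theta, log_sigma, ranges = param_ranges(),
                         log_sigma_range = log(c(0.01, 100))) {
  if (any(theta < ranges$lower) || any(theta > ranges$upper)) return(-Inf)
  if (!(theta[1] < theta[2] && theta[2] < theta[3])) return(-Inf)
  if (log_sigma < log_sigma_range[1] || log_sigma > log_sigma_range[2]) {
    return(-Inf)
  }
  0
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Plain Metropolis-Hastings with independent Gaussian random-walk
#' proposals and per-parameter scales. A proposed state is accepted with
#' probability `min(1, exp(delta log-posterior))`. Proposal scales are
#' adapted in batches toward a 20-50% acceptance rate during burn-in only
#' and frozen afterwards, preserving detailed balance for the retained part
#' of the chain.
#'
#' @param log_post `function(x)` returning the (unnormalized) log posterior
#'   density at parameter vector `x`; must be finite at `init`.
#' @param init numeric initial state (names become sample column names).
#' @param n_iter total chain length.
#' @param proposal_scales per-parameter Gaussian proposal SDs; recycled.
#' @param seed integer seed; a fixed seed reproduces the chain exactly.
#' @param burn_in_frac fraction of `n_iter` treated as burn-in (default 0.2).
#' @param adapt_every batch size (iterations) for burn-in scale adaptation.
#' @return An object of class `posterior_chain`: `samples`
#'   (`n_iter x d` matrix), `log_post` per iteration, `acceptance_rate`
#'   (post-burn-in), `burn_in` index, final `proposal_scales`, `seed`.
#' @export
metropolis_hastings <- function(log_post, init, n_iter = 1e5L,
                                proposal_scales = NULL, seed = 1L,
                                burn_in_frac = 0.2, adapt_every = 100L) {
  d <- length(init)
  n_iter <- as.integer(n_iter)
  scales <- rep_len(proposal_scales %||% (abs(init) * 0.1 + 0.1), d)
  lp0 <- log_post(init)
  if (!is.finite(lp0)) {
    tg_abort("`log_post` must be finite at `init`.",
             "tggpp_error_invalid_config")
  }
  burn_in <- as.integer(floor(n_iter * burn_in_frac))
  samples <- matrix(NA_real_, n_iter, d)
  colnames(samples) <- names(init) %||% paste0("par", seq_len(d))
  lps <- numeric(n_iter)
  with_seed(seed, {
    cur <- as.numeric(init); lp <- lp0
    acc_post <- 0L; acc_batch <- 0L
    for (it in seq_len(n_iter)) {
      prop <- cur + stats::rnorm(d) * scales
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) &&
          (lp_prop >= lp || log(stats::runif(1)) < lp_prop - lp)) {
        cur <- prop; lp <- lp_prop
        acc_batch <- acc_batch + 1L
        if (it > burn_in) acc_post <- acc_post + 1L
      }
      samples[it, ] <- cur
      lps[it] <- lp
      if (it <= burn_in && it %% adapt_every == 0L) {
        rate <- acc_batch / adapt_every
        if (rate < 0.2) scales <- scales * 0.8
        else if (rate > 0.5) scales <- scales * 1.25
        acc_batch <- 0L
      }
    }
    if (n_iter > burn_in && acc_post == 0L) {
      tg_abort("no accepted move after burn-in: chain is stuck.",
               "tggpp_error_stuck_chain")
    }
    structure(list(
      samples = samples, log_post = lps,
      acceptance_rate = acc_post / max(n_iter - burn_in, 1L),
      burn_in = burn_in, proposal_scales = scales, seed = seed
    ), class = "posterior_chain")
  })
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "<posterior_chain> %d iterations x %d parameters; burn-in %d; acceptance %.1f%%\n",
    nrow(x$samples), ncol(x$samples), x$burn_in, 100 * x$acceptance_rate))
  invisible(x)
}

#' Post-burn-in samples of a chain
#' @param chain a `posterior_chain`.
#' @return Matrix of samples after burn-in.
#' @export
posterior_samples <- function(chain) {
  chain$samples[(chain$burn_in + 1L):nrow(chain$samples), , drop = FALSE]
}

# split-chain potential scale reduction factor for one parameter, given a
# list of numeric sample vectors (each split in half internally)
#' @noRd
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps) {
    if (B <= .Machine$double.eps) return(1)
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence and identifiability diagnostics for posterior chains
#'
#' Programmatic proxies for the visual posterior-density and running-mean
#' checks used when reading MCMC output: per parameter, (a) the split-chain
#' potential scale reduction factor must be below `rhat_max`, (b) the drift
#' of the running mean over the last half of the retained samples must stay
#' below `drift_max` of the prior range, and (c) a posterior whose
#' Kolmogorov-Smirnov distance from its uniform prior falls below
#' `ks_min` is reported `prior-dominated` — the data carry no information
#' about that parameter, the situation observed for the maximum-temperature
#' parameter when LST never approaches it.
#'
#' @param chains a `posterior_chain` or list of them (same parameters).
#' @param ranges optional [param_ranges()] giving the uniform prior box; the
#'   prior-dominance check and range-relative drift need it. Parameters not
#'   named in `ranges` are diagnosed on (a) and (b) only, with drift
#'   relative to the observed sample span.
#' @param rhat_max,drift_max,ks_min diagnostic thresholds.
#' @return A `posterior_summary` data frame: per parameter the posterior
#'   mode (kernel density estimate), median, mean, 95% credible interval,
#'   diagnostics (`rhat`, `drift_frac`, `ks_d`) and a `status` of
#'   `"converged"`, `"not-converged"` or `"prior-dominated"`.
#' @export
diagnose_convergence <- function(chains, ranges = NULL, rhat_max = 1.1,
                                 drift_max = 0.05, ks_min = 0.15) {
  if (inherits(chains, "posterior_chain")) chains <- list(chains)
  if (!length(chains)) {
    tg_abort("need at least one chain.", "tggpp_error_insufficient_samples")
  }
  mats <- lapply(chains, posterior_samples)
  if (nrow(mats[[1L]]) < 10L) {
    tg_abort("too few post-burn-in samples to diagnose.",
             "tggpp_error_insufficient_samples")
  }
  pars <- colnames(mats[[1L]])
  res <- lapply(seq_along(pars), function(j) {
    per_chain <- lapply(mats, function(m) m[, j])
    x <- unlist(per_chain)
    rhat <- split_rhat(per_chain)
    # running-mean drift over the last half of the first chain
    y <- per_chain[[1L]]
    rm_all <- cumsum(y) / seq_along(y)
    last_half <- rm_all[(length(y) %/% 2L):length(y)]
    drift <- diff(range(last_half))
    rg <- NULL
    if (!is.null(ranges) && pars[j] %in% ranges$parameter) {
      i <- match(pars[j], ranges$parameter)
      rg <- c(ranges$lower[i], ranges$upper[i])
    }
    span <- if (!is.null(rg)) diff(rg) else max(diff(range(x)), .Machine$double.eps)
    drift_frac <- drift / span
    ks_d <- if (!is.null(rg)) {
      # KS distance to the uniform prior, computed directly (tie-proof)
      u <- stats::punif(sort(x), min = rg[1], max = rg[2])
      nn <- length(u)
      max(max(seq_len(nn) / nn - u), max(u - (seq_len(nn) - 1L) / nn))
    } else NA_real_
    mode <- if (stats::sd(x) <= .Machine$double.eps) x[1L] else {
      dens <- stats::density(x)
      dens$x[which.max(dens$y)]
    }
    status <- if (!is.na(ks_d) && ks_d < ks_min) "prior-dominated"
      else if (is.finite(rhat) && rhat < rhat_max && drift_frac < drift_max)
        "converged"
      else "not-converged"
    data.frame(
      parameter = pars[j],
      mode = mode,
      median = stats::median(x), mean = mean(x),
      ci_lower = unname(stats::quantile(x, 0.025)),
      ci_upper = unname(stats::quantile(x, 0.975)),
      rhat = unname(rhat), drift_frac = drift_frac, ks_d = unname(ks_d),
      status = status, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Bayesian calibration of the TG temperature parameters
#'
#' Samples the joint posterior of `(x_n, x_o, x_m, log_sigma)` for one PFT
#' (pooled sites) by random-walk Metropolis-Hastings: uniform priors over
#' `ranges` ([tg_log_prior()]), Gaussian error likelihood with `m` profiled
#' ([tg_log_likelihood()]). Initial proposal SDs are 5% of each prior
#' range, adapted during burn-in only.
#'
#' @param series a [site_series()] or list of them (pooled).
#' @param ranges a [param_ranges()] for the three temperature parameters.
#' @param n_iter chain length (default 1e5).
#' @param seed integer seed.
#' @param init optional initial `c(x_n, x_o, x_m, log_sigma)`; defaults to
#'   the range midpoints and the log observed GPP SD.
#' @param ... passed to [metropolis_hastings()].
#' @return A `posterior_chain` with columns `x_n`, `x_o`, `x_m`,
#'   `log_sigma`, carrying the `ranges` used as an attribute.
#' @export
calibrate_tg <- function(series, ranges = param_ranges(), n_iter = 1e5L,
                         seed = 1L, init = NULL, ...) {
  loglik <- make_tg_loglik(series)
  lsr <- log(c(0.01, 100))
  log_post <- function(x) {
    lp <- tg_log_prior(x[1:3], x[4], ranges, lsr)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(x[1:3], x[4])
  }
  if (is.null(init)) {
    pooled <- pool_series(series)
    g <- pooled$gpp[!pooled$masked & is.finite(pooled$gpp)]
    s0 <- stats::sd(g); if (!is.finite(s0) || s0 <= 0) s0 <- 1
    init <- c((ranges$lower + ranges$upper) / 2,
              min(max(log(s0), lsr[1] + 0.1), lsr[2] - 0.1))
    names(init) <- c(ranges$parameter, "log_sigma")
  }
  scales <- c((ranges$upper - ranges$lower) * 0.05, 0.1)
  chain <- metropolis_hastings(log_post, init, n_iter = n_iter,
                               proposal_scales = scales, seed = seed, ...)
  attr(chain, "ranges") <- ranges
  chain
}

#' Posterior summary of a TG calibration
#'
#' Convenience wrapper: [diagnose_convergence()] with the prior ranges the
#' chain was drawn under. The "optimized value" of a parameter is its
#' posterior mode from a kernel density estimate of the post-burn-in
#' samples; median and mean are reported alongside.
#'
#' @param chain a `posterior_chain` from [calibrate_tg()].
#' @param ... passed to [diagnose_convergence()].
#' @return A `posterior_summary` data frame.
#' @export
summarize_calibration <- function(chain, ...) {
  diagnose_convergence(chain, ranges = attr(chain, "ranges"), ...)
}

#' Write a posterior chain as CSV
#'
#' Columns `iteration`, one per parameter, and `log_post`.
#'
#' @param chain a `posterior_chain`.
#' @param path output file.
#' @export
write_chain_csv <- function(chain, path) {
  d <- data.frame(iteration = seq_len(nrow(chain$samples)), chain$samples,
                  log_post = chain$log_post)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
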