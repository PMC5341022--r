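#' Normalized Taylor-diagram statistics
#'
#' The skill triple used on a normalized Taylor diagram: Pearson correlation
#' `r`, model-to-observation standard-deviation ratio `std_norm`, and the
#' centered (bias-removed) root-mean-square difference divided by the
#' observation SD, `crmsd_norm`. A perfect model sits at
#' `(r = 1, std_norm = 1, crmsd_norm = 0)`. The mean bias, which centered
#' statistics cannot see, is reported separately as `bias_norm`. The three
#' centered statistics obey the law-of-cosines identity
#' `crmsd_norm^2 = 1 + std_norm^2 - 2 * std_norm * r`.
#'
#' Pairs where either series is missing are removed pairwise before
#' computing the statistics.
#'
#' @param obs,mod numeric series of equal length (NAs allowed; removed
#'   pairwise).
#' @return An object of class `taylor_stats`: `r`, `std_norm`,
#'   `crmsd_norm`, `bias_norm`, `n`.
#' @export
taylor_stats <- function(obs, mod) {
  if (length(obs) != length(mod)) {
    tg_abort("`obs` and `mod` must have the same length.",
             "tggpp_error_invalid_input")
  }
  keep <- is.finite(obs) & is.finite(mod)
  o <- obs[keep]; m <- mod[keep]
  n <- length(o)
  if (n < 3L) {
    tg_abort("need at least 3 paired months.", "tggpp_error_invalid_input")
  }
  so <- stats::sd(o)
  if (so <= .Machine$double.eps) {
    tg_abort("observation SD is zero: normalized statistics are undefined.",
             "tggpp_error_undefined_normalization")
  }
  sm <- stats::sd(m)
  r <- if (sm <= .Machine$double.eps) 0 else stats::cor(o, m)
  d <- (m - mean(m)) - (o - mean(o))
  structure(list(
    r = r,
    std_norm = sm / so,
    crmsd_norm = sqrt(sum(d * d) / (n - 1)) / so,
    bias_norm = mean(m - o) / so,
    n = n
  ), class = "taylor_stats")
}

#' @export
print.taylor_stats <- function(x, ...) {
  cat(sprintf(
    "<taylor_stats> r = %.3f, STD = %.3f, RMSD = %.3f, bias = %.3f (n = %d)\n",
    x$r, x$std_norm, x$crmsd_norm, x$bias_norm, x$n))
  invisible(x)
}

#' @export
as.data.frame.taylor_stats <- function(x, ...) {
  data.frame(r = x$r, std_norm = x$std_norm, crmsd_norm = x$crmsd_norm,
             bias_norm = x$bias_norm, n = x$n)
}

#' Polar coordinates of a Taylor point
#'
#' `azimuth = acos(r)` (radians) and `radius = std_norm` — the coordinates
#' at which the point is drawn on a Taylor diagram.
#'
#' @param x a `taylor_stats`.
#' @return Data frame with `azimuth` and `radius`.
#' @export
taylor_polar <- function(x) {
  stopifnot(inherits(x, "taylor_stats"))
  data.frame(azimuth = acos(min(max(x$r, -1), 1)), radius = x$std_norm)
}

#' Compare default and optimized model runs on the Taylor plane
#'
#' Computes [taylor_stats()] for two model versions against the same
#' observations and reports the deltas (optimized minus default) plus the
#' Euclidean distance moved on the Taylor plane (in the polar embedding
#' `(std_norm * cos(acos r), std_norm * sin(acos r))`) — the longer the
#' distance, the greater the effect of calibration.
#'
#' @param obs observed series.
#' @param mod_default,mod_optimized model predictions under default and
#'   calibrated parameters, aligned with `obs`.
#' @return A list with `default` and `optimized` (`taylor_stats`), `delta`
#'   (named numeric: `r`, `std_norm`, `crmsd_norm`) and `distance_moved`.
#' @export
compare_runs <- function(obs, mod_default, mod_optimized) {
  a <- taylor_stats(obs, mod_default)
  b <- taylor_stats(obs, mod_optimized)
  xy <- function(s) s$std_norm * c(s$r, sin(acos(min(max(s$r, -1), 1))))
  list(
    default = a, optimized = b,
    delta = c(r = b$r - a$r,
              std_norm = b$std_norm - a$std_norm,
              crmsd_norm = b$crmsd_norm - a$crmsd_norm),
    distance_moved = sqrt(sum((xy(b) - xy(a))^2))
  )
}

#' Taylor statistics of TG predictions for a pooled PFT series
#'
#' Predicts GPP with the given parameters (`m` profiled on the same pooled
#' unmasked months) and evaluates the normalized Taylor statistics against
#' observed GPP.
#'
#' @param series a [site_series()] or list of them (pooled per PFT).
#' @param params a [tg_params()]; its `m` is ignored and re-profiled.
#' @return A `taylor_stats`.
#' @export
evaluate_tg <- function(series, params = tg_params()) {
  pooled <- pool_series(series)
  keep <- !pooled$masked & is.finite(pooled$gpp) & is.finite(pooled$evi) &
    is.finite(pooled$lst)
  g <- pooled$gpp[keep]
  prod <- scale_evi(pooled$evi[keep]) * scale_lst(pooled$lst[keep], params)
  m <- fit_m(g, prod)
  taylor_stats(g, m * prod)
}
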