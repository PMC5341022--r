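#' SSA configuration
#'
#' Window length and number of leading components for singular spectrum
#' analysis smoothing. The defaults — a 37-month window and 6 leading
#' components — are the settings found to best capture the periodicity of
#' monthly EVI and LST series while suppressing random noise.
#'
#' @param window embedding window length in months (>= 2, <= series length - 1).
#' @param n_components number of leading eigentriples summed (1..window).
#' @return An object of class `ssa_config`.
#' @export
ssa_config <- function(window = 37L, n_components = 6L) {
  window <- as.integer(window); n_components <- as.integer(n_components)
  if (window < 2L) {
    tg_abort("`window` must be at least 2 months.", "tggpp_error_invalid_config")
  }
  if (n_components < 1L || n_components > window) {
    tg_abort("`n_components` must lie in 1..window.", "tggpp_error_invalid_config")
  }
  structure(list(window = window, n_components = n_components),
            class = "ssa_config")
}

#' Quality screening of EVI
#'
#' Masks EVI for months contaminated by snow/ice or cold-temperature
#' effects: EVI is set missing (and the month flagged in `masked`) wherever
#' the snow/ice flag is raised or LST < -2.0 degC (strict inequality; a
#' month at exactly -2.0 degC is retained). All other columns are untouched.
#' The operation is idempotent.
#'
#' @param series a [site_series()].
#' @param lst_threshold cold-screening threshold, degC (default -2.0).
#' @return The screened `site_series`, with attribute `n_masked` giving the
#'   number of months masked by this screening.
#' @export
qa_screen <- function(series, lst_threshold = -2.0) {
  stopifnot(inherits(series, "site_series"))
  drop <- series$snow_flag | (is.finite(series$lst) & series$lst < lst_threshold)
  drop[is.na(drop)] <- FALSE
  out <- series
  out$evi[drop] <- NA_real_
  out$masked <- out$masked | drop
  attr(out, "n_masked") <- sum(drop)
  if (all(out$masked)) {
    message("qa_screen: every month is masked for site ", site_id(series))
  }
  out
}

# Linear interpolation of internal gaps of at most `max_gap` consecutive
# months; edge gaps and longer runs are filled too (nearest-value carry /
# interpolation) so SSA sees a complete series, but months in runs longer
# than `max_gap` stay TRUE in the returned `long_gap` attribute so callers
# keep them masked for likelihoods and statistics.
#' @noRd
fill_gaps <- function(x, max_gap = 3L) {
  n <- length(x)
  miss <- !is.finite(x)
  if (!any(miss)) return(structure(x, long_gap = logical(n)))
  if (all(miss)) {
    tg_abort("series has no finite values to interpolate from.",
             "tggpp_error_insufficient_data")
  }
  filled <- stats::approx(seq_len(n)[!miss], x[!miss], xout = seq_len(n),
                          rule = 2)$y
  r <- rle(miss)
  long <- rep(r$values & r$lengths > max_gap, r$lengths)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  edge <- rep(r$values & (starts == 1L | ends == n), r$lengths)
  structure(filled, long_gap = long | edge)
}

#' Singular spectrum analysis reconstruction
#'
#' Smooths a complete (gap-free) series by SSA: embed the series into the
#' `window x (N - window + 1)` Hankel trajectory matrix, take its singular
#' value decomposition, sum the first `n_components` rank-one terms, and
#' Hankelize back to a series by anti-diagonal averaging. With
#' `n_components = window` the input is reproduced to numerical tolerance.
#'
#' @param x numeric series without missing values, length >= `window + 1`.
#' @param cfg an [ssa_config()].
#' @return Smoothed series of the same length as `x`.
#' @export
ssa_reconstruct <- function(x, cfg = ssa_config()) {
  stopifnot(inherits(cfg, "ssa_config"))
  check_finite(x, "x")
  n <- length(x); L <- cfg$window; k <- cfg$n_components
  if (n < L + 1L) {
    tg_abort(sprintf("series length %d is below window + 1 = %d.", n, L + 1L),
             "tggpp_error_insufficient_data")
  }
  K <- n - L + 1L
  traj <- stats::embed(x, L)[, L:1, drop = FALSE]   # K x L, rows are windows
  s <- svd(t(traj), nu = k, nv = k)                 # L x K trajectory matrix
  d <- s$d[seq_len(k)]
  approxim <- s$u %*% (d * t(s$v))                  # rank-k L x K
  # anti-diagonal averaging: mean over each i + j = const
  out <- numeric(n); cnt <- numeric(n)
  for (j in seq_len(K)) {
    idx <- j:(j + L - 1L)
    out[idx] <- out[idx] + approxim[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' Preprocess a site series for model fitting
#'
#' The standard preparation chain: QA screening ([qa_screen()]), linear
#' interpolation of short internal gaps (<= `max_gap` months), then SSA
#' smoothing ([ssa_reconstruct()]) of EVI and LST separately. Months masked
#' by screening, or lying in gaps too long to interpolate, remain masked and
#' are excluded from all downstream likelihoods and statistics rather than
#' imputed.
#'
#' @param series a [site_series()].
#' @param cfg an [ssa_config()].
#' @param max_gap longest internal gap (months) bridged by interpolation.
#' @param smooth apply SSA (default TRUE); FALSE performs screening and gap
#'   handling only.
#' @return The preprocessed `site_series`.
#' @export
preprocess_site <- function(series, cfg = ssa_config(), max_gap = 3L,
                            smooth = TRUE) {
  x <- qa_screen(series)
  evi_f <- fill_gaps(x$evi, max_gap)
  lst_f <- fill_gaps(x$lst, max_gap)
  x$masked <- x$masked | attr(evi_f, "long_gap") | attr(lst_f, "long_gap")
  if (smooth && nrow(x) >= cfg$window + 1L) {
    x$evi <- ssa_reconstruct(as.numeric(evi_f), cfg)
    x$lst <- ssa_reconstruct(as.numeric(lst_f), cfg)
  } else {
    x$evi <- as.numeric(evi_f)
    x$lst <- as.numeric(lst_f)
  }
  x
}
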