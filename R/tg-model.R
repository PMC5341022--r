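#' TG model parameters
#'
#' The temperature-and-greenness (TG) model has three temperature parameters
#' — the minimum (`x_n`), optimum (`x_o`) and maximum (`x_m`) land surface
#' temperature for photosynthesis, in degrees C — plus a proportionality
#' scalar `m` (gC m^-2 day^-1). The published defaults are (0, 30, 50) degC.
#' Strict ordering `x_n < x_o < x_m` is required; degenerate orderings are
#' rejected, not repaired.
#'
#' @param x_n minimum LST for photosynthesis, degC.
#' @param x_o optimum LST, degC.
#' @param x_m maximum LST, degC.
#' @param m proportionality scalar, gC m^-2 day^-1 (>= 0). Usually profiled
#'   out by [fit_m()] rather than set directly.
#' @return An object of class `tg_params`.
#' @examples
#' tg_params()          # published defaults
#' tg_params(-10, 27, 50, m = 8)
#' @export
tg_params <- function(x_n = 0, x_o = 30, x_m = 50, m = 1) {
  check_finite(c(x_n, x_o, x_m, m), "tg_params")
  if (!(x_n < x_o && x_o < x_m)) {
    tg_abort("TG parameters must satisfy x_n < x_o < x_m (strict).",
             "tggpp_error_invalid_params")
  }
  if (m < 0) tg_abort("`m` must be >= 0.", "tggpp_error_invalid_params")
  structure(list(x_n = x_n, x_o = x_o, x_m = x_m, m = m),
            class = "tg_params")
}

#' @export
print.tg_params <- function(x, ...) {
  cat(sprintf(
    "<tg_params> x_n = %.2f, x_o = %.2f, x_m = %.2f degC; m = %.3f\n",
    x$x_n, x$x_o, x$x_m, x$m))
  invisible(x)
}

#' Scaled EVI
#'
#' The greenness scalar of the TG model: `max(evi - 0.1, 0)`. The offset 0.1
#' is the EVI value at which GPP drops to zero; values below it are clamped
#' to zero so predicted GPP stays non-negative.
#'
#' @param evi enhanced vegetation index, dimensionless, typically in
#'   \[-0.2, 1\].
#' @return Scaled EVI in \[0, 0.9\], same length as `evi`.
#' @export
scale_evi <- function(evi) {
  check_finite(evi, "evi")
  pmax(evi - 0.1, 0)
}

#' Scaled LST
#'
#' The temperature scalar of the TG model: the smaller of the two linear
#' ramps `(lst - x_n)/(x_o - x_n)` and `(x_m - lst)/(x_m - x_o)`, clamped
#' below at 0. It equals 1 exactly at `lst = x_o` and 0 at or beyond `x_n`
#' and `x_m`; under strict parameter ordering the min of the two ramps never
#' exceeds 1, so no upper clamp is needed.
#'
#' @param lst land surface temperature, degC.
#' @param params a [tg_params()] object.
#' @return Scaled LST in \[0, 1\], same length as `lst`.
#' @export
scale_lst <- function(lst, params = tg_params()) {
  stopifnot(inherits(params, "tg_params"))
  check_finite(lst, "lst")
  up <- (lst - params$x_n) / (params$x_o - params$x_n)
  down <- (params$x_m - lst) / (params$x_m - params$x_o)
  pmax(pmin(up, down), 0)
}

#' TG model GPP prediction
#'
#' Elementwise `m * scale_evi(evi) * scale_lst(lst, params)`: GPP as a
#' proportionally linear function of the product of scaled greenness and
#' scaled land surface temperature.
#'
#' @param evi,lst equal-length numeric series.
#' @inheritParams scale_lst
#' @return Predicted GPP, gC m^-2 day^-1, all values >= 0.
#' @examples
#' predict_gpp(evi = 0.6, lst = 30, params = tg_params(m = 10))  # 5
#' @export
predict_gpp <- function(evi, lst, params = tg_params()) {
  if (length(evi) != length(lst)) {
    tg_abort("`evi` and `lst` must have the same length.",
             "tggpp_error_invalid_input")
  }
  params$m * scale_evi(evi) * scale_lst(lst, params)
}

#' Profile the proportionality scalar m
#'
#' Origin-constrained least squares of observed GPP on the scaled
#' EVI-times-LST product: `m = sum(p * g) / sum(p^2)`, truncated below at 0.
#' The TG model is calibrated over its three temperature parameters only, so
#' `m` is re-estimated (profiled out) for every candidate parameter set.
#'
#' @param gpp_obs observed GPP series.
#' @param product series of `scale_evi(evi) * scale_lst(lst, params)`;
#'   must contain at least one positive value.
#' @return The scalar `m >= 0`.
#' @export
fit_m <- function(gpp_obs, product) {
  if (length(gpp_obs) != length(product)) {
    tg_abort("`gpp_obs` and `product` must have the same length.",
             "tggpp_error_invalid_input")
  }
  keep <- is.finite(gpp_obs) & is.finite(product)
  g <- gpp_obs[keep]; p <- product[keep]
  if (!length(p) || all(p == 0)) {
    tg_abort("all-zero scaled product: the slope through the origin is undefined.",
             "tggpp_error_degenerate_fit")
  }
  max(sum(p * g) / sum(p * p), 0)
}

# RMSE of the TG prediction with m profiled, over unmasked months.
# The scalar fit statistic used by Morris screening; also the residual core
# of the calibration likelihood.
#' @noRd
tg_rmse <- function(series, params) {
  keep <- !series$masked & is.finite(series$gpp) & is.finite(series$evi) &
    is.finite(series$lst)
  evi_s <- scale_evi(series$evi[keep])
  lst_s <- scale_lst(series$lst[keep], params)
  prod <- evi_s * lst_s
  g <- series$gpp[keep]
  m <- tryCatch(fit_m(g, prod), tggpp_error_degenerate_fit = function(e) 0)
  sqrt(mean((g - m * prod)^2))
}
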