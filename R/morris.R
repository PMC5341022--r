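#' Parameter ranges for screening and calibration
#'
#' Lower and upper bounds per parameter, in degC. The defaults are the wide
#' screening/calibration ranges used for the three TG temperature
#' parameters: x_n in \[-15, 10\], x_o in \[10, 40\], x_m in \[40, 65\].
#'
#' @param parameter character vector of parameter names.
#' @param lower,upper numeric bounds, `lower < upper` elementwise.
#' @return An object of class `param_ranges` (a data frame).
#' @export
param_ranges <- function(parameter = c("x_n", "x_o", "x_m"),
                         lower = c(-15, 10, 40),
                         upper = c(10, 40, 65)) {
  if (length(parameter) != length(lower) || length(lower) != length(upper)) {
    tg_abort("`parameter`, `lower`, `upper` must have equal length.",
             "tggpp_error_invalid_config")
  }
  if (any(lower >= upper)) {
    tg_abort("each lower bound must be strictly below its upper bound.",
             "tggpp_error_invalid_config")
  }
  structure(data.frame(parameter = parameter, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("param_ranges", "data.frame"))
}

# map unit-cube coordinates (vector or matrix rows) to physical units
#' @noRd
map_to_ranges <- function(u, ranges) {
  lo <- ranges$lower; hi <- ranges$upper
  if (is.matrix(u)) sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  else lo + u * (hi - lo)
}

#' Morris one-at-a-time screening design
#'
#' Builds `r` random Morris trajectories on the `p`-level grid of the unit
#' cube. Each trajectory has `n_params + 1` points; consecutive points
#' differ in exactly one coordinate by the canonical step
#' `delta = p / (2 * (p - 1))`, and each parameter moves exactly once per
#' trajectory. Mapping to physical units is affine per `ranges`. If an
#' `accept` predicate is supplied (e.g. the strict TG parameter ordering), a
#' trajectory containing any rejected physical point is resampled wholesale,
#' so the design never evaluates an invalid parameter set.
#'
#' @param ranges a [param_ranges()].
#' @param r number of trajectories (>= 2).
#' @param p number of grid levels (even, >= 4).
#' @param seed integer seed; the design is byte-identical across runs for a
#'   fixed seed.
#' @param accept optional `function(theta)` returning TRUE for admissible
#'   physical parameter vectors.
#' @return An object of class `morris_design`: trajectories in unit-cube and
#'   physical coordinates plus design metadata.
#' @export
morris_design <- function(ranges, r = 20L, p = 8L, seed = 1L, accept = NULL) {
  stopifnot(inherits(ranges, "param_ranges"))
  r <- as.integer(r); p <- as.integer(p)
  if (r < 2L || p < 4L || p %% 2L != 0L) {
    tg_abort("need r >= 2 trajectories and an even number of levels p >= 4.",
             "tggpp_error_invalid_config")
  }
  k <- nrow(ranges)
  delta <- p / (2 * (p - 1))
  base_levels <- (0:(p - 1)) / (p - 1)
  start_levels <- base_levels[base_levels <= 1 - delta + 1e-12]
  with_seed(seed, {
    trajs <- vector("list", r)
    for (t in seq_len(r)) {
      repeat {
        x0 <- sample(start_levels, k, replace = TRUE)
        dirs <- sample(c(-1, 1), k, replace = TRUE)
        perm <- sample.int(k)
        pts <- matrix(NA_real_, k + 1L, k)
        cur <- x0 + ifelse(dirs < 0, delta, 0)
        pts[1L, ] <- cur
        for (s in seq_len(k)) {
          i <- perm[s]
          cur[i] <- cur[i] + dirs[i] * delta
          pts[s + 1L, ] <- cur
        }
        phys <- map_to_ranges(pts, ranges)
        ok <- is.null(accept) || all(apply(phys, 1L, accept))
        if (ok) {
          trajs[[t]] <- list(unit = pts, phys = phys, perm = perm, dirs = dirs)
          break
        }
      }
    }
    structure(list(trajectories = trajs, delta = delta, r = r, p = p,
                   seed = seed, ranges = ranges),
              class = "morris_design")
  })
}

#' Design points of a Morris design
#'
#' @param design a [morris_design()].
#' @param units `"phys"` (default) or `"unit"`.
#' @return Matrix of all `r * (n_params + 1)` design points, trajectory by
#'   trajectory, in the requested coordinates.
#' @export
design_points <- function(design, units = c("phys", "unit")) {
  units <- match.arg(units)
  do.call(rbind, lapply(design$trajectories, `[[`, units))
}

#' Elementary effects from evaluated design points
#'
#' For each trajectory step that moved parameter i by `+/- delta` (in
#' unit-cube coordinates), the elementary effect is
#' `(f(after) - f(before)) / (+/- delta)`, signed by the direction of the
#' move. Trajectories containing a non-finite output are dropped with a
#' warning.
#'
#' @param design a [morris_design()].
#' @param outputs numeric vector of model outputs, one per design point, in
#'   the order of [design_points()].
#' @return An `r x n_params` matrix of elementary effects (rows = retained
#'   trajectories).
#' @export
elementary_effects <- function(design, outputs) {
  k <- nrow(design$ranges)
  npt <- k + 1L
  if (length(outputs) != design$r * npt) {
    tg_abort("`outputs` length must equal r * (n_params + 1).",
             "tggpp_error_invalid_input")
  }
  ee <- matrix(NA_real_, design$r, k)
  bad <- logical(design$r)
  for (t in seq_len(design$r)) {
    y <- outputs[((t - 1L) * npt + 1L):(t * npt)]
    if (any(!is.finite(y))) { bad[t] <- TRUE; next }
    tr <- design$trajectories[[t]]
    for (s in seq_len(k)) {
      i <- tr$perm[s]
      ee[t, i] <- (y[s + 1L] - y[s]) / (tr$dirs[i] * design$delta)
    }
  }
  if (any(bad)) {
    warning(sprintf("%d trajectory(ies) dropped: non-finite model output.",
                    sum(bad)))
    ee <- ee[!bad, , drop = FALSE]
  }
  if (!nrow(ee)) {
    tg_abort("no finite trajectory remains.", "tggpp_error_invalid_input")
  }
  colnames(ee) <- design$ranges$parameter
  ee
}

# Summarise an EE matrix into a morris_result
#' @noRd
morris_summary <- function(ee, design) {
  mu_star <- colMeans(abs(ee))
  sigma <- apply(ee, 2L, stats::sd)
  ord <- order(-mu_star, seq_along(mu_star))   # ties: declaration order
  rk <- integer(length(mu_star)); rk[ord] <- seq_along(mu_star)
  structure(list(
    parameter = design$ranges$parameter,
    mu_star = mu_star, sigma = sigma, rank = rk,
    interaction_flag = sigma > 2 * mu_star,
    ee = ee, r = nrow(ee), p = design$p, seed = design$seed
  ), class = "morris_result")
}

#' @export
print.morris_result <- function(x, ...) {
  cat(sprintf("<morris_result> r = %d trajectories, p = %d levels\n", x$r, x$p))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.morris_result <- function(x, ...) {
  data.frame(parameter = x$parameter, mu_star = x$mu_star, sigma = x$sigma,
             rank = x$rank, interaction_flag = x$interaction_flag,
             row.names = NULL)
}

#' Morris screening of an arbitrary scalar model
#'
#' Runs the full Morris procedure — design, model evaluation, elementary
#' effects, summary — for a scalar-valued function of the physical
#' parameters. The summary reports, per parameter, the mean of absolute
#' elementary effects (`mu_star`, influence), their standard deviation
#' (`sigma`, non-linearity/interaction), the influence rank (1 = most
#' influential, ties broken by declaration order) and an interaction flag
#' raised where `sigma > 2 * mu_star`.
#'
#' @param f `function(theta)` returning a finite scalar for an admissible
#'   physical parameter vector.
#' @inheritParams morris_design
#' @return A `morris_result`.
#' @export
morris_screen <- function(f, ranges, r = 20L, p = 8L, seed = 1L,
                          accept = NULL) {
  design <- morris_design(ranges, r = r, p = p, seed = seed, accept = accept)
  pts <- design_points(design)
  outputs <- apply(pts, 1L, f)
  morris_summary(elementary_effects(design, outputs), design)
}

#' Morris screening of the TG model on observed data
#'
#' Screens the three TG temperature parameters against a model-fit scalar:
#' the root-mean-square error between TG predictions (with the scalar `m`
#' profiled out by [fit_m()]) and observed GPP over the pooled series.
#' Design points violating the strict ordering `x_n < x_o < x_m` are never
#' evaluated (the trajectory is resampled).
#'
#' @param series a [site_series()] or list of them (pooled, e.g. all sites
#'   of one PFT); months masked by QA are excluded.
#' @inheritParams morris_design
#' @return A `morris_result` with parameters ranked by descending `mu_star`.
#' @export
screen_tg <- function(series, ranges = param_ranges(), r = 20L, p = 8L,
                      seed = 1L) {
  pooled <- pool_series(series)
  keep <- !pooled$masked & is.finite(pooled$gpp) & is.finite(pooled$evi) &
    is.finite(pooled$lst)
  if (!any(keep)) {
    tg_abort("no usable months after QA masking.", "tggpp_error_no_data")
  }
  f <- function(theta) {
    tg_rmse(pooled, tg_params(theta[1], theta[2], theta[3], m = 1))
  }
  ordering_ok <- function(theta) theta[1] < theta[2] && theta[2] < theta[3]
  morris_screen(f, ranges, r = r, p = p, seed = seed, accept = ordering_ok)
}

# Pool one series or a list of series into one masked data frame for
# fitting; rows are simply concatenated (per-PFT pooling).
#' @noRd
pool_series <- function(series) {
  if (inherits(series, "site_series")) return(series)
  if (is.data.frame(series)) return(series)
  if (!length(series)) tg_abort("empty series list.", "tggpp_error_no_data")
  do.call(rbind, lapply(series, function(s) as.data.frame(s)))
}

#' Long-format export of a Morris result
#'
#' One row per parameter and metric (`mu_star`, `sigma`) — the layout a
#' radar plot of per-PFT screening results consumes.
#'
#' @param x a `morris_result`.
#' @param pft optional PFT label column.
#' @return A long data frame with columns `pft` (if given), `parameter`,
#'   `metric`, `value`.
#' @export
morris_long <- function(x, pft = NULL) {
  d <- data.frame(
    parameter = rep(x$parameter, 2L),
    metric = rep(c("mu_star", "sigma"), each = length(x$parameter)),
    value = c(x$mu_star, x$sigma)
  )
  if (!is.null(pft)) d <- cbind(pft = pft, d)
  d
}
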