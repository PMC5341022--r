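#' Synthetic PFT preset
#'
#' Ground-truth configuration for simulating one plant functional type:
#' true TG parameters, seasonal LST/EVI climatology, observation noise as a
#' fraction of mean GPP, optional additive radiation/precipitation
#' co-driver strengths, and a winter snow-flag probability.
#'
#' @param pft a PFT code, see [pft_codes()].
#' @param params true [tg_params()] (including the scalar `m`).
#' @param lst_mean,lst_amp seasonal mean and amplitude of LST, degC.
#' @param evi_mean,evi_amp seasonal mean and amplitude of EVI (kept in
#'   \[0, 1\]).
#' @param phase EVI phase lag behind the LST cycle, months.
#' @param noise_frac GPP observation noise SD as a fraction of mean clean
#'   GPP (in \[0, 1\]).
#' @param rad_coeff,prc_coeff additive co-driver strengths applied to the
#'   standardized radiation and precipitation anomalies, gC m^-2 day^-1 per
#'   SD.
#' @param snow_prob probability that a winter month (the 3 months of lowest
#'   LST climatology) is snow-flagged.
#' @param ar1 lag-1 autocorrelation of the GPP noise (0 = i.i.d., the
#'   default, matching the calibration likelihood; > 0 stresses
#'   misspecification).
#' @return An object of class `pft_preset`.
#' @export
pft_preset <- function(pft, params, lst_mean, lst_amp, evi_mean, evi_amp,
                       phase = 0, noise_frac = 0.15, rad_coeff = 0,
                       prc_coeff = 0, snow_prob = 0, ar1 = 0) {
  stopifnot(inherits(params, "tg_params"))
  if (!pft %in% pft_codes()) {
    tg_abort(sprintf("unknown PFT '%s'.", pft), "tggpp_error_invalid_preset")
  }
  if (noise_frac < 0 || noise_frac > 1) {
    tg_abort("`noise_frac` must lie in [0, 1].", "tggpp_error_invalid_preset")
  }
  if (evi_mean - evi_amp < 0 || evi_mean + evi_amp > 1) {
    tg_abort("EVI seasonal cycle must stay inside [0, 1].",
             "tggpp_error_invalid_preset")
  }
  structure(list(pft = pft, params = params, lst_mean = lst_mean,
                 lst_amp = lst_amp, evi_mean = evi_mean, evi_amp = evi_amp,
                 phase = phase, noise_frac = noise_frac,
                 rad_coeff = rad_coeff, prc_coeff = prc_coeff,
                 snow_prob = snow_prob, ar1 = ar1),
            class = "pft_preset")
}

#' Default presets for the twelve PFTs
#'
#' True temperature parameters follow the per-PFT calibrated values of the
#' TG model (e.g. evergreen broadleaf forest with an optimum LST of 15 degC
#' and evergreen needleleaf forest with a minimum of -10 degC); seasonal
#' climatologies, proportionality scalars and snow probabilities are chosen
#' to caricature each biome (tropical EBF warm and aseasonal, boreal
#' DNF/ENF cold with frequent winter snow, etc.).
#'
#' @param noise_frac GPP noise fraction applied to every preset.
#' @return Named list of twelve [pft_preset()] objects.
#' @export
pft_presets <- function(noise_frac = 0.15) {
  spec <- list(
    #      x_n   x_o  x_m   m  lstm lsta evim evia snow
    CRO = c(0,   30,  50,   7,  12,  15, 0.45, 0.25, 0.20),
    CSH = c(0,   29,  50,   5,  16,  10, 0.35, 0.15, 0.05),
    DBF = c(2.5, 27,  50,   9,  12,  14, 0.50, 0.30, 0.30),
    DNF = c(0,   30,  50,   6,   0,  20, 0.35, 0.25, 0.60),
    EBF = c(-6,  15,  50,  10,  24,   4, 0.60, 0.10, 0.00),
    ENF = c(-10, 27,  50,   8,   5,  16, 0.45, 0.20, 0.50),
    GRA = c(0,   27,  50,   6,  10,  14, 0.40, 0.20, 0.25),
    MF  = c(0,   24,  50,   8,  10,  14, 0.50, 0.25, 0.30),
    OSH = c(0,   30,  50,   4,   8,  14, 0.25, 0.10, 0.30),
    SAV = c(0,   28,  50,   6,  25,   6, 0.35, 0.15, 0.00),
    WET = c(5,   22,  50,   7,  10,  12, 0.45, 0.20, 0.20),
    WSA = c(0,   31,  50,   6,  22,   8, 0.35, 0.15, 0.00)
  )
  out <- lapply(names(spec), function(code) {
    v <- spec[[code]]
    pft_preset(code, tg_params(v[1], v[2], v[3], m = v[4]),
               lst_mean = v[5], lst_amp = v[6],
               evi_mean = v[7], evi_amp = v[8],
               noise_frac = noise_frac, snow_prob = v[9])
  })
  stats::setNames(out, names(spec))
}

# AR(1) series with marginal SD `sd`
#' @noRd
ar1_noise <- function(n, sd, phi = 0.5) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  x <- numeric(n); x[1] <- stats::rnorm(1, sd = sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + e[i + 1L]
  x
}

#' Simulate one synthetic flux site
#'
#' Generates a multi-year monthly [site_series()] from a [pft_preset()]:
#' LST and EVI follow sinusoidal seasonal cycles (warmest month July) plus
#' mild autocorrelated noise; precipitation is log-normal; radiation is
#' sinusoidal. Observed GPP is the TG model applied to the realized EVI and
#' LST, plus the optional standardized radiation/precipitation co-drivers,
#' plus Gaussian noise with SD `noise_frac * mean(clean GPP)`, truncated
#' below at 0. Winter months (the three coldest climatological months)
#' receive a snow flag with the preset probability. Fully reproducible from
#' `seed`.
#'
#' @param preset a [pft_preset()].
#' @param n_years number of simulated years (>= 2).
#' @param seed integer seed.
#' @param site_id identifier (default derived from the PFT).
#' @param start first month (a `Date`, first of month).
#' @return A `site_series` with attribute `truth` (list: the true
#'   `tg_params` and the realized noise SD).
#' @export
simulate_site <- function(preset, n_years = 10L, seed = 1L,
                          site_id = paste0("SYN_", preset$pft),
                          start = as.Date("2000-01-01")) {
  stopifnot(inherits(preset, "pft_preset"))
  if (n_years < 2L) {
    tg_abort("need at least 2 simulated years.", "tggpp_error_invalid_preset")
  }
  n <- 12L * as.integer(n_years)
  dates <- seq(start, by = "month", length.out = n)
  mon <- as.integer(format(dates, "%m"))
  seas <- function(amp, lag = 0) amp * cos(2 * pi * (mon - 7 - lag) / 12)
  with_seed(seed, {
    lst <- preset$lst_mean + seas(preset$lst_amp) + ar1_noise(n, 1.5)
    evi <- pmin(pmax(
      preset$evi_mean + seas(preset$evi_amp, preset$phase) +
        ar1_noise(n, 0.02), 0), 1)
    rad <- pmax(15 + seas(8) + stats::rnorm(n, sd = 1), 0)
    prc <- stats::rlnorm(n, meanlog = log(60), sdlog = 0.5)
    gpp_clean <- predict_gpp(evi, lst, preset$params)
    zscore <- function(x) (x - mean(x)) / max(stats::sd(x), .Machine$double.eps)
    noise_sd <- preset$noise_frac * mean(gpp_clean)
    noise <- if (preset$ar1 > 0) ar1_noise(n, noise_sd, preset$ar1)
      else stats::rnorm(n, sd = noise_sd)
    gpp <- pmax(gpp_clean + preset$rad_coeff * zscore(rad) +
                  preset$prc_coeff * zscore(prc) + noise, 0)
    clim <- vapply(1:12, function(k) {
      preset$lst_mean + preset$lst_amp * cos(2 * pi * (k - 7) / 12)
    }, 0)
    winter <- order(clim)[1:3]
    snow <- (mon %in% winter) & (stats::runif(n) < preset$snow_prob)
    out <- site_series(dates, gpp, evi, lst, prc, rad, snow,
                       site_id = site_id, pft = preset$pft)
    attr(out, "truth") <- list(params = preset$params, noise_sd = noise_sd)
    out
  })
}

#' Simulate a cohort of synthetic sites
#'
#' Independent sites for each preset, with per-site seeds derived
#' deterministically from one master seed and unique site identifiers.
#'
#' @param presets list of [pft_preset()] (default: all twelve,
#'   [pft_presets()]).
#' @param sites_per_pft sites simulated per preset (>= 1).
#' @param n_years years per site.
#' @param seed master seed.
#' @return A list of class `site_cohort`: `series` (list of
#'   `site_series`) and `manifest` (data frame with site_id, pft, the true
#'   parameters and the per-site seed).
#' @export
simulate_cohort <- function(presets = pft_presets(), sites_per_pft = 1L,
                            n_years = 10L, seed = 1L) {
  if (sites_per_pft < 1L) {
    tg_abort("`sites_per_pft` must be >= 1.", "tggpp_error_invalid_preset")
  }
  n_sites <- length(presets) * sites_per_pft
  seeds <- derive_seeds(seed, n_sites)
  series <- vector("list", n_sites)
  rows <- vector("list", n_sites)
  k <- 0L
  for (preset in presets) {
    for (i in seq_len(sites_per_pft)) {
      k <- k + 1L
      sid <- sprintf("SYN_%s_%02d", preset$pft, i)
      series[[k]] <- simulate_site(preset, n_years = n_years,
                                   seed = seeds[k], site_id = sid)
      p <- preset$params
      rows[[k]] <- data.frame(site_id = sid, pft = preset$pft,
                              x_n = p$x_n, x_o = p$x_o, x_m = p$x_m,
                              m = p$m, seed = seeds[k])
    }
  }
  names(series) <- vapply(series, site_id, "")
  structure(list(series = series, manifest = do.call(rbind, rows)),
            class = "site_cohort")
}

#' @export
print.site_cohort <- function(x, ...) {
  cat(sprintf("<site_cohort> %d sites, %d PFTs\n",
              length(x$series), length(unique(x$manifest$pft))))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One site-series CSV per site plus a `manifest.csv` holding the ground
#' truth (site_id, pft, true x_n/x_o/x_m/m, per-site seed).
#'
#' @param cohort a `site_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$series) {
    write_site_csv(s, file.path(dir, paste0(site_id(s), ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
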