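#' Plant functional type codes
#'
#' The twelve plant functional types (PFTs) used throughout the package:
#' cropland (CRO), closed shrubland (CSH), deciduous broadleaf forest (DBF),
#' deciduous needleleaf forest (DNF), evergreen broadleaf forest (EBF),
#' evergreen needleleaf forest (ENF), grassland (GRA), mixed forest (MF),
#' open shrubland (OSH), savanna (SAV), wetland (WET) and woody savanna (WSA).
#'
#' @return Character vector of the twelve PFT codes.
#' @export
pft_codes <- function() {
  c("CRO", "CSH", "DBF", "DNF", "EBF", "ENF",
    "GRA", "MF", "OSH", "SAV", "WET", "WSA")
}

#' Monthly flux-site series
#'
#' Construct a `site_series`: aligned monthly vectors of observed GPP, EVI,
#' LST, precipitation and shortwave radiation with a snow/ice QA flag, a
#' mask column, a site identifier and a PFT label. This is the container
#' every stage of the pipeline consumes.
#'
#' @param date `Date` vector, first of each month, strictly increasing at a
#'   monthly step.
#' @param gpp observed gross primary production, gC m^-2 day^-1 (NA allowed;
#'   non-missing values must be >= 0).
#' @param evi enhanced vegetation index, dimensionless (NA allowed).
#' @param lst land surface temperature, degrees C.
#' @param prc precipitation, mm month^-1.
#' @param rad shortwave radiation, MJ m^-2 day^-1.
#' @param snow_flag logical, TRUE where the month is snow/ice contaminated.
#' @param site_id character scalar identifier.
#' @param pft one of [pft_codes()].
#' @param masked logical; months excluded from likelihoods and statistics.
#'   Defaults to all `FALSE`; [qa_screen()] sets it.
#'
#' @return A data frame of class `site_series` with columns `date`, `gpp`,
#'   `evi`, `lst`, `prc`, `rad`, `snow_flag`, `masked` and attributes
#'   `site_id` and `pft`.
#' @seealso [qa_screen()], [simulate_site()], [read_site_csv()]
#' @export
site_series <- function(date, gpp, evi, lst, prc, rad, snow_flag,
                        site_id, pft, masked = NULL) {
  n <- length(date)
  lens <- c(length(gpp), length(evi), length(lst), length(prc),
            length(rad), length(snow_flag))
  if (any(lens != n)) {
    tg_abort("all series columns must have the same length as `date`.",
             "tggpp_error_invalid_input")
  }
  if (!inherits(date, "Date")) date <- as.Date(date)
  x <- data.frame(
    date = date,
    gpp = as.numeric(gpp), evi = as.numeric(evi), lst = as.numeric(lst),
    prc = as.numeric(prc), rad = as.numeric(rad),
    snow_flag = as.logical(snow_flag),
    masked = if (is.null(masked)) rep(FALSE, n) else as.logical(masked)
  )
  attr(x, "site_id") <- as.character(site_id)
  attr(x, "pft") <- as.character(pft)
  class(x) <- c("site_series", "data.frame")
  validate_site_series(x)
}

#' @noRd
validate_site_series <- function(x) {
  if (nrow(x) < 1) tg_abort("empty series.", "tggpp_error_invalid_input")
  pft <- attr(x, "pft")
  if (!pft %in% pft_codes()) {
    tg_abort(sprintf("unknown PFT code '%s'.", pft),
             "tggpp_error_invalid_input")
  }
  if (nrow(x) > 1) {
    step <- diff(12 * as.integer(format(x$date, "%Y")) +
                   as.integer(format(x$date, "%m")))
    if (any(step != 1L)) {
      tg_abort("`date` must increase in strict monthly steps.",
               "tggpp_error_invalid_input")
    }
  }
  if (any(x$gpp < 0, na.rm = TRUE)) {
    tg_abort("observed GPP must be non-negative where present.",
             "tggpp_error_invalid_input")
  }
  x
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("<site_series> %s (%s): %d months, %s to %s; %d masked\n",
              attr(x, "site_id"), attr(x, "pft"), nrow(x),
              format(min(x$date)), format(max(x$date)), sum(x$masked)))
  invisible(x)
}

#' Site identifier and PFT accessors
#' @param x a `site_series`.
#' @return `site_id()` the site identifier; `site_pft()` the PFT code.
#' @export
site_id <- function(x) attr(x, "site_id")

#' @rdname site_id
#' @export
site_pft <- function(x) attr(x, "pft")

#' Read and write monthly site series as CSV
#'
#' The on-disk schema has header columns `site_id, pft, date, gpp, evi, lst,
#' prc, rad, snow_flag` (ISO-8601 first-of-month dates, empty cells for
#' missing values). A `masked` column is written when present and read back
#' if found.
#'
#' @param path file path.
#' @return `read_site_csv()` a `site_series` (the file must contain a single
#'   site); `write_site_csv()` the path, invisibly.
#' @export
read_site_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "pft", "date", "gpp", "evi", "lst", "prc", "rad",
            "snow_flag")
  if (!all(need %in% names(d))) {
    tg_abort("CSV is missing required site-series columns.",
             "tggpp_error_invalid_input")
  }
  if (length(unique(d$site_id)) != 1L) {
    tg_abort("file contains more than one site_id.",
             "tggpp_error_invalid_input")
  }
  site_series(
    date = as.Date(d$date), gpp = d$gpp, evi = d$evi, lst = d$lst,
    prc = d$prc, rad = d$rad, snow_flag = as.logical(d$snow_flag),
    site_id = d$site_id[1], pft = d$pft[1],
    masked = if ("masked" %in% names(d)) as.logical(d$masked) else NULL
  )
}

#' @rdname read_site_csv
#' @param x a `site_series`.
#' @param keep_mask write the `masked` column too (default TRUE when any
#'   month is masked).
#' @export
write_site_csv <- function(x, path, keep_mask = any(x$masked)) {
  stopifnot(inherits(x, "site_series"))
  d <- data.frame(site_id = site_id(x), pft = site_pft(x),
                  date = format(x$date), x[setdiff(names(x), c("date", "masked"))],
                  check.names = FALSE)
  if (keep_mask) d$masked <- x$masked
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
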