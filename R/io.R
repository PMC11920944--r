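# Reading and writing the plain-text interchange formats: AmeriFlux-style
# half-hourly flux CSV (-9999 = missing), 8-day LAI CSV, tidy parameter CSV.

parse_ameriflux_timestamp <- function(ts) {
  if (inherits(ts, "POSIXct")) return(ts)  # readr already parsed ISO 8601
  if (inherits(ts, "Date")) return(as.POSIXct(ts, tz = "UTC"))
  ts <- as.character(ts)
  if (all(grepl("^\\d{12}$", ts))) {
    as.POSIXct(ts, format = "%Y%m%d%H%M", tz = "UTC")
  } else {
    as.POSIXct(ts, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  }
}

#' Read an AmeriFlux-style half-hourly flux CSV
#'
#' Expects columns `TIMESTAMP_START` (ISO 8601 or `YYYYMMDDHHMM`), `NEE`
#' (umol CO2 m-2 s-1), `SW_IN` (W m-2), `TA` (degC), with `-9999` as the
#' missing code. Feb 29 records are dropped (the pipeline runs on a 365-day
#' calendar) and the time axis is expressed in days since Jan 1 of the first
#' year.
#'
#' @param path CSV file path.
#' @return A flux tibble: `time, year, doy, hod, nee, rg, tair, qc`.
#' @export
read_fluxes <- function(path) {
  raw <- readr::read_csv(path, na = c("-9999", "-9999.0", "NA", ""),
                         show_col_types = FALSE)
  need <- c("TIMESTAMP_START", "NEE", "SW_IN", "TA")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("flux CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  ts <- parse_ameriflux_timestamp(raw$TIMESTAMP_START)
  doy <- noleap_doy(as.Date(ts, tz = "UTC"))
  keep <- !is.na(doy)  # drop Feb 29
  raw <- raw[keep, ]; ts <- ts[keep]; doy <- doy[keep]
  year <- as.integer(format(ts, "%Y"))
  hod <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  tibble::tibble(
    time = (year - min(year)) * 365 + doy - 1 + hod / 24,
    year = year, doy = doy, hod = hod,
    nee = raw$NEE, rg = raw$SW_IN, tair = raw$TA,
    qc = ifelse(is.na(raw$NEE), "missing", "ok"))
}

#' Write a flux series as AmeriFlux-style CSV
#'
#' @param series Flux tibble with `year, doy, hod, nee, rg, tair`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(series, path) {
  check_flux(series, c("year", "doy", "hod", "nee", "rg", "tair"))
  date <- noleap_date(series$year, series$doy)
  out <- data.frame(
    TIMESTAMP_START = paste0(format(date, "%Y%m%d"),
                             sprintf("%02d%02d", floor(series$hod),
                                     round((series$hod %% 1) * 60))),
    NEE = ifelse(is.na(series$nee), -9999, series$nee),
    SW_IN = ifelse(is.na(series$rg), -9999, series$rg),
    TA = ifelse(is.na(series$tair), -9999, series$tair))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an 8-day LAI CSV
#'
#' Expects columns `date`, `lai`, optionally `pixel_id` and a logical
#' `qa_pass` screen flag. Feb 29 never occurs on the 8-day grid of a
#' 365-day calendar; if present it is dropped.
#'
#' @param path CSV file path.
#' @return Tibble `year, doy, date, lai` (plus `pixel_id`, `qa_pass` when
#'   present).
#' @export
read_lai_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("date", "lai") %in% names(raw)))
    stop("LAI CSV needs columns: date, lai")
  date <- as.Date(raw$date)
  doy <- noleap_doy(date)
  keep <- !is.na(doy)
  out <- tibble::tibble(year = as.integer(format(date[keep], "%Y")),
                        doy = doy[keep], date = date[keep],
                        lai = raw$lai[keep])
  for (extra in intersect(c("pixel_id", "qa_pass"), names(raw)))
    out[[extra]] <- raw[[extra]][keep]
  out
}

#' Write a tidy per-period parameter table as CSV
#'
#' @param params Tidy table from [tidy_params()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}
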