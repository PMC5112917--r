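#' Read a per-bird feather isotope table
#'
#' Ingests a CSV of individual feather isotope measurements: one row per
#' bird, with collection-site coordinates, a state label, the collection
#' season, and delta values in permil (d2H on the VSMOW-SLAP scale, d13C on
#' VPDB, d15N on AIR). Rows violating physical plausibility bounds
#' (latitude outside [-90, 90], longitude outside [-180, 180], d2H outside
#' [-200, 0], d13C outside [-40, 0], d15N outside [-5, 25]) are retained but
#' reported, with their row numbers, in the `problems` attribute — they are
#' never silently dropped.
#'
#' @param path Path to a CSV file with header `bird_id, site_id, lat, lon,
#'   state, season, d2h, d13c, d15n` (`site_id`, `d13c`, `d15n` optional).
#' @return A tibble of feather samples with attribute `problems`, a tibble
#'   of `(row, column, value, message)` describing rows that failed a bound.
#' @export
read_feather_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("bird_id", "lat", "lon", "state", "season", "d2h")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("Missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"site_id" %in% names(raw)) raw$site_id <- NA_character_
  if (!"d13c" %in% names(raw)) raw$d13c <- NA_real_
  if (!"d15n" %in% names(raw)) raw$d15n <- NA_real_

  num_cols <- c("lat", "lon", "d2h", "d13c", "d15n")
  problems <- list()
  for (cc in num_cols) {
    v <- raw[[cc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop("Unparseable numeric value(s) in column '", cc, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      raw[[cc]] <- conv
    }
  }

  bounds <- list(
    lat = c(-90, 90), lon = c(-180, 180),
    d2h = c(-200, 0), d13c = c(-40, 0), d15n = c(-5, 25)
  )
  for (cc in names(bounds)) {
    b <- bounds[[cc]]
    v <- raw[[cc]]
    bad <- which(!is.na(v) & (v < b[1] | v > b[2]))
    if (length(bad)) {
      problems[[cc]] <- tibble::tibble(
        row = bad, column = cc, value = v[bad],
        message = sprintf("%s outside [%g, %g]", cc, b[1], b[2])
      )
    }
  }
  problems <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(row = integer(), column = character(),
                   value = double(), message = character())

  out <- tibble::as_tibble(raw)[, c("bird_id", "site_id", "lat", "lon",
                                    "state", "season", "d2h", "d13c",
                                    "d15n")]
  out$season <- tolower(out$season)
  bad_season <- which(!out$season %in% c("spring", "winter") &
                        !is.na(out$season))
  if (length(bad_season)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      row = bad_season, column = "season",
      value = NA_real_, message = "season not 'spring' or 'winter'"
    ))
  }
  attr(out, "problems") <- dplyr::arrange(problems, .data$row)
  out
}

#' Site-level d2H calibration summaries (51 blackbird collection sites)
#'
#' The published site-level calibration table used to rescale a growing
#' season precipitation d2H isoscape into a feather d2H isoscape for
#' red-winged blackbirds: for each of 51 known-origin collection sites, the
#' site coordinates, the number of birds sampled, the site mean and SD of
#' feather d2H, and the predicted mean and SD of precipitation d2H at the
#' site. All delta values in permil.
#'
#' Rows 36-51 of the printed table carry precipitation means (-19 to -26
#' permil) that are grossly inconsistent with the latitudinal gradient of
#' the remaining rows and with their own tiny SDs; they appear to be a
#' typesetting/column error in the source table. [flag_inconsistent_sites()]
#' identifies them from the data alone; this loader returns the table as
#' printed.
#'
#' @return A tibble with columns `site_id`, `lat`, `lon`, `n`, `f_mean`,
#'   `f_sd`, `p_mean`, `p_sd`.
#' @seealso [flag_inconsistent_sites()], [fit_rescaling_bootstrap()]
#' @export
calibration_sites <- function() {
  path <- system.file("extdata", "calibration_sites.csv",
                      package = "moltrace", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Flag calibration sites inconsistent with the regional isotopic gradient
#'
#' Precipitation d2H over a continental study area follows a strong, smooth
#' latitude/longitude trend. This screen fits a high-breakdown least
#' trimmed squares (LTS) regression of the site precipitation d2H mean on
#' latitude and longitude and flags sites whose absolute robust residual
#' exceeds `threshold` robust scale units. It is intended for detecting
#' transcription or column errors in printed calibration tables; the
#' decision is driven entirely by internal consistency of the table, not by
#' any external target.
#'
#' @param sites A tibble of site summaries (needs `lat`, `lon`, `p_mean`).
#' @param threshold Robust-residual cutoff in scale units (default 4).
#' @return `sites` with an added logical column `consistent`.
#' @export
flag_inconsistent_sites <- function(sites, threshold = 4) {
  stopifnot(all(c("lat", "lon", "p_mean") %in% names(sites)))
  # lqs() subsamples internally; fix its stream locally for reproducibility
  fit <- local_seed(20231L, MASS::lqs(p_mean ~ lat + lon, data = sites,
                                      method = "lts"))
  r <- sites$p_mean - stats::predict(fit, sites)
  scale <- fit$scale[2]
  dplyr::mutate(sites, consistent = abs(r) <= threshold * scale)
}
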