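#' Simulation configuration for the synthetic study system
#'
#' Bundles every parameter of the synthetic data generator: the geographic
#' extent and resolution of the precipitation d2H isoscape, its smooth
#' latitude/longitude trend and spatially correlated noise, the affine
#' precipitation-to-feather calibration, between-individual feather
#' variation, and the C3/C4 diet and d15N models. Defaults mirror the
#' magnitudes observed in North American blackbird feathers: a growing
#' season precipitation d2H surface spanning roughly -20 permil in the
#' southeast to -101 permil in the northwest of the calibration transect,
#' a feather calibration of intercept -37.45 permil and slope 0.86,
#' between-individual SD 8.4 permil, C3/C4 feather d13C endpoints of -27
#' and -12 permil, and feather d15N centred on 10 permil with an optional
#' +2 permil shift for sites flagged as arid.
#'
#' @param seed Integer seed; every generator is deterministic given the
#'   config.
#' @param extent `c(lat_min, lat_max, lon_min, lon_max)` in decimal
#'   degrees. The default covers the blackbird calibration transect.
#' @param cell_size Grid resolution in decimal degrees.
#' @param gradient Named vector `c(intercept, lat, lon)`: the linear trend
#'   of precipitation d2H (permil) on latitude and longitude.
#' @param noise_sd SD (permil) of the spatially correlated field added to
#'   the trend.
#' @param noise_range_km Correlation range (km) of that field.
#' @param calib_intercept,calib_slope Affine map from precipitation d2H to
#'   expected feather d2H (permil; slope dimensionless, nonzero).
#' @param sigma_ind Between-individual feather d2H SD (permil).
#' @param isoscape_sd_range Range (permil) from which per-pixel isoscape
#'   prediction SDs are drawn uniformly.
#' @param c3_endpoint,c4_endpoint Feather d13C (permil) of a pure C3 and a
#'   pure C4 diet; must differ by at least 5 permil.
#' @param diet_alpha,diet_beta Beta-distribution shape parameters for each
#'   individual's C4 diet fraction.
#' @param diet_resid_sd Residual SD (permil) of feather d13C around the
#'   mixing line.
#' @param d15n_mean,d15n_sd Mean and SD (permil) of feather d15N.
#' @param arid_shift Additive d15N shift (permil) applied at sites flagged
#'   arid (the arid-region enrichment pattern); sites are non-arid unless
#'   flagged, so the shift is off by default.
#' @param crop_c4_range Range of the per-site proportion of county area
#'   planted to C4 crops; the proportion increases with longitude when
#'   `crop_lon_slope > 0`.
#' @param crop_lon_slope Logistic slope (per degree longitude) of the C4
#'   crop proportion.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       extent = c(29.5, 52.0, -109.5, -88.0),
                       cell_size = 0.2,
                       gradient = c(intercept = 172, lat = -2.4, lon = 1.35),
                       noise_sd = 3,
                       noise_range_km = 300,
                       calib_intercept = -37.45,
                       calib_slope = 0.86,
                       sigma_ind = 8.4,
                       isoscape_sd_range = c(9, 11.3),
                       c3_endpoint = -27,
                       c4_endpoint = -12,
                       diet_alpha = 2,
                       diet_beta = 2,
                       diet_resid_sd = 1,
                       d15n_mean = 10,
                       d15n_sd = 1.5,
                       arid_shift = 2,
                       crop_c4_range = c(0.05, 0.8),
                       crop_lon_slope = 0.3) {
  stopifnot(length(extent) == 4)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("Degenerate extent.", call. = FALSE)
  }
  if (calib_slope == 0) stop("`calib_slope` must be nonzero.", call. = FALSE)
  if (abs(c4_endpoint - c3_endpoint) < 5) {
    stop("Diet endpoints must differ by at least 5 permil.", call. = FALSE)
  }
  sds <- c(noise_sd, sigma_ind, diet_resid_sd, d15n_sd, isoscape_sd_range)
  if (any(sds < 0)) stop("SD parameters must be nonnegative.", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# Approximate zero-mean Gaussian random field with exponential-type
# correlation, by FFT convolution of white noise with an exponential kernel
# on a padded grid. Approximate by design: only smoothness and a
# controllable range matter to the generator's contract.
random_field <- function(nr, nc, range_cells) {
  if (range_cells <= 0) return(matrix(stats::rnorm(nr * nc), nr, nc))
  pr <- stats::nextn(nr + 4 * ceiling(range_cells), 2)
  pc <- stats::nextn(nc + 4 * ceiling(range_cells), 2)
  z <- matrix(stats::rnorm(pr * pc), pr, pc)
  di <- pmin(0:(pr - 1), pr - 0:(pr - 1))
  dj <- pmin(0:(pc - 1), pc - 0:(pc - 1))
  d <- sqrt(outer(di^2, dj^2, "+"))
  k <- exp(-d / range_cells)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE))
  f <- f[seq_len(nr), seq_len(nc)]
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic precipitation d2H isoscape
#'
#' The mean surface is the configured linear latitude/longitude trend plus
#' a spatially correlated Gaussian field; the companion SD surface is drawn
#' uniformly from `isoscape_sd_range`, mimicking the per-pixel prediction
#' errors a published isoscape ships with.
#'
#' @param config A [sim_config()].
#' @return A list with `mean` and `sd`, both [iso_grid()] objects.
#' @export
make_precip_isoscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tmpl <- grid_template(config$extent, config$cell_size)
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  lats <- grid_lats(tmpl); lons <- grid_lons(tmpl)
  g <- config$gradient
  trend <- outer(lats, lons, function(la, lo) {
    g[["intercept"]] + g[["lat"]] * la + g[["lon"]] * lo
  })
  local_seed(config$seed, {
    range_cells <- config$noise_range_km / (config$cell_size * 111)
    noise <- if (config$noise_sd > 0) {
      config$noise_sd * random_field(nr, nc, range_cells)
    } else {
      matrix(0, nr, nc)
    }
    sd_vals <- matrix(
      stats::runif(nr * nc, config$isoscape_sd_range[1],
                   config$isoscape_sd_range[2]), nr, nc)
    list(
      mean = iso_grid(trend + noise, tmpl$origin_lon, tmpl$origin_lat,
                      config$cell_size),
      sd = iso_grid(sd_vals, tmpl$origin_lon, tmpl$origin_lat,
                    config$cell_size)
    )
  })
}

#' Sample spatially separated collection sites
#'
#' Draws site locations uniformly over the configured extent, enforcing a
#' minimum pairwise great-circle separation (collection sites in field
#' studies are deliberately spaced, typically by at least 5 km, to keep
#' sites statistically independent). Sites are labelled with a state-like
#' group formed from latitude bands, and carry an `arid` flag (all `FALSE`;
#' flip it to engage the d15N arid shift).
#'
#' @param config A [sim_config()].
#' @param n_sites Number of sites.
#' @param min_separation_km Minimum pairwise great-circle distance (km).
#' @param n_states Number of latitude-band state labels.
#' @return A tibble with `site_id`, `lat`, `lon`, `state`, `arid`.
#' @export
sample_sites <- function(config, n_sites, min_separation_km = 5,
                         n_states = 3) {
  stopifnot(inherits(config, "sim_config"), n_sites >= 1)
  ex <- config$extent
  local_seed(config$seed + 1L, {
    pts <- matrix(NA_real_, n_sites, 2)
    accepted <- 0L
    tries <- 0L
    max_tries <- 500L * n_sites
    while (accepted < n_sites && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, ex[1], ex[2]), stats::runif(1, ex[3], ex[4]))
      ok <- TRUE
      if (accepted > 0L && min_separation_km > 0) {
        d <- dist_km(list(lat = cand[1], lon = cand[2]),
                     list(lat = pts[seq_len(accepted), 1],
                          lon = pts[seq_len(accepted), 2]))
        ok <- all(d >= min_separation_km)
      }
      if (ok) {
        accepted <- accepted + 1L
        pts[accepted, ] <- cand
      }
    }
    if (accepted < n_sites) {
      stop("Could not place ", n_sites, " sites with ", min_separation_km,
           " km separation after ", max_tries, " proposals.", call. = FALSE)
    }
    band <- cut(pts[, 1], breaks = seq(ex[1], ex[2], length.out = n_states + 1),
                labels = paste0("S", seq_len(n_states)),
                include.lowest = TRUE)
    tibble::tibble(
      site_id = sprintf("site_%02d", seq_len(n_sites)),
      lat = pts[, 1], lon = pts[, 2],
      state = as.character(band),
      arid = FALSE
    )
  })
}

#' Simulate per-bird feather isotope values at sites
#'
#' The generative model the whole pipeline assumes: feather d2H is an
#' affine function of precipitation d2H at the site plus independent
#' between-individual noise; feather d13C is a two-endpoint C3/C4 mixture
#' with an individual C4 diet fraction drawn from a Beta distribution;
#' feather d15N is Gaussian, shifted upward at arid-flagged sites.
#'
#' @param config A [sim_config()].
#' @param sites A site tibble from [sample_sites()] (or with the same
#'   columns).
#' @param n_per_site Birds per site (scalar or vector of length
#'   `nrow(sites)`).
#' @param precip Optional precipitation mean [iso_grid()]; defaults to the
#'   one generated from `config`, so a given config is self-consistent.
#' @param season Season label stamped on the records.
#' @return A tibble of feather samples (`bird_id`, `site_id`, `lat`, `lon`,
#'   `state`, `season`, `d2h`, `d13c`, `d15n`, plus the site's true
#'   precipitation value `p_true` and diet fraction `c4_frac` for use as
#'   generator truth in tests).
#' @export
simulate_feathers <- function(config, sites, n_per_site = 8,
                              precip = NULL, season = "spring") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(precip)) precip <- make_precip_isoscape(config)$mean
  ext <- extract_at_points(precip, sites)
  if (any(ext$flag != "ok")) {
    stop("Site(s) outside the precipitation grid or on nodata cells: ",
         paste(which(ext$flag != "ok"), collapse = ", "), call. = FALSE)
  }
  n_per_site <- rep_len(n_per_site, nrow(sites))
  local_seed(config$seed + 2L, {
    rows <- purrr::map(seq_len(nrow(sites)), function(i) {
      n <- n_per_site[i]
      p <- ext$value[i]
      d2h <- config$calib_intercept + config$calib_slope * p +
        stats::rnorm(n, 0, config$sigma_ind)
      frac <- stats::rbeta(n, config$diet_alpha, config$diet_beta)
      d13c <- frac * config$c4_endpoint + (1 - frac) * config$c3_endpoint +
        stats::rnorm(n, 0, config$diet_resid_sd)
      d15n <- stats::rnorm(n, config$d15n_mean, config$d15n_sd) +
        if (isTRUE(sites$arid[i])) config$arid_shift else 0
      tibble::tibble(
        bird_id = sprintf("%s_b%02d", sites$site_id[i], seq_len(n)),
        site_id = sites$site_id[i],
        lat = sites$lat[i], lon = sites$lon[i],
        state = sites$state[i], season = season,
        d2h = d2h, d13c = d13c, d15n = d15n,
        p_true = p, c4_frac = frac
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate per-site C3/C4 crop cover proportions
#'
#' Emulates county-level planted-crop statistics: the proportion of the
#' area planted to C4 crops follows a smooth logistic trend in longitude
#' (sign and steepness set by `crop_lon_slope`), the C3 proportion fills
#' part of the remainder, and the two always satisfy `prop_c3, prop_c4 >= 0`
#' and `prop_c3 + prop_c4 <= 1`.
#'
#' @param sites A site tibble.
#' @param config A [sim_config()].
#' @return `sites` with added `prop_c3` and `prop_c4` columns.
#' @export
simulate_crop_covariates <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$extent
  lon_mid <- (ex[3] + ex[4]) / 2
  rng <- config$crop_c4_range
  local_seed(config$seed + 3L, {
    f <- stats::plogis(config$crop_lon_slope * (sites$lon - lon_mid) +
                         stats::rnorm(nrow(sites), 0, 0.15))
    prop_c4 <- rng[1] + (rng[2] - rng[1]) * f
    c3_share <- 0.6 * stats::plogis(-config$crop_lon_slope *
                                      (sites$lon - lon_mid))
    prop_c3 <- (1 - prop_c4) * c3_share
    dplyr::mutate(sites, prop_c3 = prop_c3, prop_c4 = prop_c4)
  })
}
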