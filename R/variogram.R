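#' Empirical (sample) semivariogram
#'
#' Bins point pairs by great-circle separation and computes the Matheron
#' estimator per lag: `gamma(h) = (1 / (2 N(h))) * sum (z_i - z_j)^2` over
#' the `N(h)` pairs in the bin. Directional variograms restrict pairs to
#' those whose initial bearing falls within `tolerance` degrees of the
#' given azimuth (modulo 180).
#'
#' @param points Data frame with `lat`, `lon` (decimal degrees).
#' @param values Numeric vector, one value per point (permil).
#' @param lag_km Width of each lag bin (km).
#' @param n_lags Number of lag bins.
#' @param direction `NULL` for isotropic, or `c(azimuth, tolerance)` in
#'   degrees for a directional variogram.
#' @return A tibble of class `empirical_variogram` with `lag` (bin centre,
#'   km), `gamma` (permil^2) and `np` (pair count); empty bins omitted.
#' @export
empirical_variogram <- function(points, values, lag_km = 80.6, n_lags = 12,
                                direction = NULL) {
  stopifnot(nrow(points) >= 2, length(values) == nrow(points))
  D <- dist_km(points)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  keep <- d <= lag_km * n_lags
  if (!is.null(direction)) {
    br <- geosphere::bearing(cbind(points$lon[iu[, 1]], points$lat[iu[, 1]]),
                             cbind(points$lon[iu[, 2]], points$lat[iu[, 2]]))
    diff <- abs(((br - direction[1]) + 90) %% 180 - 90)
    keep <- keep & diff <= direction[2]
  }
  if (!any(keep)) {
    stop("No point pairs within the maximum lag distance.", call. = FALSE)
  }
  d <- d[keep]
  sq <- (values[iu[keep, 1]] - values[iu[keep, 2]])^2
  bin <- pmin(pmax(ceiling(d / lag_km), 1L), n_lags)
  gamma <- tapply(sq, bin, function(x) sum(x) / (2 * length(x)))
  np <- tapply(sq, bin, length)
  lags <- (as.integer(names(gamma)) - 0.5) * lag_km
  out <- tibble::tibble(lag = lags, gamma = as.numeric(gamma),
                        np = as.integer(np))
  class(out) <- c("empirical_variogram", class(out))
  attr(out, "lag_km") <- lag_km
  attr(out, "direction") <- direction
  out
}

#' Evaluate a variogram model
#'
#' The stable model is
#' `gamma(h) = nugget + psill * (1 - exp(-3 (h / range)^shape))` with shape
#' in (0, 2]; `range` is the *effective* range (the factor 3 puts gamma at
#' ~95% of the sill at `h = range`). The Gaussian model is the stable model
#' with shape fixed at 2. `gamma(0) = 0` by convention (the nugget is a
#' discontinuity at the origin), which makes kriging exact at data
#' locations.
#'
#' @param model A `variogram_model`.
#' @param h Distances (km).
#' @return Semivariance values (permil^2).
#' @export
vgm_gamma <- function(model, h) {
  g <- model$nugget + model$psill *
    (1 - exp(-3 * (h / model$range_km)^model$shape))
  g[h == 0] <- 0
  g
}

#' Construct a variogram model
#'
#' @param kind `"stable"` or `"gaussian"` (shape fixed at 2).
#' @param nugget,psill Nugget and partial sill (permil^2).
#' @param range_km Effective range (km).
#' @param shape Stable-model shape exponent in (0, 2].
#' @param anisotropy `NULL`, or `c(azimuth, ratio)`: geometric anisotropy
#'   with the major axis at `azimuth` degrees and minor-axis range shorter
#'   by `ratio`.
#' @return A list of class `variogram_model`.
#' @export
variogram_model <- function(kind = c("stable", "gaussian"), nugget, psill,
                            range_km, shape = 1, anisotropy = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") shape <- 2
  stopifnot(nugget >= 0, psill >= 0, range_km > 0, shape > 0, shape <= 2)
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range_km = range_km, shape = shape,
                 anisotropy = anisotropy),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model> %s: nugget %.2f, partial sill %.2f, range %.1f km, shape %.2f\n",
    x$kind, x$nugget, x$psill, x$range_km, x$shape))
  if (!is.null(x$anisotropy)) {
    cat(sprintf("  anisotropy: azimuth %g deg, ratio %g\n",
                x$anisotropy[1], x$anisotropy[2]))
  }
  invisible(x)
}

#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "psill", "range_km", "shape"),
    estimate = c(x$nugget, x$psill, x$range_km, x$shape)
  )
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares with Cressie-style weights
#' (`np / gamma_model^2`), minimised by a bounded quasi-Newton optimiser
#' from multiple starting points. The Gaussian model fixes the shape at 2;
#' the stable model estimates it in (0.1, 2].
#'
#' @param ev An [empirical_variogram()].
#' @param kind `"stable"` or `"gaussian"`.
#' @param anisotropy Passed through to the returned model (the fit itself
#'   operates on the supplied, possibly directional, empirical variogram).
#' @return A `variogram_model`.
#' @export
fit_variogram <- function(ev, kind = c("stable", "gaussian"),
                          anisotropy = NULL) {
  kind <- match.arg(kind)
  if (nrow(ev) < 3) stop("Need at least 3 usable lags.", call. = FALSE)
  h <- ev$lag; g <- ev$gamma; np <- ev$np
  sill0 <- max(g)
  obj <- function(par) {
    m <- list(nugget = par[1], psill = par[2], range_km = par[3],
              shape = if (kind == "gaussian") 2 else par[4])
    gm <- m$nugget + m$psill * (1 - exp(-3 * (h / m$range_km)^m$shape))
    gm <- pmax(gm, 1e-10)
    sum(np * (g - gm)^2 / gm^2)
  }
  n_par <- if (kind == "gaussian") 3L else 4L
  lower <- c(0, 0, max(h) / 50, 0.1)[seq_len(n_par)]
  upper <- c(sill0 * 2 + 1e-6, sill0 * 3 + 1e-6, max(h) * 10, 2)[seq_len(n_par)]
  starts <- list(
    c(0, sill0, max(h) / 2, 1),
    c(sill0 / 4, sill0, max(h), 1.5),
    c(sill0 / 2, sill0 / 2, max(h) / 4, 0.8),
    c(0, sill0, max(h) * 2, 2)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s[seq_len(n_par)], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("Variogram fit failed to converge from any starting point.",
         call. = FALSE)
  }
  p <- best$par
  variogram_model(kind, nugget = p[1], psill = p[2], range_km = p[3],
                  shape = if (kind == "gaussian") 2 else p[4],
                  anisotropy = anisotropy)
}

#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$np), alpha = 0.7) +
    ggplot2::labs(x = "separation (km)",
                  y = expression(gamma ~ ("‰"^2)), size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    hh <- seq(0.01, max(object$lag), length.out = 200)
    curve <- tibble::tibble(lag = hh, gamma = vgm_gamma(model, hh))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}
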