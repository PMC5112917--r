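#' Bootstrap calibration of the precipitation-to-feather rescaling function
#'
#' Estimates the affine rescaling from growing-season precipitation d2H to
#' feather d2H by bootstrap regression over site-level summaries, with the
#' sampling error of both variables propagated into the coefficient
#' uncertainty. For each of `n_boot` replicates, every site contributes a
#' simulated feather site mean drawn from `N(f_mean, f_sd / sqrt(n))` and a
#' simulated precipitation value drawn from `N(p_mean, p_sd)`; an unweighted
#' ordinary least squares regression of feather on precipitation across
#' sites yields one (intercept, slope) draw. The reported coefficients are
#' the means of the draws and the reported SDs are the SDs of the draws.
#'
#' Sites with a missing SD (typically single-bird sites) have it replaced
#' by the mean SD of the remaining sites (`missing_sd = "substitute"`, the
#' default) or are excluded (`missing_sd = "drop"`). A per-bird variant of
#' the feather draw (`site_mean_se = FALSE`) draws `n` individual birds
#' `~ N(f_mean, f_sd)` and averages them, which is distributionally the
#' same mean but makes the resampling explicit.
#'
#' @param sites Tibble of site summaries with columns `lat`, `lon`, `n`,
#'   `f_mean`, `f_sd`, `p_mean`, `p_sd` (see [calibration_sites()]).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for reproducibility.
#' @param site_mean_se Draw site means with SE `f_sd/sqrt(n)` (default) or
#'   per-bird then average.
#' @param missing_sd `"substitute"` (mean SD of other sites) or `"drop"`.
#' @return An object of class `rescaling_fn`: intercept/slope (permil /
#'   dimensionless), their bootstrap SDs, `n_boot`, `n_sites`, and the full
#'   tibble of per-replicate `draws`.
#' @export
fit_rescaling_bootstrap <- function(sites, n_boot = 1000, seed = NULL,
                                    site_mean_se = TRUE,
                                    missing_sd = c("substitute", "drop")) {
  missing_sd <- match.arg(missing_sd)
  need <- c("n", "f_mean", "f_sd", "p_mean", "p_sd")
  stopifnot(all(need %in% names(sites)))
  d <- sites[is.finite(sites$f_mean) & is.finite(sites$p_mean), ]
  if (missing_sd == "drop") {
    d <- d[is.finite(d$f_sd) & is.finite(d$p_sd), ]
  } else {
    d$f_sd[!is.finite(d$f_sd)] <- mean(d$f_sd, na.rm = TRUE)
    d$p_sd[!is.finite(d$p_sd)] <- mean(d$p_sd, na.rm = TRUE)
  }
  if (nrow(d) < 3) stop("Need at least 3 usable sites.", call. = FALSE)

  f_se <- if (site_mean_se) d$f_sd / sqrt(d$n) else d$f_sd
  one_rep <- function() {
    for (try in 1:20) {
      p <- stats::rnorm(nrow(d), d$p_mean, d$p_sd)
      f <- if (site_mean_se) {
        stats::rnorm(nrow(d), d$f_mean, f_se)
      } else {
        vapply(seq_len(nrow(d)), function(i) {
          mean(stats::rnorm(d$n[i], d$f_mean[i], d$f_sd[i]))
        }, numeric(1))
      }
      if (stats::sd(p) > 1e-12) {
        return(stats::lm.fit(cbind(1, p), f)$coefficients)
      }
    }
    stop("Simulated predictor had zero variance in 20 consecutive draws.",
         call. = FALSE)
  }

  run <- function() {
    draws <- vapply(seq_len(n_boot), function(i) one_rep(), numeric(2))
    tibble::tibble(replicate = seq_len(n_boot),
                   intercept = draws[1, ], slope = draws[2, ])
  }
  draws <- if (is.null(seed)) run() else local_seed(seed, run())

  structure(
    list(
      intercept = mean(draws$intercept),
      slope = mean(draws$slope),
      intercept_sd = stats::sd(draws$intercept),
      slope_sd = stats::sd(draws$slope),
      n_boot = n_boot,
      n_sites = nrow(d),
      draws = draws
    ),
    class = "rescaling_fn"
  )
}

#' Construct a rescaling function from known coefficients
#'
#' Useful for applying a published calibration, or for tests: the "draws"
#' are degenerate at the given coefficients so downstream error pooling
#' attributes zero calibration variance.
#'
#' @param intercept,slope Affine coefficients (permil; dimensionless).
#' @return A `rescaling_fn` with a single degenerate draw.
#' @export
rescaling_fn <- function(intercept, slope) {
  structure(
    list(intercept = intercept, slope = slope,
         intercept_sd = 0, slope_sd = 0, n_boot = 1L, n_sites = NA_integer_,
         draws = tibble::tibble(replicate = 1L, intercept = intercept,
                                slope = slope)),
    class = "rescaling_fn"
  )
}

#' @export
print.rescaling_fn <- function(x, ...) {
  cat(sprintf(
    "<rescaling_fn> feather_d2H = %.2f (SD %.2f) + %.3f (SD %.3f) * precip_d2H\n",
    x$intercept, x$intercept_sd, x$slope, x$slope_sd))
  cat("  ", x$n_boot, " bootstrap replicate(s), ", x$n_sites, " sites\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.rescaling_fn <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_sd, x$slope_sd)
  )
}

#' @export
glance.rescaling_fn <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_sites = x$n_sites)
}

#' @export
autoplot.rescaling_fn <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$intercept, y = .data$slope)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(
      data = tibble::tibble(intercept = object$intercept,
                            slope = object$slope),
      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "intercept (‰)", y = "slope",
                  title = "Bootstrap calibration draws") +
    ggplot2::theme_minimal()
}

#' Apply an affine rescaling to a grid
#'
#' Maps every finite cell `v` of a precipitation isoscape to
#' `intercept + slope * v`, producing the corresponding feather isoscape;
#' nodata cells are preserved.
#'
#' @param precip An [iso_grid()].
#' @param rf A `rescaling_fn`.
#' @return An [iso_grid()] of feather values.
#' @export
apply_rescaling <- function(precip, rf) {
  stopifnot(inherits(precip, "iso_grid"), inherits(rf, "rescaling_fn"))
  out <- precip
  out$values <- rf$intercept + rf$slope * precip$values
  out
}

#' Pooled per-pixel prediction SD for likelihood assignment
#'
#' Pools, in quadrature, the three independent error sources of a
#' rescaled feather isoscape: between-individual feather variation
#' (`sigma_ind`), the isoscape's own spatial prediction error (scaled by
#' the rescaling slope, since the rescaling is applied to the predicted
#' precipitation value), and the uncertainty of the calibration itself,
#' evaluated per pixel as the variance across bootstrap draws of
#' `intercept + slope * precip(pixel)`:
#'
#' `pooled(pixel) = sqrt(sigma_ind^2 + (slope * sd_p(pixel))^2 +
#'                        var_draws(intercept + slope * p(pixel)))`
#'
#' The result is never smaller than `sigma_ind`.
#'
#' @param precip Precipitation mean [iso_grid()] (needed to evaluate the
#'   calibration variance per pixel).
#' @param precip_sd Per-pixel SD [iso_grid()] of the precipitation
#'   isoscape, aligned with `precip`.
#' @param rf A `rescaling_fn` whose stored draws carry the calibration
#'   uncertainty.
#' @param sigma_ind Between-individual SD in permil (default 8.4, the mean
#'   of site-level feather SDs in the blackbird calibration table).
#' @return An [iso_grid()] of pooled SDs (permil).
#' @export
pooled_error_surface <- function(precip, precip_sd, rf, sigma_ind = 8.4) {
  stopifnot(inherits(rf, "rescaling_fn"), sigma_ind >= 0)
  stop_if_misaligned(precip, precip_sd, "mean and SD grids")
  p <- as.vector(precip$values)
  a <- rf$draws$intercept; b <- rf$draws$slope
  var_calib <- if (length(a) > 1) {
    # var over draws of (a + b p) = var(a) + p^2 var(b) + 2 p cov(a, b)
    stats::var(a) + p^2 * stats::var(b) + 2 * p * stats::cov(a, b)
  } else {
    rep(0, length(p))
  }
  var_calib <- pmax(var_calib, 0)
  pooled <- sqrt(sigma_ind^2 + (rf$slope * as.vector(precip_sd$values))^2 +
                   var_calib)
  out <- precip
  out$values <- matrix(pooled, nrow(precip$values), ncol(precip$values))
  out
}
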