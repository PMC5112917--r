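# Pairwise distances (km) honouring a model's geometric anisotropy.
# Isotropic models use great-circle (haversine) distance; anisotropic
# models use a local equirectangular projection so the affine distance
# transform is well defined.
model_dist_km <- function(model, a, b = a) {
  if (is.null(model$anisotropy)) {
    return(dist_km(a, b))
  }
  az <- model$anisotropy[1] * pi / 180
  ratio <- model$anisotropy[2]
  mid_lat <- mean(c(a$lat, b$lat)) * pi / 180
  proj <- function(p) {
    x <- p$lon * 111.32 * cos(mid_lat)
    y <- p$lat * 110.57
    # rotate so the major axis lies along the first coordinate
    cbind(x * sin(az) + y * cos(az), -x * cos(az) + y * sin(az))
  }
  pa <- proj(a); pb <- proj(b)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-") * ratio
  sqrt(dx^2 + dy^2)
}

# Average duplicate locations (exact lat/lon ties), warning when found.
collapse_duplicates <- function(points, values) {
  key <- paste(points$lat, points$lon)
  if (!anyDuplicated(key)) {
    return(list(points = points, values = values))
  }
  warning("Duplicate point locations found; values averaged per location.",
          call. = FALSE)
  agg <- tapply(values, key, mean)
  first <- !duplicated(key)
  pts <- points[first, , drop = FALSE]
  list(points = pts, values = as.numeric(agg[paste(pts$lat, pts$lon)]))
}

#' Ordinary kriging onto a grid
#'
#' Solves the ordinary kriging system (semivariogram form, weights
#' constrained to sum to 1 via a Lagrange multiplier) once for the data
#' configuration and applies it to every cell centre of the target grid.
#' With `gamma(0) = 0` the predictor is exact at data locations; the
#' kriging variance is nonnegative and zero there when the nugget is zero.
#'
#' @param points Data frame with `lat`, `lon`.
#' @param values Numeric vector of observations (permil).
#' @param model A [variogram_model()].
#' @param grid_spec An [iso_grid()] used as a template, or a list with
#'   `extent` and `cell_size` (see [grid_template()]).
#' @return A list with `mean` and `sd` [iso_grid()] layers (prediction and
#'   kriging standard error).
#' @export
krige <- function(points, values, model, grid_spec) {
  stopifnot(inherits(model, "variogram_model"), nrow(points) >= 2)
  cd <- collapse_duplicates(points, values)
  points <- cd$points; z <- cd$values
  n <- nrow(points)

  tmpl <- if (inherits(grid_spec, "iso_grid")) grid_spec else
    grid_template(grid_spec$extent, grid_spec$cell_size)
  cells <- tibble::tibble(
    lon = rep(grid_lons(tmpl), each = nrow(tmpl$values)),
    lat = rep(grid_lats(tmpl), times = ncol(tmpl$values))
  )

  G <- vgm_gamma(model, model_dist_km(model, points))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- solve(A)

  D0 <- model_dist_km(model, points, cells)       # n x m
  G0 <- vgm_gamma(model, D0)
  B <- rbind(G0, 1)                               # (n+1) x m
  W <- Ainv %*% B                                 # weights + multiplier
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  kvar <- colSums(W[seq_len(n), , drop = FALSE] * G0) + W[n + 1, ]
  kvar <- pmax(kvar, 0)

  mk <- function(v) iso_grid(matrix(v, nrow(tmpl$values), ncol(tmpl$values)),
                             tmpl$origin_lon, tmpl$origin_lat,
                             tmpl$cell_size)
  list(mean = mk(pred), sd = mk(sqrt(kvar)))
}

# Ordinary kriging prediction at arbitrary points (used for LOO and the
# residual surface); returns a tibble of predictions and kriging SDs.
krige_at_points <- function(points, values, model, new_points) {
  cd <- collapse_duplicates(points, values)
  points <- cd$points; z <- cd$values
  n <- nrow(points)
  G <- vgm_gamma(model, model_dist_km(model, points))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- solve(A)
  G0 <- vgm_gamma(model, model_dist_km(model, points, new_points))
  B <- rbind(G0, 1)
  W <- Ainv %*% B
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  kvar <- pmax(colSums(W[seq_len(n), , drop = FALSE] * G0) + W[n + 1, ], 0)
  tibble::tibble(pred = pred, sd = sqrt(kvar))
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Predicts each observation from all the others under the given variogram
#' model and reports the root-mean-squared error.
#'
#' @inheritParams krige
#' @return A list with `rmse` (permil) and `residuals`, a tibble of
#'   per-point observed, predicted and residual values.
#' @export
loo_cross_validate <- function(points, values, model) {
  stopifnot(nrow(points) >= 3)
  preds <- vapply(seq_len(nrow(points)), function(i) {
    krige_at_points(points[-i, , drop = FALSE], values[-i], model,
                    points[i, , drop = FALSE])$pred
  }, numeric(1))
  res <- values - preds
  list(
    rmse = sqrt(mean(res^2)),
    residuals = tibble::tibble(lat = points$lat, lon = points$lon,
                               observed = values, predicted = preds,
                               residual = res)
  )
}

#' Compare candidate isoscapes against holdout samples
#'
#' For each candidate surface, regresses observed holdout feather d2H on
#' the surface's predicted value at the holdout locations (OLS), computes
#' the small-sample AICc (`n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with k = 3:
#' intercept, slope, residual variance), and converts AICc differences to
#' Akaike weights. A well-calibrated surface has validation slope near 1
#' and intercept near 0; 85% confidence intervals for both are reported
#' alongside R-squared.
#'
#' @param surfaces A named list of [iso_grid()] candidate surfaces.
#' @param holdout A tibble of holdout samples with `lat`, `lon`, `d2h`.
#' @return A tibble of class `surface_comparison` (one row per surface:
#'   `surface`, `n`, `aicc`, `delta_aicc`, `weight`, `intercept`, `slope`,
#'   CI bounds, `r_squared`) with attribute `chosen`, the name of the
#'   highest-weight surface.
#' @export
compare_surfaces_by_validation <- function(surfaces, holdout) {
  stopifnot(length(surfaces) >= 2, nrow(holdout) >= 1)
  if (is.null(names(surfaces))) {
    names(surfaces) <- paste0("surface_", seq_along(surfaces))
  }
  rows <- purrr::imap(surfaces, function(surf, nm) {
    ex <- extract_at_points(surf, holdout)
    ok <- ex$flag == "ok" & is.finite(holdout$d2h)
    if (any(!ok)) {
      warning(sum(!ok), " holdout point(s) outside surface '", nm,
              "' excluded.", call. = FALSE)
    }
    obs <- holdout$d2h[ok]; prd <- ex$value[ok]
    n <- length(obs)
    fit <- stats::lm(obs ~ prd)
    rss <- sum(stats::residuals(fit)^2)
    cf <- summary(fit)$coefficients
    tq <- stats::qt(0.925, df = n - 2)
    tibble::tibble(
      surface = nm, n = n,
      aicc = aicc_from_rss(n, rss, k = 3),
      intercept = cf[1, 1], intercept_lo85 = cf[1, 1] - tq * cf[1, 2],
      intercept_hi85 = cf[1, 1] + tq * cf[1, 2],
      slope = cf[2, 1], slope_lo85 = cf[2, 1] - tq * cf[2, 2],
      slope_hi85 = cf[2, 1] + tq * cf[2, 2],
      r_squared = summary(fit)$r.squared
    )
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- akaike_weights(out$aicc)
  out <- dplyr::relocate(out, "delta_aicc", "weight", .after = "aicc")
  class(out) <- c("surface_comparison", class(out))
  attr(out, "chosen") <- out$surface[which.max(out$weight)]
  out
}
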