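#' Candidate-model selection for the feather d13C regression isoscape
#'
#' Fits the four competing ordinary least squares models of feather d13C on
#' feather d2H and the county proportion of C4 crops — each main effect
#' alone, both additively, and both plus their interaction — ranks them by
#' small-sample AICc, and applies an 85% confidence-interval screen: the
#' chosen model is the least-parameterized member of the confidence set
#' (delta AICc <= 2) all of whose non-intercept coefficients have 85% CIs
#' excluding zero. A model is additionally dropped as carrying a
#' "pretending parameter" when its extra coefficient's 85% CI covers zero
#' and its delta AICc to the nested model is below 2 (the extra parameter
#' buys no fit). If no candidate passes the screen, the selection falls
#' back to the lowest-AICc model with a warning.
#'
#' @param samples Tibble with columns `d13c`, `d2h` and `prop_c4` (the
#'   latter typically in percent or proportion; used as given).
#' @return An object of class `candidate_set`: a tibble of per-model
#'   statistics with attributes `chosen` (model name) and `fits` (the lm
#'   objects).
#' @export
fit_candidates <- function(samples) {
  need <- c("d13c", "d2h", "prop_c4")
  stopifnot(all(need %in% names(samples)))
  d <- samples[stats::complete.cases(samples[, need]), need]
  if (nrow(d) < 10) stop("Need at least 10 complete samples.", call. = FALSE)
  if (abs(stats::cor(d$d2h, d$prop_c4)) > 0.99) {
    stop("Covariates d2h and prop_c4 are collinear (|r| > 0.99).",
         call. = FALSE)
  }
  forms <- list(
    d2h          = d13c ~ d2h,
    prop_c4      = d13c ~ prop_c4,
    additive     = d13c ~ d2h + prop_c4,
    interaction  = d13c ~ d2h * prop_c4
  )
  fits <- purrr::map(forms, ~ stats::lm(.x, data = d))
  n <- nrow(d)
  stats_tbl <- purrr::imap(fits, function(f, nm) {
    k <- length(stats::coef(f)) + 1  # + residual variance
    rss <- sum(stats::residuals(f)^2)
    cf <- summary(f)$coefficients
    tq <- stats::qt(0.925, df = f$df.residual)
    slopes <- cf[-1, , drop = FALSE]
    pass <- all(abs(slopes[, 1]) - tq * slopes[, 2] > 0)
    tibble::tibble(model = nm, k = k, n = n,
                   aicc = aicc_from_rss(n, rss, k),
                   r_squared = summary(f)$r.squared,
                   ci85_excludes_zero = pass)
  }) |> dplyr::bind_rows()
  stats_tbl$delta_aicc <- stats_tbl$aicc - min(stats_tbl$aicc)
  stats_tbl$weight <- akaike_weights(stats_tbl$aicc)

  # pretending-parameter screen: interaction vs additive, additive vs mains
  nested <- list(interaction = "additive",
                 additive = c("d2h", "prop_c4"))
  pretending <- vapply(stats_tbl$model, function(m) {
    if (!m %in% names(nested)) return(FALSE)
    extra_ok <- stats_tbl$ci85_excludes_zero[stats_tbl$model == m]
    d_nested <- min(stats_tbl$aicc[stats_tbl$model %in% nested[[m]]]) -
      stats_tbl$aicc[stats_tbl$model == m]
    !extra_ok && abs(d_nested) < 2
  }, logical(1))
  stats_tbl$pretending <- pretending

  conf <- stats_tbl[stats_tbl$delta_aicc <= 2 & !stats_tbl$pretending, ]
  eligible <- conf[conf$ci85_excludes_zero, ]
  if (nrow(eligible)) {
    chosen <- eligible$model[order(eligible$k, eligible$aicc)][1]
  } else {
    warning("No candidate passed the 85% CI screen; ",
            "falling back to the lowest-AICc model.", call. = FALSE)
    chosen <- stats_tbl$model[which.min(stats_tbl$aicc)]
  }
  out <- dplyr::arrange(stats_tbl, .data$aicc)
  class(out) <- c("candidate_set", class(out))
  attr(out, "chosen") <- chosen
  attr(out, "fits") <- fits
  out
}

#' Extract the chosen model from a candidate set
#' @param cs A `candidate_set`.
#' @return The chosen `lm` fit.
#' @export
chosen_model <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  attr(cs, "fits")[[attr(cs, "chosen")]]
}

#' @export
tidy.candidate_set <- function(x, ...) {
  fit <- chosen_model(x)
  cf <- summary(fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3],
                 p.value = cf[, 4])
}

#' @export
glance.candidate_set <- function(x, ...) {
  i <- which(x$model == attr(x, "chosen"))
  tibble::tibble(chosen = x$model[i], aicc = x$aicc[i],
                 weight = x$weight[i], r_squared = x$r_squared[i],
                 n = x$n[i])
}

# Inverse-distance-weighted (power 2) interpolation of site values onto
# grid cells; exact at sites (a cell containing a site takes a weighted
# value dominated by it).
idw_at <- function(sites, values, cells, power = 2) {
  D <- dist_km(sites, cells)
  D[D < 1e-9] <- 1e-9
  W <- 1 / D^power
  drop(crossprod(W, values)) / colSums(W)
}

#' Spatially interpolated residual surface for a regression isoscape
#'
#' Averages the chosen model's residuals per site and interpolates them
#' over the grid — by ordinary kriging under a stable variogram fitted to
#' the site residuals, falling back to inverse-distance weighting (power
#' 2) when the variogram fit fails. Cells farther than twice the maximum
#' pairwise site distance from every site have no data support and are set
#' to zero.
#'
#' @param samples Tibble with `lat`, `lon` and the model's variables.
#' @param model A fitted `lm` (typically [chosen_model()] output).
#' @param grid_spec An [iso_grid()] template or `list(extent, cell_size)`.
#' @param method `"kriging"` (default, with IDW fallback) or `"idw"`.
#' @return An [iso_grid()] of interpolated residuals.
#' @export
residual_surface <- function(samples, model, grid_spec,
                             method = c("kriging", "idw")) {
  method <- match.arg(method)
  vars <- all.vars(stats::formula(model))
  ok <- stats::complete.cases(samples[, unique(c(vars, "lat", "lon"))])
  d <- samples[ok, ]
  d$res <- d[[vars[1]]] - stats::predict(model, newdata = d)
  d <- d[, c("lat", "lon", "res")]
  site_res <- dplyr::summarise(dplyr::group_by(d, .data$lat, .data$lon),
                               res = mean(.data$res), .groups = "drop")
  if (nrow(site_res) < 3) stop("Need at least 3 sites.", call. = FALSE)

  tmpl <- if (inherits(grid_spec, "iso_grid")) grid_spec else
    grid_template(grid_spec$extent, grid_spec$cell_size)
  cells <- tibble::tibble(
    lon = rep(grid_lons(tmpl), each = nrow(tmpl$values)),
    lat = rep(grid_lats(tmpl), times = ncol(tmpl$values))
  )

  vals <- NULL
  if (method == "kriging") {
    vals <- tryCatch({
      dmax <- max(dist_km(site_res))
      ev <- empirical_variogram(site_res, site_res$res,
                                lag_km = dmax / 8, n_lags = 8)
      vm <- fit_variogram(ev, kind = "stable")
      krige_at_points(site_res, site_res$res, vm, cells)$pred
    }, error = function(e) NULL)
  }
  if (is.null(vals)) {
    vals <- idw_at(site_res, site_res$res, cells)
  }
  # zero out cells beyond the supported neighbourhood
  dmin <- apply(dist_km(site_res, cells), 2, min)
  vals[dmin > 2 * max(dist_km(site_res))] <- 0

  iso_grid(matrix(vals, nrow(tmpl$values), ncol(tmpl$values)),
           tmpl$origin_lon, tmpl$origin_lat, tmpl$cell_size)
}

#' Predict a feather d13C surface from covariate grids
#'
#' Evaluates the chosen regression model cell-by-cell on aligned covariate
#' grids and adds the interpolated residual surface when supplied. Partial
#' prediction (for partial-regression-style curves) holds one covariate at
#' its median: pass a constant grid for it.
#'
#' @param d2h_grid,prop_c4_grid Aligned [iso_grid()] covariate surfaces.
#' @param model A fitted `lm` over `d2h` and/or `prop_c4`.
#' @param resid_grid Optional aligned [iso_grid()] of interpolated
#'   residuals (from [residual_surface()]).
#' @return An [iso_grid()] of predicted d13C.
#' @export
predict_d13c <- function(d2h_grid, prop_c4_grid, model, resid_grid = NULL) {
  stop_if_misaligned(d2h_grid, prop_c4_grid, "covariate grids")
  newdata <- data.frame(d2h = as.vector(d2h_grid$values),
                        prop_c4 = as.vector(prop_c4_grid$values))
  pred <- stats::predict(model, newdata = newdata)
  out <- d2h_grid
  out$values <- matrix(pred, nrow(d2h_grid$values), ncol(d2h_grid$values))
  if (!is.null(resid_grid)) {
    stop_if_misaligned(out, resid_grid, "prediction and residual grids")
    out$values <- out$values + resid_grid$values
  }
  out
}
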