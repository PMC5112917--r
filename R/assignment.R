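#' Normalized likelihood-of-origin surface for one bird
#'
#' Evaluates the normal probability density of the observed feather d2H at
#' every finite cell of the feather isoscape, treating the cell's predicted
#' value as the mean and the pooled per-cell SD as the standard deviation,
#' then normalizes so the finite cells sum to 1 (a flat prior over the
#' isoscape's finite cells, so the normalized likelihood is the posterior).
#'
#' @param observed Observed feather d2H (permil).
#' @param mean_grid Feather isoscape [iso_grid()].
#' @param sd_grid Aligned pooled-SD [iso_grid()]; must be positive on
#'   finite cells.
#' @return An [iso_grid()] posterior whose finite cells sum to 1.
#' @export
likelihood_surface <- function(observed, mean_grid, sd_grid) {
  stop_if_misaligned(mean_grid, sd_grid, "mean and SD grids")
  mu <- mean_grid$values; sg <- sd_grid$values
  fin <- is.finite(mu) & is.finite(sg)
  if (!any(fin)) stop("All cells are nodata.", call. = FALSE)
  if (any(sg[fin] <= 0)) stop("SD grid must be positive on finite cells.",
                              call. = FALSE)
  # log-density for numerical stability, shifted before exponentiation
  ll <- matrix(NA_real_, nrow(mu), ncol(mu))
  ll[fin] <- stats::dnorm(observed, mu[fin], sg[fin], log = TRUE)
  ll[fin] <- exp(ll[fin] - max(ll[fin]))
  ll[fin] <- ll[fin] / sum(ll[fin])
  out <- mean_grid
  out$values <- ll
  out
}

#' Odds-ratio likely-origin region
#'
#' The smallest set of cells, taken in decreasing order of posterior mass,
#' whose cumulative mass reaches `odds / (odds + 1)`; at the default 2:1
#' odds this is the top two-thirds of the probability mass — the bird's
#' "likely origin". Cells tied in mass at the cut are taken in cell-index
#' order, keeping the region minimal and the result deterministic (a
#' rule that includes every tied cell would, on a uniform posterior,
#' inflate the region to the whole grid).
#'
#' @param posterior A normalized [iso_grid()] from [likelihood_surface()].
#' @param odds Odds ratio of a correct versus incorrect assignment.
#' @return A binary [iso_grid()] mask (1 inside the region, 0 outside, NA
#'   on nodata cells), with attribute `mass`, the mass actually enclosed.
#' @export
odds_region <- function(posterior, odds = 2) {
  stopifnot(odds > 0)
  target <- odds / (odds + 1)
  v <- as.vector(posterior$values)
  fin <- which(is.finite(v))
  ord <- fin[order(v[fin], decreasing = TRUE)]  # stable: ties by cell index
  cum <- cumsum(v[ord])
  k <- which(cum >= target - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  keep <- ord[seq_len(k)]
  mask <- rep(NA_real_, length(v))
  mask[fin] <- 0
  mask[keep] <- 1
  out <- posterior
  out$values <- matrix(mask, nrow(posterior$values), ncol(posterior$values))
  attr(out, "mass") <- sum(v[keep])
  out
}

#' Classify a bird as resident or north/south migrant
#'
#' A bird whose collection cell falls inside its likely-origin region is a
#' resident. Otherwise it is a migrant whose origin lay north of the
#' collection site when the observed feather d2H is *less* than the
#' isoscape prediction there (feathers grown at higher latitude are more
#' depleted), and south when greater. The measure-zero case of exact
#' equality for a non-resident is deterministically labelled south and
#' flagged.
#'
#' @param mask Binary likely-origin [iso_grid()] from [odds_region()].
#' @param site `c(lat, lon)` of the collection site.
#' @param feather_isoscape The feather [iso_grid()] used for assignment.
#' @param observed Observed feather d2H (permil).
#' @return A one-row tibble: `status` (`"resident"`, `"north"`, `"south"`),
#'   `observed`, `predicted_at_site`, `tie` flag.
#' @export
classify_migrant <- function(mask, site, feather_isoscape, observed) {
  pt <- tibble::tibble(lat = site[1], lon = site[2])
  in_mask <- extract_at_points(mask, pt)
  pred <- extract_at_points(feather_isoscape, pt)
  if (in_mask$flag != "ok" || pred$flag != "ok") {
    stop("Collection site outside the grid or on a nodata cell.",
         call. = FALSE)
  }
  tie <- FALSE
  if (in_mask$value == 1) {
    status <- "resident"
  } else if (observed < pred$value) {
    status <- "north"
  } else {
    status <- "south"
    tie <- observed == pred$value
  }
  tibble::tibble(status = status, observed = observed,
                 predicted_at_site = pred$value, tie = tie)
}

#' Assign a set of birds to likely molt origins
#'
#' Runs the full per-bird assignment: normal-likelihood surface,
#' odds-ratio region, and resident/north/south classification against the
#' collection site.
#'
#' @param birds Tibble with `bird_id`, `lat`, `lon`, `d2h`.
#' @param mean_grid Feather isoscape [iso_grid()].
#' @param sd_grid Aligned pooled-SD [iso_grid()].
#' @param odds Odds ratio (default 2, i.e. the top 2/3 of posterior mass).
#' @param keep_masks Keep each bird's binary mask (needed for
#'   [stack_origins()]); set `FALSE` to save memory on large grids.
#' @return An object of class `origin_assignment`: a tibble with one row
#'   per bird (`bird_id`, `status`, `observed`, `predicted_at_site`,
#'   `mask_mass`) and, when `keep_masks`, a list column `mask` of binary
#'   [iso_grid()]s.
#' @export
assign_origin <- function(birds, mean_grid, sd_grid, odds = 2,
                          keep_masks = TRUE) {
  stopifnot(all(c("bird_id", "lat", "lon", "d2h") %in% names(birds)))
  rows <- purrr::map(seq_len(nrow(birds)), function(i) {
    post <- likelihood_surface(birds$d2h[i], mean_grid, sd_grid)
    mask <- odds_region(post, odds = odds)
    cls <- classify_migrant(mask, c(birds$lat[i], birds$lon[i]),
                            mean_grid, birds$d2h[i])
    out <- tibble::tibble(bird_id = birds$bird_id[i],
                          status = cls$status, observed = cls$observed,
                          predicted_at_site = cls$predicted_at_site,
                          mask_mass = attr(mask, "mass"))
    if (keep_masks) out$mask <- list(mask)
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("origin_assignment", class(out))
  out
}

#' Stack likely-origin regions into an origin-count map
#'
#' Cell-by-cell count of birds whose likely-origin region covers the cell,
#' optionally restricted to one migrant status — the "number of birds
#' isotopically consistent with each pixel" map.
#'
#' @param assignments An `origin_assignment` (with masks kept).
#' @param subset Optional status filter (`"resident"`, `"north"`,
#'   `"south"`).
#' @return An [iso_grid()] of counts.
#' @export
stack_origins <- function(assignments, subset = NULL) {
  stopifnot(inherits(assignments, "origin_assignment"),
            "mask" %in% names(assignments))
  keep <- if (is.null(subset)) rep(TRUE, nrow(assignments)) else
    assignments$status %in% subset
  masks <- assignments$mask[keep]
  if (!length(masks)) {
    stop("No assignments matching the requested subset.", call. = FALSE)
  }
  acc <- masks[[1]]$values
  acc[is.na(acc)] <- 0
  if (length(masks) > 1) {
    for (m in masks[-1]) {
      stop_if_misaligned(masks[[1]], m, "origin masks")
      v <- m$values
      v[is.na(v)] <- 0
      acc <- acc + v
    }
  }
  acc[is.na(masks[[1]]$values)] <- NA_real_
  out <- masks[[1]]
  out$values <- acc
  attr(out, "mass") <- NULL
  out
}

#' Validate assignment accuracy on known-origin holdout birds
#'
#' Assigns each holdout bird and reports the fraction whose collection
#' cell falls inside its likely-origin region. Under a correctly specified
#' error model the expected accuracy equals the odds-region mass
#' (2/3 at 2:1 odds).
#'
#' @param holdout Tibble with `bird_id`, `lat`, `lon`, `d2h`.
#' @inheritParams assign_origin
#' @return A list with `accuracy` (fraction), `n_correct`, `n`, and the
#'   per-bird `assignments` tibble.
#' @export
validate_assignment <- function(holdout, mean_grid, sd_grid, odds = 2) {
  stopifnot(nrow(holdout) >= 1)
  asg <- assign_origin(holdout, mean_grid, sd_grid, odds = odds,
                       keep_masks = FALSE)
  n_correct <- sum(asg$status == "resident")
  list(accuracy = n_correct / nrow(asg), n_correct = n_correct,
       n = nrow(asg), assignments = asg)
}

#' @export
autoplot.origin_assignment <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object[, "status"]),
                         .data$status)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "birds",
                  title = "Resident / migrant classification") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iso_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[is.finite(df$value), ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(1.3) +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "permil") +
    ggplot2::theme_minimal()
}
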