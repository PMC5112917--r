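#' @importFrom rlang .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Great-circle distance matrix (km) between two sets of points.
# Points are data frames / lists with $lon and $lat in decimal degrees.
dist_km <- function(a, b = a) {
  m <- geosphere::distm(cbind(a$lon, a$lat), cbind(b$lon, b$lat),
                        fun = geosphere::distHaversine)
  m / 1000
}

# Small-sample Akaike information criterion from an OLS-style fit summary.
# k counts all estimated parameters (coefficients + residual variance).
aicc_from_rss <- function(n, rss, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Akaike weights from a vector of AICc values.
akaike_weights <- function(aicc) {
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
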