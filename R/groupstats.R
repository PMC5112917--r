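iso_combo_vars <- function(combo) {
  map <- c(H = "d2h", C = "d13c", N = "d15n")
  vars <- map[strsplit(combo, "")[[1]]]
  if (anyNA(vars)) stop("Unknown isotope combo: ", combo, call. = FALSE)
  unname(vars)
}

#' Discriminant classification rates by isotope combination
#'
#' For each isotope combination, fits a linear discriminant analysis
#' predicting the collection state from the named feather isotopes (pooled
#' covariance, equal priors — the classic discriminant-analysis defaults)
#' and reports the percentage of birds classified to their collection
#' state. Resubstitution rates by default, matching the single printed
#' percentage per combination in field studies; leave-one-out
#' cross-validated rates behind `cv = TRUE`.
#'
#' @param samples Tibble with `state`, `season`, and isotope columns
#'   `d2h`, `d13c`, `d15n`.
#' @param combos Character vector of combinations over `H`, `C`, `N`
#'   (e.g. `"HC"`).
#' @param subset `"all"`, `"spring"` or `"winter"`.
#' @param cv Use leave-one-out cross-validated rates instead of
#'   resubstitution.
#' @param round Round percentages to integers (the printed-table analog).
#' @return A tibble with `combo`, `subset`, `n`, `pct_correct`.
#' @export
lda_classification_rates <- function(samples,
                                     combos = c("H", "C", "N", "HC", "HN",
                                                "CN", "HCN"),
                                     subset = c("all", "spring", "winter"),
                                     cv = FALSE, round = TRUE) {
  subset <- match.arg(subset)
  d <- if (subset == "all") samples else
    samples[samples$season == subset, , drop = FALSE]
  if (length(unique(d$state)) < 2) {
    stop("Need at least 2 states in the subset.", call. = FALSE)
  }
  rows <- purrr::map(combos, function(cb) {
    vars <- iso_combo_vars(cb)
    dd <- d[stats::complete.cases(d[, vars]), ]
    g <- factor(dd$state)
    x <- as.matrix(dd[, vars])
    n_g <- length(levels(g))
    if (min(table(g)) < length(vars) + 2) {
      stop("Each state needs at least ", length(vars) + 2,
           " samples for combo ", cb, ".", call. = FALSE)
    }
    prior <- rep(1 / n_g, n_g)
    pred <- if (cv) {
      MASS::lda(x, grouping = g, prior = prior, CV = TRUE)$class
    } else {
      fit <- MASS::lda(x, grouping = g, prior = prior)
      stats::predict(fit, x)$class
    }
    pct <- 100 * mean(pred == g)
    tibble::tibble(combo = cb, subset = subset, n = nrow(dd),
                   pct_correct = if (round) round(pct) else pct)
  })
  dplyr::bind_rows(rows)
}

# Wilks' Lambda for a variable set: det(W)/det(T) of within/total SSCP.
wilks_lambda <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  xc <- scale(x, center = TRUE, scale = FALSE)
  T_ <- crossprod(xc)
  W <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xg <- x[g == lev, , drop = FALSE]
    xgc <- scale(xg, center = TRUE, scale = FALSE)
    W <- W + crossprod(xgc)
  }
  det(W) / det(T_)
}

# Rao's F approximation for Wilks' Lambda with p variables and g groups.
wilks_rao_f <- function(lambda, n, p, g) {
  q <- g - 1
  t_den <- p^2 + q^2 - 5
  t <- if (t_den > 0) sqrt((p^2 * q^2 - 4) / t_den) else 1
  df1 <- p * q
  df2 <- t * ((n - 1) - (p + g) / 2) - (df1 - 2) / 2
  lam_t <- lambda^(1 / t)
  F <- (1 - lam_t) / lam_t * df2 / df1
  list(statistic = F, df1 = df1, df2 = df2,
       p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Forward stepwise discriminant variable selection (Wilks' Lambda)
#'
#' Forward selection over candidate predictors using the partial-F test on
#' the ratio of Wilks' Lambda values with and without each candidate: at
#' each step the variable with the largest significant partial F (p below
#' the entry threshold, default 0.15 as in the classic SAS STEPDISC
#' defaults) enters; selection stops when no candidate passes. The overall
#' Wilks' Lambda of the final set is reported with Rao's F approximation.
#'
#' @param samples Tibble with `state` and candidate columns.
#' @param candidates Candidate predictor column names.
#' @param alpha_enter Entry significance level.
#' @return A list: `selected` (in entry order), `lambda`, `statistic`
#'   (Rao's F), `df1`, `df2`, `p_value`, and the per-step `steps` tibble.
#' @export
stepwise_wilks <- function(samples, candidates = c("d2h", "d13c", "d15n"),
                           alpha_enter = 0.15) {
  if (!length(candidates)) stop("No candidate variables.", call. = FALSE)
  d <- samples[stats::complete.cases(samples[, candidates]), ]
  g <- factor(d$state)
  n <- nrow(d); n_g <- length(levels(g))
  selected <- character(0)
  steps <- list()
  lambda_cur <- 1
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    p_in <- length(selected)
    cand_stats <- purrr::map(remaining, function(v) {
      lam_new <- wilks_lambda(d[, c(selected, v)], g)
      partial <- lam_new / lambda_cur
      df1 <- n_g - 1
      df2 <- n - n_g - p_in
      F <- (1 - partial) / partial * df2 / df1
      tibble::tibble(variable = v, lambda = lam_new, partial_f = F,
                     p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
    }) |> dplyr::bind_rows()
    best <- cand_stats[which.max(cand_stats$partial_f), ]
    if (best$p_value > alpha_enter) break
    selected <- c(selected, best$variable)
    lambda_cur <- best$lambda
    steps[[length(steps) + 1]] <- best
  }
  if (!length(selected)) {
    warning("No variable passed the entry test; empty model.",
            call. = FALSE)
    return(list(selected = character(0), lambda = 1, statistic = NA_real_,
                df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
                steps = tibble::tibble()))
  }
  overall <- wilks_rao_f(lambda_cur, n, length(selected), n_g)
  c(list(selected = selected, lambda = lambda_cur),
    overall, list(steps = dplyr::bind_rows(steps)))
}

# All distinct permutations of a label vector (multiset permutations),
# as a matrix with one permutation per column. Used for exact enumeration.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(counts) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (lv in names(counts)[counts > 0]) {
      c2 <- counts
      c2[lv] <- c2[lv] - 1
      for (tail in rec(c2)) out[[length(out) + 1]] <- c(lv, tail)
    }
    out
  }
  counts <- table(labels)
  perms <- rec(counts)
  matrix(unlist(perms), nrow = length(labels))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared Euclidean distances into between-
#' and within-group components (the distance-based pseudo-F construction:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`, `SS_within` from within-group
#' pairwise distances, `F = (SS_B / df_B) / (SS_W / df_W)`), and assesses
#' significance by unrestricted permutation of group labels over rows:
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`. For a univariate
#' response the pseudo-F is algebraically identical to the one-way ANOVA
#' F. When the data admit fewer distinct label arrangements than
#' `n_perm`, the exact permutation distribution is enumerated instead.
#'
#' @param response Numeric matrix or data frame (rows = observations,
#'   e.g. columns d13c and d15n).
#' @param groups Group labels, length `nrow(response)`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `permanova`: `statistic` (pseudo-F), `r_squared`
#'   (SS_B/SS_T), `p_value`, `n_perm` (or number enumerated), `exact`,
#'   `df_between`, `df_resid`.
#' @export
permanova <- function(response, groups, n_perm = 999, seed = NULL) {
  x <- as.matrix(response)
  g <- factor(groups)
  n <- nrow(x)
  stopifnot(length(g) == n, nlevels(g) >= 2, all(table(g) >= 2))
  D2 <- as.matrix(stats::dist(x))^2

  pseudo_f <- function(gg) {
    ss_t <- sum(D2[upper.tri(D2)]) / n
    ss_w <- 0
    for (lev in levels(gg)) {
      idx <- which(gg == lev)
      ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) /
        length(idx)
    }
    ss_b <- ss_t - ss_w
    df_b <- nlevels(gg) - 1
    df_w <- n - nlevels(gg)
    list(F = (ss_b / df_b) / (ss_w / df_w), r2 = ss_b / ss_t,
         df_b = df_b, df_w = df_w)
  }
  obs <- pseudo_f(g)

  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(table(g) + 1)))
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exact) {
    perms <- multiset_permutations(g)
    Fs <- apply(perms, 2, function(p) pseudo_f(factor(p, levels(g)))$F)
    p_value <- mean(Fs >= obs$F - 1e-12)
    n_used <- ncol(perms)
  } else {
    run <- function() {
      vapply(seq_len(n_perm), function(i) {
        pseudo_f(g[sample.int(n)])$F
      }, numeric(1))
    }
    Fs <- if (is.null(seed)) run() else local_seed(seed, run())
    p_value <- (sum(Fs >= obs$F - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(statistic = obs$F, r_squared = obs$r2, p_value = p_value,
         n_perm = n_used, exact = exact, df_between = obs$df_b,
         df_resid = obs$df_w),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "<permanova> pseudo-F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%s, %d perms)\n",
    x$df_between, x$df_resid, x$statistic, x$r_squared, x$p_value,
    if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(term = "groups", statistic = x$statistic,
                 df = x$df_between, df.residual = x$df_resid,
                 r.squared = x$r_squared, p.value = x$p_value)
}

#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, r.squared = x$r_squared,
                 p.value = x$p_value, n_perm = x$n_perm, exact = x$exact)
}

# Compact letter display from CI overlap: states ordered by mean; every
# maximal run of states whose CIs pairwise overlap shares a letter.
ci_letters <- function(lo, hi) {
  k <- length(lo)
  overlap <- function(i, j) lo[i] <= hi[j] & lo[j] <= hi[i]
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(vapply((i:j), function(m) overlap(m, j + 1),
                               logical(1)))) {
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- c(i, j)
  }
  runs <- unique(runs)
  # drop runs contained in another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && runs[[b]][1] <= runs[[a]][1] && runs[[b]][2] >= runs[[a]][2]
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    letters_out[idx] <- paste0(letters_out[idx],
                               ifelse(letters_out[idx] == "", "", ","),
                               letters[r])
  }
  letters_out
}

#' Per-state isotope summary with CI letter groupings
#'
#' Mean, standard error, range and 95% confidence interval of one isotope
#' per state, with compact letters assigned by confidence-interval
#' overlap: states sorted by mean (descending), each maximal run of
#' states with pairwise-overlapping CIs sharing a letter — so states with
#' non-overlapping CIs never share one.
#'
#' @param samples Tibble with `state` and the isotope column.
#' @param isotope Isotope column name (`"d2h"`, `"d13c"` or `"d15n"`).
#' @return A tibble (`state`, `mean`, `se`, `n`, `min`, `max`, `lower_ci`,
#'   `upper_ci`, `group`) sorted by decreasing mean.
#' @export
state_summary <- function(samples, isotope = "d2h") {
  stopifnot(isotope %in% names(samples))
  d <- samples[is.finite(samples[[isotope]]), ]
  out <- d |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      mean = mean(.data[[isotope]]),
      se = stats::sd(.data[[isotope]]) / sqrt(dplyr::n()),
      n = dplyr::n(),
      min = min(.data[[isotope]]),
      max = max(.data[[isotope]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(lower_ci = .data$mean - 1.96 * .data$se,
                  upper_ci = .data$mean + 1.96 * .data$se) |>
    dplyr::arrange(dplyr::desc(.data$mean))
  if (any(out$n < 2)) stop("Each state needs n >= 2.", call. = FALSE)
  out$group <- ci_letters(out$lower_ci, out$upper_ci)
  out
}

#' Correlations of feather isotopes with latitude and longitude
#'
#' Simple per-pair linear regressions of each isotope on collection-site
#' latitude and longitude, reporting the Pearson correlation, adjusted
#' R-squared and regression p-value.
#'
#' @param samples Tibble with `lat`, `lon` and isotope columns.
#' @param isotopes Isotope columns to test.
#' @return A tibble (`isotope`, `coordinate`, `r`, `adj_r_squared`,
#'   `p_value`, `n`).
#' @export
geo_correlations <- function(samples, isotopes = c("d2h", "d13c", "d15n")) {
  rows <- purrr::map(isotopes, function(iso) {
    purrr::map(c("lat", "lon"), function(co) {
      ok <- stats::complete.cases(samples[, c(iso, co)])
      y <- samples[[iso]][ok]; x <- samples[[co]][ok]
      if (length(y) < 3) stop("Need n >= 3.", call. = FALSE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("Zero variance in ", iso, " or ", co, ".", call. = FALSE)
      }
      fit <- summary(stats::lm(y ~ x))
      tibble::tibble(
        isotope = iso, coordinate = co,
        r = stats::cor(x, y),
        adj_r_squared = fit$adj.r.squared,
        p_value = fit$coefficients[2, 4],
        n = length(y)
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
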