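sep_states <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    state = rep(c("A", "B"), each = n),
    season = "spring",
    d2h = c(rnorm(n, -120, 8), rnorm(n, -40, 8)),
    d13c = rnorm(2 * n, -20, 2),
    d15n = rnorm(2 * n, 10, 1)
  )
}

test_that("widely separated states classify perfectly on d2H", {
  d <- sep_states()
  out <- lda_classification_rates(d, combos = "H", subset = "all")
  expect_equal(out$pct_correct, 100)
})

test_that("identical state distributions classify at chance", {
  set.seed(2)
  rates <- vapply(1:10, function(i) {
    d <- tibble::tibble(
      state = rep(c("A", "B", "C", "D"), each = 30), season = "spring",
      d2h = rnorm(120, -80, 10), d13c = rnorm(120, -20, 2),
      d15n = rnorm(120, 10, 1)
    )
    lda_classification_rates(d, combos = "HCN", subset = "all",
                             round = FALSE)$pct_correct
  }, numeric(1))
  # chance level for four equal groups is 25%; resubstitution optimism
  # keeps it slightly above
  expect_lt(abs(mean(rates) - 25), 12)
})

test_that("classification rate is invariant to affine predictor rescaling", {
  d <- sep_states(seed = 3)
  base <- lda_classification_rates(d, combos = "HCN", round = FALSE)
  d2 <- d
  d2$d2h <- 3.5 * d2$d2h + 100
  d2$d13c <- -2 * d2$d13c
  resc <- lda_classification_rates(d2, combos = "HCN", round = FALSE)
  expect_equal(base$pct_correct, resc$pct_correct)
})

test_that("season subsets restrict the sample", {
  d <- sep_states()
  d$season[seq(1, 80, by = 2)] <- "winter"
  all_ <- lda_classification_rates(d, combos = "H", subset = "all")
  spr <- lda_classification_rates(d, combos = "H", subset = "spring")
  expect_equal(all_$n, 80)
  expect_equal(spr$n, 40)
  expect_equal(sum(d$season == "spring"), 40)
})

test_that("stepwise selection keeps signal and drops pure noise", {
  set.seed(4)
  d <- sep_states(n = 60, seed = 4)
  d$noise <- rnorm(nrow(d))
  sw <- stepwise_wilks(d, candidates = c("d2h", "noise"))
  expect_equal(sw$selected, "d2h")
  # all three isotopes informative -> all enter
  d2 <- tibble::tibble(
    state = rep(c("A", "B", "C"), each = 50),
    d2h = rnorm(150, rep(c(-120, -80, -40), each = 50), 8),
    d13c = rnorm(150, rep(c(-25, -20, -15), each = 50), 2),
    d15n = rnorm(150, rep(c(8, 10, 12), each = 50), 1)
  )
  sw2 <- stepwise_wilks(d2)
  expect_setequal(sw2$selected, c("d2h", "d13c", "d15n"))
  expect_lt(sw2$p_value, 1e-6)
  expect_error(stepwise_wilks(d, candidates = character(0)), "No candidate")
})

test_that("Rao's F approximation matches the printed df convention", {
  # 3 predictors, 9 groups, 661 observations -> df 24 and ~1885
  rao <- moltrace:::wilks_rao_f(0.3, n = 661, p = 3, g = 9)
  expect_equal(rao$df1, 24)
  expect_equal(rao$df2, 1885, tolerance = 0.01)
})

test_that("perMANOVA pseudo-F equals classical ANOVA F in one dimension", {
  set.seed(5)
  y <- rnorm(30, rep(c(0, 1, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  pm <- permanova(matrix(y, ncol = 1), g, n_perm = 99, seed = 1)
  a <- anova(lm(y ~ g))
  expect_equal(pm$statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(pm$df_between, 2)
  expect_equal(pm$df_resid, 27)
})

test_that("perMANOVA agrees with vegan on statistic and R2", {
  skip_if_not_installed("vegan")
  set.seed(6)
  x <- cbind(rnorm(24, rep(c(0, 1.5), each = 12)), rnorm(24))
  g <- rep(c("a", "b"), each = 12)
  pm <- permanova(x, g, n_perm = 199, seed = 2)
  av <- vegan::adonis2(dist(x) ~ g, permutations = 199)
  expect_equal(pm$statistic, av$F[1], tolerance = 1e-8)
  expect_equal(pm$r_squared, av$R2[1], tolerance = 1e-8)
})

test_that("tiny designs are enumerated exactly and match brute force", {
  y <- matrix(c(1.2, 0.8, 1.5, 3.1, 2.9, 3.4), ncol = 1)
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(y, g, n_perm = 999, seed = 3)
  expect_true(pm$exact)
  expect_equal(pm$n_perm, 20)
  # independent oracle: classical ANOVA F over all 20 label splits
  f_of <- function(gg) anova(lm(y[, 1] ~ factor(gg)))$`F value`[1]
  splits <- combn(6, 3)
  fs <- apply(splits, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    f_of(gg)
  })
  expect_equal(pm$p_value, mean(fs >= f_of(g) - 1e-12), tolerance = 1e-12)
})

test_that("perMANOVA type-I error is near nominal under the null", {
  set.seed(7)
  rejections <- vapply(1:100, function(i) {
    x <- cbind(rnorm(18), rnorm(18))
    g <- rep(c("a", "b", "c"), each = 6)
    permanova(x, g, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.07)
})

test_that("CI letters separate disjoint and join overlapping states", {
  d <- tibble::tibble(
    state = rep(c("A", "B"), each = 30),
    d2h = c(rnorm(30, -120, 3), rnorm(30, -40, 3))
  )
  s <- state_summary(d, "d2h")
  expect_equal(s$group, c("a", "b"))

  d2 <- tibble::tibble(
    state = rep(c("A", "B", "C"), each = 5),
    d2h = rep(c(-100.2, -100, -99.8), each = 5) + rep(rnorm(5, 0, 8), 3)
  )
  s2 <- state_summary(d2, "d2h")
  expect_equal(unique(s2$group), "a")

  # identical data always share a letter
  d3 <- tibble::tibble(state = rep(c("X", "Y"), each = 10),
                       d2h = rep(rnorm(10, -80, 5), 2))
  expect_equal(length(unique(state_summary(d3, "d2h")$group)), 1)
})

test_that("geographic correlations recover exact and null relationships", {
  d <- tibble::tibble(
    lat = seq(30, 48, length.out = 50),
    lon = runif(50, -105, -95),
    d2h = 10 - 3 * seq(30, 48, length.out = 50),
    d13c = rnorm(50, -20), d15n = rnorm(50, 10)
  )
  gc <- suppressWarnings(geo_correlations(d))  # perfect-fit lm warning
  expect_equal(gc$r[gc$isotope == "d2h" & gc$coordinate == "lat"], -1,
               tolerance = 1e-9)
  # independent noise: small |r|
  expect_lt(abs(gc$r[gc$isotope == "d13c" & gc$coordinate == "lat"]), 0.4)
  d$flat <- 1
  expect_error(geo_correlations(dplyr::mutate(d, d2h = 1)), "Zero variance")
})
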