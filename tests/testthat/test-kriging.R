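test_that("Matheron estimator is exact on a two-point instance", {
  pts <- tibble::tibble(lat = c(45, 45), lon = c(-100, -99.5))
  ev <- empirical_variogram(pts, c(0, 2), lag_km = 100, n_lags = 1)
  expect_equal(ev$gamma, 2)   # (1/2) * (2^2) / 1
  expect_equal(ev$np, 1L)
})

test_that("a constant field has zero semivariance in every bin", {
  set.seed(1)
  pts <- tibble::tibble(lat = runif(15, 44, 48), lon = runif(15, -104, -96))
  ev <- empirical_variogram(pts, rep(5, 15), lag_km = 80, n_lags = 8)
  expect_true(all(ev$gamma == 0))
})

test_that("all pairs beyond the maximum lag is an error", {
  pts <- tibble::tibble(lat = c(30, 50), lon = c(-100, -100))
  expect_error(empirical_variogram(pts, c(0, 1), lag_km = 10, n_lags = 2),
               "maximum lag")
})

test_that("variogram fit recovers parameters from an exact model curve", {
  truth <- variogram_model("stable", nugget = 132.01, psill = 380.20,
                           range_km = 718, shape = 1.2)
  h <- seq(40, 1200, by = 80.6)
  ev <- tibble::tibble(lag = h, gamma = vgm_gamma(truth, h),
                       np = rep(200L, length(h)))
  class(ev) <- c("empirical_variogram", class(ev))
  fit <- fit_variogram(ev, "stable")
  expect_lt(abs(fit$nugget - 132.01) / 132.01, 0.01)
  expect_lt(abs(fit$psill - 380.20) / 380.20, 0.01)
  expect_lt(abs(fit$range_km - 718) / 718, 0.01)
})

test_that("pure-nugget data fit to a negligible partial sill", {
  set.seed(2)
  pts <- tibble::tibble(lat = runif(60, 40, 48), lon = runif(60, -105, -95))
  vals <- rnorm(60, 0, 5)
  ev <- empirical_variogram(pts, vals, lag_km = 100, n_lags = 8)
  fit <- fit_variogram(ev, "stable")
  sill_tot <- fit$nugget + fit$psill
  expect_lt(fit$psill / sill_tot, 0.35)
})

test_that("kriging matches a brute-force solve of the full system", {
  # three-point toy; the oracle writes out the ordinary kriging system
  # explicitly and solves it with a plain linear solve
  pts <- tibble::tibble(lat = c(45, 45, 45), lon = c(-100, -99, -97.5))
  z <- c(-90, -95, -105)
  vm <- variogram_model("stable", nugget = 10, psill = 100, range_km = 150,
                        shape = 1)
  target <- tibble::tibble(lat = 45, lon = -98.2)

  D <- moltrace:::dist_km(pts)
  g0 <- vgm_gamma(vm, moltrace:::dist_km(pts, target))
  A <- rbind(cbind(vgm_gamma(vm, D), 1), c(1, 1, 1, 0))
  sol <- solve(A, c(g0, 1))
  oracle_pred <- sum(sol[1:3] * z)
  oracle_var <- sum(sol[1:3] * g0) + sol[4]

  kp <- moltrace:::krige_at_points(pts, z, vm, target)
  expect_equal(kp$pred, oracle_pred, tolerance = 1e-8)
  expect_equal(kp$sd, sqrt(oracle_var), tolerance = 1e-8)
  # ordinary-kriging constraint: weights sum to one
  expect_equal(sum(sol[1:3]), 1, tolerance = 1e-10)
})

test_that("kriging is exact at data locations and unbiased on constants", {
  set.seed(3)
  pts <- tibble::tibble(lat = runif(8, 44, 47), lon = runif(8, -102, -97))
  z <- rnorm(8, -100, 10)
  vm <- variogram_model("stable", nugget = 0, psill = 150, range_km = 200)
  at_data <- moltrace:::krige_at_points(pts, z, vm, pts)
  expect_equal(at_data$pred, z, tolerance = 1e-6)
  expect_equal(at_data$sd, rep(0, 8), tolerance = 1e-6)
  # constant data -> constant surface with zero variance at data points
  kc <- krige(pts, rep(-80, 8), vm,
              grid_template(c(44, 47, -102, -97), 0.5))
  expect_true(all(abs(kc$mean$values + 80) < 1e-6))
})

test_that("weights sum to one at every predicted cell", {
  # implied check through affine equivariance: adding a constant to the
  # data shifts every prediction by exactly that constant
  set.seed(4)
  pts <- tibble::tibble(lat = runif(10, 44, 47), lon = runif(10, -102, -97))
  z <- rnorm(10, -100, 8)
  vm <- variogram_model("stable", nugget = 20, psill = 100, range_km = 150)
  tmpl <- grid_template(c(44.5, 46.5, -101, -98), 0.5)
  k1 <- krige(pts, z, vm, tmpl)
  k2 <- krige(pts, z + 50, vm, tmpl)
  expect_equal(k2$mean$values, k1$mean$values + 50, tolerance = 1e-8)
})

test_that("duplicate locations are averaged with a warning", {
  pts <- tibble::tibble(lat = c(45, 45, 46), lon = c(-100, -100, -99))
  vm <- variogram_model("stable", nugget = 1, psill = 10, range_km = 100)
  expect_warning(
    k <- moltrace:::krige_at_points(pts, c(-90, -94, -100), vm,
                                    tibble::tibble(lat = 45, lon = -100)),
    "Duplicate")
  expect_equal(k$pred, -92, tolerance = 1e-6)  # exact at the averaged datum
})

test_that("LOO RMSE behaves like the field noise", {
  set.seed(5)
  pts <- tibble::tibble(lat = runif(40, 42, 48), lon = runif(40, -105, -95))
  vals <- rnorm(40, 0, 6)   # pure noise
  vm <- variogram_model("stable", nugget = 36, psill = 1e-6, range_km = 300)
  cv <- loo_cross_validate(pts, vals, vm)
  expect_lt(abs(cv$rmse - 6), 2.5)
  # an outlier inflates RMSE monotonically
  v1 <- vals; v1[1] <- 30
  v2 <- vals; v2[1] <- 60
  r1 <- loo_cross_validate(pts, v1, vm)$rmse
  r2 <- loo_cross_validate(pts, v2, vm)$rmse
  expect_gt(r1, cv$rmse)
  expect_gt(r2, r1)
})

test_that("anisotropic distances stretch the minor axis", {
  vm_iso <- variogram_model("gaussian", nugget = 0, psill = 1,
                            range_km = 100)
  vm_ani <- variogram_model("gaussian", nugget = 0, psill = 1,
                            range_km = 100, anisotropy = c(0, 2))
  a <- tibble::tibble(lat = 45, lon = -100)
  b <- tibble::tibble(lat = 45, lon = -99)   # east-west displacement
  d_iso <- moltrace:::model_dist_km(vm_iso, a, b)[1, 1]
  d_ani <- moltrace:::model_dist_km(vm_ani, a, b)[1, 1]
  # azimuth 0 = north-south major axis, so east-west is minor and doubled
  expect_equal(d_ani / d_iso, 2, tolerance = 0.01)
  c_ <- tibble::tibble(lat = 45.9, lon = -100)  # north-south displacement
  expect_equal(moltrace:::model_dist_km(vm_ani, a, c_)[1, 1] /
                 moltrace:::model_dist_km(vm_iso, a, c_)[1, 1],
               1, tolerance = 0.01)
})

test_that("surface comparison: identical surfaces split the weight", {
  g <- plane_grid()
  hold <- birds_on_grid(g, 20, sigma = 2, seed = 6)
  cmp <- compare_surfaces_by_validation(list(a = g, b = g), hold)
  expect_equal(cmp$weight, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("the AICc formula matches its closed form", {
  expect_equal(moltrace:::aicc_from_rss(n = 10, rss = 10, k = 3), 10)
})

test_that("validation strongly favours the truth surface over noise", {
  g <- plane_grid(nr = 20, nc = 20, b_lat = -4)
  set.seed(7)
  corrupted <- g
  corrupted$values <- g$values + rnorm(length(g$values), 0, 15)
  hold <- birds_on_grid(g, 30, sigma = 2, seed = 8)
  cmp <- compare_surfaces_by_validation(list(truth = g, noisy = corrupted),
                                        hold)
  expect_equal(attr(cmp, "chosen"), "truth")
  expect_gt(cmp$weight[cmp$surface == "truth"], 0.95)
})

test_that("validation slope covers 1 at 85% confidence on clean data", {
  g <- plane_grid(nr = 20, nc = 20, b_lat = -4)
  cover <- vapply(1:20, function(i) {
    hold <- birds_on_grid(g, 40, sigma = 3, seed = 100 + i)
    cmp <- compare_surfaces_by_validation(list(a = g, b = g), hold)
    cmp$slope_lo85[1] <= 1 && cmp$slope_hi85[1] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})
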