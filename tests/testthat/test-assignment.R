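test_that("likelihood surface matches the closed-form normal ratio", {
  mu <- iso_grid(matrix(c(-100, -120), 1, 2), -100, 45, 1)
  sg <- iso_grid(matrix(10, 1, 2), -100, 45, 1)
  post <- likelihood_surface(-100, mu, sg)
  # densities proportional to exp(0) and exp(-2)
  expect_equal(as.vector(post$values),
               c(1, exp(-2)) / (1 + exp(-2)), tolerance = 1e-10)
  expect_equal(as.vector(post$values), c(0.8808, 0.1192), tolerance = 1e-4)
})

test_that("a flat isoscape yields a uniform posterior", {
  mu <- constant_grid(-90, nr = 9, nc = 11)
  sg <- constant_grid(12, nr = 9, nc = 11)
  post <- likelihood_surface(-90, mu, sg)
  expect_equal(as.vector(post$values), rep(1 / 99, 99), tolerance = 1e-12)
})

test_that("posteriors are normalized on any synthetic grid", {
  cfg <- sim_config(seed = 41, cell_size = 0.5)
  ps <- make_precip_isoscape(cfg)
  rf <- rescaling_fn(-37.45, 0.86)
  fi <- apply_rescaling(ps$mean, rf)
  pe <- pooled_error_surface(ps$mean, ps$sd, rf)
  for (obs in c(-140, -100, -60, -25)) {
    post <- likelihood_surface(obs, fi, pe)
    expect_equal(sum(post$values, na.rm = TRUE), 1, tolerance = 1e-8)
  }
  expect_error(likelihood_surface(-100, fi, apply_rescaling(pe,
                                                rescaling_fn(0, 0))),
               "positive")
})

test_that("odds region equals the brute-force top-mass set", {
  # uniform over 99 cells: the smallest prefix reaching 2/3 has
  # ceiling(2/3 * 99) = 66 cells
  mu <- constant_grid(-90, nr = 9, nc = 11)
  sg <- constant_grid(12, nr = 9, nc = 11)
  post <- likelihood_surface(-90, mu, sg)
  mask <- odds_region(post, odds = 2)
  expect_equal(sum(mask$values), 66)

  # random posterior: compare against direct cumulation
  set.seed(42)
  v <- rexp(60)
  v <- v / sum(v)
  post2 <- iso_grid(matrix(v, 6, 10), -100, 45, 1)
  mask2 <- odds_region(post2, odds = 2)
  sorted <- sort(v, decreasing = TRUE)
  k_expected <- which(cumsum(sorted) >= 2 / 3)[1]
  expect_equal(sum(mask2$values), k_expected)
  expect_gte(attr(mask2, "mass"), 2 / 3 - 1e-9)
  # minimality: dropping the smallest included cell goes below 2/3
  expect_lt(attr(mask2, "mass") - sorted[k_expected], 2 / 3)
})

test_that("a dominant cell alone forms the region", {
  v <- c(0.70, rep(0.30 / 8, 8))
  post <- iso_grid(matrix(v, 3, 3), -100, 45, 1)
  mask <- odds_region(post, odds = 2)
  expect_equal(sum(mask$values), 1)
  expect_equal(mask$values[1, 1], 1)
})

test_that("raising the odds grows the region monotonically", {
  set.seed(43)
  v <- rexp(100); v <- v / sum(v)
  post <- iso_grid(matrix(v, 10, 10), -100, 45, 1)
  n2 <- sum(odds_region(post, 2)$values)
  n3 <- sum(odds_region(post, 3)$values)
  expect_gte(n3, n2)
})

test_that("migrant classification follows the sign rule", {
  g <- plane_grid(nr = 20, nc = 20, a = 0, b_lat = -3, b_lon = 0)
  sg <- g; sg$values[] <- 5
  site <- c(45, -98)
  pred <- extract_at_points(g, tibble::tibble(lat = 45, lon = -98))$value

  # observed = predicted: collection cell is the posterior mode -> resident
  post <- likelihood_surface(pred, g, sg)
  mask <- odds_region(post)
  cls <- classify_migrant(mask, site, g, pred)
  expect_equal(cls$status, "resident")

  # far more depleted than predicted, tight sigma -> north
  sg$values[] <- 2
  post <- likelihood_surface(pred - 30, g, sg)
  cls <- classify_migrant(odds_region(post), site, g, pred - 30)
  expect_equal(cls$status, "north")

  # far more enriched -> south
  post <- likelihood_surface(pred + 30, g, sg)
  cls <- classify_migrant(odds_region(post), site, g, pred + 30)
  expect_equal(cls$status, "south")
})

test_that("status partition over non-residents is exhaustive and exclusive", {
  g <- plane_grid(nr = 15, nc = 15, a = 0, b_lat = -3, b_lon = 0)
  sg <- g; sg$values[] <- 8
  birds <- birds_on_grid(g, 40, sigma = 25, seed = 44)
  asg <- assign_origin(birds, g, sg, keep_masks = FALSE)
  expect_true(all(asg$status %in% c("resident", "north", "south")))
  non_res <- asg[asg$status != "resident", ]
  expect_true(all((non_res$observed < non_res$predicted_at_site) ==
                    (non_res$status == "north")))
})

test_that("stacked origin counts are exact bookkeeping", {
  m1 <- iso_grid(matrix(c(1, 0, 0, 0), 2, 2), -100, 45, 1)
  m2 <- iso_grid(matrix(c(0, 1, 0, 0), 2, 2), -100, 45, 1)
  fake <- tibble::tibble(bird_id = c("a", "b"),
                         status = c("north", "south"),
                         observed = 0, predicted_at_site = 0,
                         mask_mass = 1, mask = list(m1, m2))
  class(fake) <- c("origin_assignment", class(fake))
  expect_equal(max(stack_origins(fake)$values), 1)  # disjoint masks
  expect_equal(sum(stack_origins(fake)$values), 2)
  north <- stack_origins(fake, subset = "north")
  expect_equal(sum(north$values), 1)

  # N identical masks count to N inside and 0 outside
  fake$mask <- list(m1, m1)
  stacked <- stack_origins(fake)
  expect_equal(stacked$values[1, 1], 2)
  expect_equal(sum(stacked$values), 2)
})

test_that("assignment accuracy approaches the limits in sigma", {
  g <- plane_grid(nr = 12, nc = 12, a = 0, b_lat = -3, b_lon = 0)
  birds <- birds_on_grid(g, 15, sigma = 0, seed = 45)
  birds$d2h <- birds$d2h + 40    # displaced observations
  tight <- g; tight$values[] <- 1e-3
  wide <- g; wide$values[] <- 1e5
  expect_equal(validate_assignment(birds, g, tight)$accuracy, 0)
  # as sigma grows the posterior flattens and the top-mass region tends to
  # the odds mass (2/3 of cells), so accuracy is bounded below by it
  expect_gte(validate_assignment(birds, g, wide)$accuracy, 2 / 3 - 0.05)
})
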