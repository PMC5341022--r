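unit_ranges <- function(k = 3) {
  param_ranges(paste0("u", seq_len(k)), rep(0, k), rep(1, k))
}

test_that("the design has the one-at-a-time trajectory structure", {
  d <- morris_design(unit_ranges(), r = 4, p = 4, seed = 3)
  expect_equal(nrow(design_points(d)), 16L)   # r * (k + 1)
  expect_equal(d$delta, 2 / 3)
  for (tr in d$trajectories) {
    steps <- diff(tr$unit)
    # exactly one coordinate moves per step, by +/- delta
    expect_true(all(rowSums(steps != 0) == 1))
    expect_true(all(abs(abs(steps[steps != 0]) - d$delta) < 1e-12))
    # each parameter moves exactly once
    expect_equal(sort(unname(colSums(steps != 0))), rep(1, 3))
    # all points on the grid inside the unit cube
    expect_true(all(tr$unit >= -1e-12 & tr$unit <= 1 + 1e-12))
  }
  expect_error(morris_design(unit_ranges(), r = 1, p = 4),
               class = "tggpp_error_invalid_config")
  expect_error(morris_design(unit_ranges(), r = 4, p = 5),
               class = "tggpp_error_invalid_config")
})

test_that("constant and additive-linear functions give exact mu* and sigma", {
  res0 <- morris_screen(function(u) 42, unit_ranges(), r = 6, p = 4, seed = 1)
  expect_equal(unname(res0$mu_star), c(0, 0, 0))
  expect_equal(unname(res0$sigma), c(0, 0, 0))
  expect_equal(res0$rank, 1:3)   # ties resolved in declaration order

  # f(u) = 3 u1: mu* equals the absolute coefficient exactly, sigma = 0
  res1 <- morris_screen(function(u) 3 * u[1], unit_ranges(),
                        r = 8, p = 6, seed = 2)
  expect_equal(unname(res1$mu_star), c(3, 0, 0))
  expect_equal(unname(res1$sigma), c(0, 0, 0))
  expect_equal(res1$rank[1], 1L)
  expect_false(any(res1$interaction_flag))
})

test_that("interacting inputs show positive sigma", {
  res <- morris_screen(function(u) u[1] * u[2], unit_ranges(),
                       r = 30, p = 4, seed = 5)
  expect_gt(res$sigma[1], 0)
  expect_gt(res$sigma[2], 0)
  expect_equal(res$mu_star[[3]], 0)
})

test_that("sampled mu* and sigma match brute-force enumeration", {
  f <- function(u) 3 * u[1] + u[2] * u[3]
  r <- 50
  oracle <- enumerate_morris(f, k = 3, p = 4)
  res <- morris_screen(f, unit_ranges(), r = r, p = 4, seed = 9)
  for (i in 1:3) {
    se_mu <- oracle[[i]]$sigma / sqrt(r)
    se_sd <- oracle[[i]]$sigma / sqrt(2 * r)
    expect_lt(abs(res$mu_star[[i]] - oracle[[i]]$mu_star),
              3 * se_mu + 1e-10)
    expect_lt(abs(res$sigma[[i]] - oracle[[i]]$sigma), 3 * se_sd + 1e-10)
  }
})

test_that("ranking is invariant to affine rescaling of the output", {
  f <- function(u) u[1]^2 + 0.5 * u[2] + 0.1 * u[3]
  a <- morris_screen(f, unit_ranges(), r = 12, p = 8, seed = 4)
  b <- morris_screen(function(u) -7 * f(u) + 3, unit_ranges(),
                     r = 12, p = 8, seed = 4)
  expect_equal(a$rank, b$rank)
})

test_that("non-finite outputs drop the trajectory with a warning", {
  d <- morris_design(unit_ranges(), r = 4, p = 4, seed = 8)
  y <- rep(1, 16); y[2] <- NaN
  expect_warning(ee <- elementary_effects(d, y), "dropped")
  expect_equal(nrow(ee), 3L)
})

test_that("TG screening on synthetic data ranks x_m last", {
  s <- simulate_site(recovery_preset(), n_years = 10, seed = 21)
  res <- screen_tg(s, r = 20, p = 8, seed = 2)
  expect_equal(res$rank[res$parameter == "x_m"], 3L)
  expect_true(res$parameter[res$rank == 1L] %in% c("x_n", "x_o"))
  # all sampled parameter sets respected the strict ordering: mu* finite
  expect_true(all(is.finite(res$mu_star)))
})

test_that("screening is byte-identical under a fixed seed", {
  s <- simulate_site(recovery_preset(), n_years = 6, seed = 33)
  a <- screen_tg(s, r = 8, p = 8, seed = 7)
  b <- screen_tg(s, r = 8, p = 8, seed = 7)
  expect_identical(a, b)
})
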