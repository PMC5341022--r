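test_that("the Gaussian log-likelihood matches its closed form", {
  s <- make_series(12)   # gpp is exact TG output => zero residuals
  ll1 <- tg_log_likelihood(c(0, 30, 50), log_sigma = 0, s)
  expect_equal(ll1, -6 * log(2 * pi), tolerance = 1e-10)
  # doubling sigma with zero residuals lowers the value by n * log(2)
  ll2 <- tg_log_likelihood(c(0, 30, 50), log_sigma = log(2), s)
  expect_equal(ll1 - ll2, 12 * log(2), tolerance = 1e-10)
})

test_that("the log-likelihood agrees with an independent dnorm evaluation", {
  set.seed(77)
  s <- make_series(40)
  s$gpp <- pmax(s$gpp + rnorm(40, sd = 1.2), 0)
  theta <- c(-3, 24, 55); lsig <- log(1.7)
  prod <- scale_evi(s$evi) * scale_lst(s$lst, tg_params(theta[1], theta[2], theta[3]))
  m <- fit_m(s$gpp, prod)
  oracle <- sum(dnorm(s$gpp, mean = m * prod, sd = exp(lsig), log = TRUE))
  expect_equal(tg_log_likelihood(theta, lsig, s), oracle, tolerance = 1e-10)
})

test_that("ordering violations yield -Inf, not an error", {
  s <- make_series(12)
  expect_identical(tg_log_likelihood(c(30, 20, 50), 0, s), -Inf)
  expect_identical(tg_log_prior(c(20, 15, 50), 0), -Inf)
})

test_that("the uniform prior is finite inside the box and -Inf outside", {
  expect_identical(tg_log_prior(c(0, 30, 50), 0), 0)
  expect_identical(tg_log_prior(c(0, 45, 50), 0), -Inf)   # x_o beyond 40
  expect_identical(tg_log_prior(c(-20, 30, 50), 0), -Inf)
  expect_identical(tg_log_prior(c(0, 30, 50), log(1000)), -Inf)
})

test_that("the sampler is deterministic under a fixed seed", {
  lp <- function(x) -0.5 * sum(x^2)
  a <- metropolis_hastings(lp, c(p = 0), n_iter = 2000, proposal_scales = 2,
                           seed = 42)
  b <- metropolis_hastings(lp, c(p = 0), n_iter = 2000, proposal_scales = 2,
                           seed = 42)
  expect_identical(a$samples, b$samples)
  expect_gt(a$acceptance_rate, 0)
  expect_lt(a$acceptance_rate, 1)
})

test_that("a chain that can never move raises the stuck-chain signal", {
  init <- c(x = 0)
  lp <- function(x) if (identical(unname(x), 0)) 0 else -Inf
  expect_error(
    metropolis_hastings(lp, init, n_iter = 500, proposal_scales = 1, seed = 1),
    class = "tggpp_error_stuck_chain")
})

test_that("diagnostics separate converged, stuck and prior-dominated chains", {
  rg <- param_ranges()
  set.seed(5)
  # well-mixed, concentrated posterior inside the x_o prior
  good <- fake_chain(cbind(x_o = rnorm(20000, 25, 1)))
  s1 <- diagnose_convergence(good, rg)
  expect_equal(s1$status, "converged")
  expect_equal(s1$median, 25, tolerance = 0.1)
  expect_true(s1$ci_lower < s1$median && s1$median < s1$ci_upper)

  # posterior indistinguishable from the uniform prior
  flat <- fake_chain(cbind(x_m = runif(20000, 40, 65)))
  expect_equal(diagnose_convergence(flat, rg)$status, "prior-dominated")

  # two chains stuck at different constants
  stuck <- list(fake_chain(cbind(x_o = rep(20, 1000))),
                fake_chain(cbind(x_o = rep(30, 1000))))
  expect_equal(diagnose_convergence(stuck, rg)$status, "not-converged")

  expect_error(diagnose_convergence(fake_chain(cbind(x = 1:5)), rg),
               class = "tggpp_error_insufficient_samples")
})

test_that("calibration recovers known parameters on one synthetic site", {
  s <- simulate_site(recovery_preset(), n_years = 10, seed = 101)
  ch <- calibrate_tg(s, n_iter = 3e4, seed = 1)
  expect_true(all(posterior_samples(ch)[, "x_n"] < posterior_samples(ch)[, "x_o"]))
  su <- summarize_calibration(ch)
  expect_lt(abs(su$median[su$parameter == "x_o"] - 25), 2)
  expect_lt(abs(su$median[su$parameter == "x_n"] - 0), 3)
  # noise scale is recovered too (truth: 15% of mean clean GPP)
  truth_sd <- attr(s, "truth")$noise_sd
  expect_equal(exp(su$median[su$parameter == "log_sigma"]), truth_sd,
               tolerance = 0.25)
})

test_that("retained samples always satisfy ordering and the prior box", {
  s <- simulate_site(recovery_preset(), n_years = 6, seed = 55)
  ch <- calibrate_tg(s, n_iter = 5e3, seed = 2)
  m <- posterior_samples(ch)
  rg <- param_ranges()
  expect_true(all(m[, "x_n"] < m[, "x_o"] & m[, "x_o"] < m[, "x_m"]))
  for (j in 1:3) {
    expect_true(all(m[, j] >= rg$lower[j] & m[, j] <= rg$upper[j]))
  }
})
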