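random_design <- function(n, p, seed, rho = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0) X[, 2] <- rho * X[, 1] + sqrt(1 - rho^2) * X[, 2]
  colnames(X) <- paste0("v", seq_len(p))
  X
}

test_that("MLR recovers exact and null relationships", {
  X <- random_design(100, 3, 1)
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  fit <- suppressWarnings(mlr_fit(X, y))   # summary.lm flags the exact fit
  expect_equal(fit$r_squared, 1)
  y0 <- rnorm(100)
  expect_lt(mlr_fit(X, y0)$r_squared, 0.1)
})

test_that("MLR coefficients match the normal-equations oracle", {
  X <- random_design(40, 4, 2)
  set.seed(3)
  y <- X %*% c(1, -0.5, 0, 0.3) + rnorm(40)
  fit <- mlr_fit(X, y)
  Xs <- scale(X); ys <- as.numeric(scale(y))
  beta_oracle <- solve(t(Xs) %*% Xs, t(Xs) %*% ys)
  expect_equal(unname(fit$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-10)
})

test_that("rank-deficient predictors raise a collinearity signal naming them", {
  X <- random_design(50, 3, 4)
  X <- cbind(X, dup = X[, 1])
  err <- tryCatch(mlr_fit(X, rnorm(50)), error = function(e) e)
  expect_s3_class(err, "tggpp_error_collinearity")
  expect_match(conditionMessage(err), "dup")
})

test_that("weights of orthogonal predictors are squared correlations", {
  # exactly uncorrelated columns via Gram-Schmidt on centered draws
  raw <- random_design(60, 3, 5)
  Q <- qr.Q(qr(scale(raw, scale = FALSE)))
  X <- scale(Q); colnames(X) <- c("a", "b", "c")
  set.seed(6)
  y <- 1.5 * X[, 1] + 0.7 * X[, 2] + rnorm(60)
  rw <- relative_weights(X, y)
  r2 <- as.numeric(cor(X, y))^2
  expect_equal(unname(rw$raw_weights), r2, tolerance = 1e-8)
})

test_that("raw weights are non-negative and sum exactly to R squared", {
  for (seed in 1:25) {
    X <- random_design(45, 4, seed, rho = runif(1, 0, 0.8))
    y <- X %*% rnorm(4) + rnorm(45)
    rw <- relative_weights(X, y)
    expect_true(all(rw$raw_weights >= 0))
    expect_equal(sum(rw$raw_weights), rw$r_squared, tolerance = 1e-8)
    expect_equal(sum(rw$pct_weights), 100, tolerance = 1e-8)
  }
})

test_that("correlated duplicated signals split weight near-equally", {
  X <- random_design(500, 2, 7, rho = 0.9)
  set.seed(8)
  y <- X[, 1] + X[, 2] + rnorm(500, sd = 0.5)
  rw <- relative_weights(X, y)
  expect_equal(rw$raw_weights[[1]], rw$raw_weights[[2]], tolerance = 0.15)
  expect_equal(unname(rw$raw_weights), rwa_oracle(X, y), tolerance = 1e-8)
})

test_that("weights match the SVD-based step-by-step oracle on general designs", {
  for (seed in c(11, 12, 13)) {
    X <- random_design(35, 4, seed, rho = 0.6)
    set.seed(seed + 100)
    y <- X %*% c(0.5, 1, -0.3, 0.2) + rnorm(35)
    rw <- relative_weights(X, y)
    expect_equal(unname(rw$raw_weights), rwa_oracle(X, y), tolerance = 1e-8)
  }
})

test_that("weights are invariant to affine rescaling of predictor columns", {
  X <- random_design(50, 3, 14, rho = 0.5)
  set.seed(15)
  y <- X %*% c(1, 0.5, -1) + rnorm(50)
  a <- relative_weights(X, y)
  X2 <- X; X2[, 1] <- 10 * X2[, 1] - 4; X2[, 3] <- -0.2 * X2[, 3]
  b <- relative_weights(X2, y)
  expect_equal(unname(a$raw_weights), unname(b$raw_weights), tolerance = 1e-10)
})

test_that("a driver built into GPP dominates the attribution", {
  # GPP driven only by EVI: EVI takes > 90% of the explained variance
  set.seed(16)
  n <- 120
  evi <- runif(n, 0.2, 0.8)
  s <- make_series(n, evi = evi, lst = rnorm(n, 15, 5),
                   prc = rlnorm(n, log(60), 0.5), rad = rnorm(n, 15, 3),
                   gpp = 6 * evi + abs(rnorm(n, sd = 0.05)))
  out <- attribute_pft(s)
  expect_gt(out$rwa$pct_weights[["EVI"]], 90)
  expect_gt(out$evi_r_squared, 0.9)

  # a strong radiation co-driver outranks precipitation, across seeds
  wins <- vapply(1:10, function(sd) {
    p <- recovery_preset()
    p$rad_coeff <- 2
    site <- simulate_site(p, n_years = 10, seed = 300 + sd)
    rwa <- attribute_pft(site)$rwa
    rwa$pct_weights[["RAD"]] > rwa$pct_weights[["PRC"]]
  }, TRUE)
  expect_true(all(wins))
})

test_that("too few pooled months raises the no-data signal", {
  s <- make_series(10)
  expect_error(attribute_pft(s), class = "tggpp_error_no_data")
})
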