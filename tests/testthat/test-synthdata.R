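noise_free <- function(pft = "GRA") {
  p <- pft_presets(noise_frac = 0)[[pft]]
  p$snow_prob <- 0
  p
}

test_that("the generator and the model round-trip exactly without noise", {
  p <- noise_free()
  s <- simulate_site(p, n_years = 8, seed = 5)
  prod <- scale_evi(s$evi) * scale_lst(s$lst, p$params)
  m_hat <- fit_m(s$gpp, prod)
  expect_equal(m_hat, p$params$m, tolerance = 1e-10)
  expect_equal(m_hat * prod, s$gpp, tolerance = 1e-10)
})

test_that("simulation is reproducible and seeds differentiate sites", {
  p <- pft_presets()[["ENF"]]
  a <- simulate_site(p, n_years = 5, seed = 9)
  b <- simulate_site(p, n_years = 5, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_site(p, n_years = 5, seed = 10)
  expect_false(isTRUE(all.equal(a$gpp, c$gpp)))
})

test_that("simulated series are valid site series with plausible fields", {
  for (p in pft_presets()) {
    s <- simulate_site(p, n_years = 4, seed = 3)
    expect_s3_class(s, "site_series")
    expect_equal(nrow(s), 48L)
    expect_true(all(s$gpp >= 0))
    expect_true(all(s$evi >= 0 & s$evi <= 1))
    expect_true(all(s$prc > 0))
  }
})

test_that("snow flags fall only in the three coldest climatological months", {
  p <- pft_presets()[["DNF"]]   # snow-rich boreal preset
  s <- simulate_site(p, n_years = 30, seed = 8)
  mon <- as.integer(format(s$date, "%m"))
  expect_true(all(mon[s$snow_flag] %in% c(12, 1, 2)))
  expect_gt(sum(s$snow_flag), 0)
})

test_that("a preset truth beats the default parameters on its own data", {
  p <- pft_presets()[["EBF"]]
  s <- simulate_site(p, n_years = 10, seed = 13)
  rmse <- function(params) {
    prod <- scale_evi(s$evi) * scale_lst(s$lst, params)
    sqrt(mean((s$gpp - fit_m(s$gpp, prod) * prod)^2))
  }
  expect_gt(rmse(tg_params()), rmse(p$params))
})

test_that("cohorts have the right size, unique ids and a faithful manifest", {
  coh <- simulate_cohort(pft_presets(), sites_per_pft = 3, n_years = 3,
                         seed = 4)
  expect_length(coh$series, 36L)
  expect_equal(anyDuplicated(coh$manifest$site_id), 0L)
  expect_setequal(unique(coh$manifest$pft), pft_codes())
  ebf <- coh$manifest[coh$manifest$pft == "EBF", ][1, ]
  expect_equal(ebf$x_o, 15)
  coh2 <- simulate_cohort(pft_presets(), sites_per_pft = 3, n_years = 3,
                          seed = 4)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(as.data.frame(coh$series[[7]]),
                   as.data.frame(coh2$series[[7]]))
})

test_that("stronger precipitation forcing raises the PRC weight", {
  delta <- vapply(1:10, function(sd) {
    base <- recovery_preset()
    strong <- base; strong$prc_coeff <- 3
    w0 <- attribute_pft(simulate_site(base, 10, seed = 400 + sd))$rwa
    w1 <- attribute_pft(simulate_site(strong, 10, seed = 400 + sd))$rwa
    w1$pct_weights[["PRC"]] - w0$pct_weights[["PRC"]]
  }, 0)
  expect_true(all(delta > 0))
})

test_that("invalid presets are rejected", {
  expect_error(pft_preset("XXX", tg_params(), 10, 5, 0.4, 0.2),
               class = "tggpp_error_invalid_preset")
  expect_error(pft_preset("GRA", tg_params(), 10, 5, 0.9, 0.3),
               class = "tggpp_error_invalid_preset")
  expect_error(simulate_site(recovery_preset(), n_years = 1),
               class = "tggpp_error_invalid_preset")
})

test_that("site CSV write/read round-trips, including masks", {
  s <- qa_screen(simulate_site(pft_presets()[["ENF"]], 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_site_csv(s, path)
  back <- read_site_csv(path)
  expect_equal(site_id(back), site_id(s))
  expect_equal(site_pft(back), site_pft(s))
  expect_equal(back$gpp, s$gpp, tolerance = 1e-12)
  expect_identical(back$masked, s$masked)
  expect_identical(back$snow_flag, s$snow_flag)
})
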