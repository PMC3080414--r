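cgmp_truth <- function() one_site_params(n = 1, ka = 1 / 12e-9, dh = -12500)

test_that("the forward model obeys its structural identities", {
  d <- titration_design()
  zero <- simulate_titration(one_site_params(1, 1e8, dh = 1e-12), d)
  expect_true(all(abs(zero$heat_ucal) < 1e-6))

  base <- simulate_titration(one_site_params(1, 1e7, -10000), d)
  doubled <- simulate_titration(one_site_params(1, 1e7, -20000), d)
  expect_equal(doubled$heat_ucal, 2 * base$heat_ucal, tolerance = 1e-12)
  expect_equal(doubled$molar_ratio, base$molar_ratio)

  # scaling the cell and every injection together scales all heats linearly
  scaled <- titration_design(
    cell_volume = 2 * 1.43e-3, injection_volumes = rep(1e-5, 28)
  )
  h <- simulate_titration(one_site_params(1, 1e7, -10000), scaled)
  expect_equal(h$heat_ucal, 2 * base$heat_ucal, tolerance = 1e-9)
  expect_equal(h$molar_ratio, base$molar_ratio, tolerance = 1e-12)
})

test_that("the tight-binding limit approaches the stoichiometric heat", {
  # concentrated syringe keeps the injected-volume fraction small, where the
  # stoichiometric limit n*dH*M0*V0 applies
  d <- titration_design(
    cell_concentration = 15e-6, syringe_concentration = 2.5e-3,
    injection_volumes = rep(1e-6, 28)
  )
  cv <- simulate_titration(one_site_params(1, 1e15, -10000), d)
  expect_equal(
    sum(cv$heat_ucal) * 1e-6,
    -10000 * 15e-6 * 1.43e-3,
    tolerance = 0.02
  )
})

test_that("derived thermodynamics satisfy the defining identities", {
  expect_equal(derive_thermo(1, -500, 298)$dg, 0)
  th <- derive_thermo(1e8, -R_CAL * 310 * log(1e8), 310)
  expect_equal(th$ds, 0, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:50) {
    ka <- 10^stats::runif(1, 2, 12)
    dh <- stats::runif(1, -20000, 5000)
    temp <- stats::runif(1, 273, 330)
    th <- derive_thermo(ka, dh, temp)
    expect_equal(th$kd * ka, 1, tolerance = 1e-9)
    expect_equal(th$dg, -R_CAL * temp * log(ka), tolerance = 1e-9)
    expect_equal(th$ds * temp, dh - th$dg, tolerance = 1e-9)
  }
  expect_error(derive_thermo(-1, 0, 300), class = "cnbdkit_domain_error")
})

test_that("fitting a noiseless simulation returns the generating parameters", {
  d <- titration_design()
  truth <- cgmp_truth()
  fit <- fit_one_site(simulate_titration(truth, d))
  expect_true(fit$converged)
  expect_equal(fit$params$n, 1, tolerance = 1e-3)
  expect_equal(fit$params$ka, truth$ka, tolerance = 1e-3)
  expect_equal(fit$params$dh, truth$dh, tolerance = 1e-3)
  expect_equal(fit$kd, 1 / fit$params$ka, tolerance = 1e-12)
  expect_equal(fit$c_value, fit$params$n * fit$params$ka * 15e-6)
  g <- glance(fit)
  expect_equal(g$kd, fit$kd)
  td <- tidy(fit)
  expect_equal(td$term, c("n", "ka", "dh"))
})

test_that("fit recovery holds across the c grid and with a discarded first point", {
  d <- titration_design()
  for (cc in c(1, 10, 100, 1000)) {
    truth <- one_site_params(1, cc / 15e-6, -11000)
    fit <- fit_one_site(simulate_titration(truth, d))
    expect_equal(fit$params$n, 1, tolerance = 1e-3)
    expect_equal(fit$params$ka, truth$ka, tolerance = 1e-3)
    expect_equal(fit$params$dh, truth$dh, tolerance = 1e-3)
  }
  fit2 <- fit_one_site(simulate_titration(cgmp_truth(), d), discard_first = TRUE)
  expect_equal(fit2$params$dh, -12500, tolerance = 1)
  expect_false(fit2$fitted$used[1])
})

test_that("reported Ka uncertainty grows when c leaves the tractable window", {
  d <- titration_design()
  well <- one_site_params(1, 10 / 15e-6, -12500)
  steep <- one_site_params(1, 1250 / 15e-6, -12500)
  f_well <- fit_one_site(noisy_titration(well, d, heat_sigma = 0.05, seed = 2))
  f_steep <- fit_one_site(noisy_titration(steep, d, heat_sigma = 0.05, seed = 2))
  rel_well <- f_well$ka_se / f_well$params$ka
  rel_steep <- f_steep$ka_se / f_steep$params$ka
  expect_gt(rel_steep, rel_well)
})

test_that("noisy median recovery at c = 10 stays within ten percent", {
  d <- titration_design()
  truth <- one_site_params(1, 10 / 15e-6, -12000)
  kas <- vapply(1:200, function(s) {
    fit_one_site(noisy_titration(truth, d, heat_sigma = 0.1, seed = s))$params$ka
  }, numeric(1))
  expect_equal(stats::median(kas), truth$ka, tolerance = 0.1)
})

test_that("titration tables round-trip through delimited text", {
  d <- titration_design()
  cv <- noisy_titration(cgmp_truth(), d, heat_sigma = 0.2, seed = 9)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "volume_ul\theat_ucal",
    paste(cv$injection_volume * 1e6, cv$heat_ucal, sep = "\t")
  ), tf)
  back <- read_titration(tf, design = d)
  expect_equal(back$heat_ucal, cv$heat_ucal, tolerance = 1e-9)
  expect_equal(back$injection_volume, cv$injection_volume, tolerance = 1e-12)
  fit <- fit_one_site(back)
  expect_equal(fit$kd, 12e-9, tolerance = 0.1)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5 not_a_number", "5 xx"), bad)
  expect_error(read_titration(bad), class = "cnbdkit_parse_error")
})

test_that("design and parameter validation reject impossible inputs", {
  expect_error(titration_design(cell_concentration = 0),
    class = "cnbdkit_domain_error"
  )
  expect_error(titration_design(injection_volumes = 5e-6),
    class = "cnbdkit_domain_error"
  )
  expect_error(one_site_params(0, 1e6, -1), class = "cnbdkit_domain_error")
  expect_error(one_site_params(1, -5, -1), class = "cnbdkit_domain_error")
})
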