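test_that("CSF forms evaluate their defining equations", {
  lp <- csf_params("LP", alpha = 2, beta = 1, delta = 100)
  expect_equal(csf_sensitivity(lp, 2), 100)           # f = alpha -> delta
  expect_equal(csf_sensitivity(lp, 4), 100 * exp(-1)) # hand oracle
  de <- csf_params("dEXP", alpha = 0, beta = 3, delta = 40)
  f <- c(0.5, 2, 8)
  expect_equal(csf_sensitivity(de, f), 40 * exp(-f / 3)) # f^0 = 1
  dog <- csf_params("DoG", alpha = 3, beta = 1, gamma = 0, delta = 60)
  expect_equal(csf_sensitivity(dog, 1e-8), 60, tolerance = 1e-9)
})

test_that("canonical stand-in forms are pinned to their formulas", {
  f <- c(0.5, 1.7, 4, 12)
  alp <- csf_params("aLP", alpha = 3, beta = 1.5, gamma = 0.8, delta = 50)
  expect_equal(csf_sensitivity(alp, f),
               ifelse(f < 3, 50 * exp(-(log2(f / 3) / 1.5)^2),
                      50 * exp(-(log2(f / 3) / 0.8)^2)))
  ms <- csf_params("MS", alpha = 4, beta = 0.6, gamma = 2, delta = 70)
  expect_equal(csf_sensitivity(ms, f),
               pmax(70 * (1 - 0.6 + f / 4) * exp(-(f / 4)^2), 0))
  yqm <- csf_params("YQM", alpha = 8, beta = 1, gamma = 4, delta = 90)
  expect_equal(csf_sensitivity(yqm, f),
               90 * exp(-f / 8) / (1 + 4 / (1 + (f / 1)^2)))
  hmh <- csf_params("HmH", alpha = 4, beta = 1, gamma = 0.5, delta = 30)
  expect_equal(csf_sensitivity(hmh, f),
               pmax(30 * (1 / cosh(f / 4) - 0.5 / cosh(f / 1)), 0))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(csf_params("nope", 1, 1, delta = 10), "arg")
  expect_error(csf_params("LP", alpha = -1, beta = 1, delta = 10), "alpha")
  expect_error(csf_params("DoG", 1, 1, gamma = NA, delta = 10), "gamma")
  expect_error(csf_params("LP", 1, 1, delta = 0), "delta")
  expect_error(csf_sensitivity(csf_params("LP", 1, 1, delta = 10), -2), "f must")
})

test_that("all nine forms are finite and non-negative across the window", {
  f <- 10^seq(log10(0.25), log10(24), length.out = 200)
  set.seed(21)
  for (model in csf_models()) {
    b <- csfield:::csf_bounds(model)
    for (i in 1:20) {
      draw <- lapply(b, function(r) runif(1, r[1], r[2]))
      p <- csf_params(model, alpha = draw$alpha, beta = draw$beta,
                      gamma = draw$gamma %||% NA_real_, delta = draw$delta)
      s <- csf_sensitivity(p, f)
      expect_true(all(is.finite(s)), info = model)
      expect_true(all(s >= 0), info = model)
    }
  }
})

test_that("LP attributes match the closed forms to 1e-6", {
  p <- csf_params("LP", alpha = 2, beta = 1, delta = 100)
  a <- extract_attributes(p)
  cf <- lp_closed_form(2, 1, 100)
  expect_equal(a$peak_sf, cf$peak_sf, tolerance = 1e-6)
  expect_equal(a$peak_cs, cf$peak_cs, tolerance = 1e-6)
  expect_equal(a$cutoff_sf, cf$cutoff_sf, tolerance = 1e-6)
  expect_equal(a$cutoff_sf, 8.85, tolerance = 1e-3)
  expect_equal(a$bandwidth, cf$bandwidth, tolerance = 1e-6)
  expect_equal(a$aulcsf, cf$aulcsf, tolerance = 1e-4) # trapezoid resolution
  # a second parameterisation, partially truncated by the window
  p2 <- csf_params("LP", alpha = 1, beta = 2.5, delta = 30)
  a2 <- extract_attributes(p2)
  cf2 <- lp_closed_form(1, 2.5, 30)
  expect_equal(a2$cutoff_sf, min(cf2$cutoff_sf, 24), tolerance = 1e-6)
  expect_equal(a2$aulcsf, cf2$aulcsf, tolerance = 1e-4)
})

test_that("delta scaling moves peak_cs proportionally, peak_sf not at all", {
  base <- csf_params("DoG", alpha = 6, beta = 1.5, gamma = 0.4, delta = 50)
  a1 <- extract_attributes(base)
  k <- 3.7
  a2 <- extract_attributes(csf_params("DoG", 6, 1.5, gamma = 0.4, delta = 50 * k))
  expect_equal(a2$peak_cs, k * a1$peak_cs, tolerance = 1e-8)
  expect_equal(a2$peak_sf, a1$peak_sf, tolerance = 1e-6)
})

test_that("attributes converge under grid refinement", {
  set.seed(4)
  for (model in c("LP", "DoG", "EmG", "YQM")) {
    b <- csfield:::csf_bounds(model)
    p <- csf_params(model,
                    alpha = runif(1, 1, 8), beta = runif(1, max(b$beta[1], 0.5), 4),
                    gamma = if (is.null(b$gamma)) NA_real_ else runif(1, b$gamma[1], min(b$gamma[2], 0.8)),
                    delta = runif(1, 30, 200))
    aN <- extract_attributes(p, n_grid = 512)
    a2N <- extract_attributes(p, n_grid = 1024)
    for (col in c("peak_cs", "peak_sf", "aulcsf")) {
      expect_lt(abs(aN[[col]] - a2N[[col]]) / max(abs(a2N[[col]]), 1e-12), 0.005)
    }
  }
})

test_that("cutoff sentinel and edge flags behave", {
  # peak below 1 everywhere: no unit crossing
  weak <- extract_attributes(csf_params("LP", 2, 1, delta = 1) )
  expect_true(weak$peak_cs <= 1 + 1e-9)
  low <- extract_attributes(csf_params("LP", alpha = 2, beta = 1, delta = 0.5))
  expect_true(is.na(low$cutoff_sf))
  # sensitivity still above 1 at 24 cpd: cutoff clamped and flagged
  wide <- extract_attributes(csf_params("LP", alpha = 8, beta = 4, delta = 500))
  expect_true(wide$cutoff_at_edge)
  expect_equal(wide$cutoff_sf, 24)
  # monotone-decreasing shape peaks at the window edge
  mono <- extract_attributes(csf_params("dEXP", alpha = 0, beta = 2, delta = 50))
  expect_true(mono$peak_at_edge)
})
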