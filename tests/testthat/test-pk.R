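test_that("concentration is zero before the first dose (causality)", {
  p <- pkParams(ka = 1, ke = 0.1, V = 1, doseAmount = 100)
  s <- simulateProfile(p, doseEvents(5, 100), timeGrid = 0:24)
  expect_true(all(concentrations(s)[obsTimes(s) < 5] == 0))
  expect_true(all(concentrations(s)[obsTimes(s) > 5] > 0))
})

test_that("closed form matches a numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- pkParams(ka = 1, ke = 0.1, V = 1, F = 1, fu = 1, doseAmount = 100)
  cf <- concentrations(simulateProfile(p, doseEvents(0, 100), 1:24))
  # two-state absorption/elimination system, dose in the gut at t = 0
  rhs <- function(t, y, pr)
    list(c(-pr["ka"] * y[1], pr["ka"] * y[1] - pr["ke"] * y[2]))
  out <- deSolve::ode(y = c(A = 100, C = 0), times = 0:24, func = rhs,
                      parms = c(ka = 1, ke = 0.1), rtol = 1e-10, atol = 1e-12)
  ode_c <- out[match(1:24, out[, "time"]), "C"]
  expect_lt(max(abs(cf - ode_c) / ode_c), 1e-6)
})

test_that("PK is linear in dose and superposes across dose events", {
  p1 <- pkParams(ka = 1.3, ke = 0.15, V = 2, doseAmount = 50)
  p2 <- pkParams(ka = 1.3, ke = 0.15, V = 2, doseAmount = 100)
  grid <- seq(0, 48, by = 0.5)
  c1 <- concentrations(simulateProfile(p1, doseEvents(0, 50), grid))
  c2 <- concentrations(simulateProfile(p2, doseEvents(0, 100), grid))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)

  both <- simulateProfile(p1, doseEvents(c(0, 24), c(50, 50)), grid)
  d1 <- simulateProfile(p1, doseEvents(0, 50), grid)
  d2 <- simulateProfile(p1, doseEvents(24, 50), grid)
  expect_equal(concentrations(both),
               concentrations(d1) + concentrations(d2), tolerance = 1e-12)
})

test_that("concentration decays to near zero long after dosing", {
  p <- pkParams(ka = 2, ke = 0.3, V = 1, doseAmount = 100)
  tt <- c(seq(0, 10, 0.1), 50 / 0.3)
  s <- simulateProfile(p, doseEvents(0, 100), tt)
  cc <- concentrations(s)
  expect_lt(cc[length(cc)], 1e-6 * max(cc))
})

test_that("degenerate and under-determined inputs are rejected", {
  expect_error(pkParams(ka = 0.1, ke = 0.1, V = 1), "differ|exceed")
  p <- pkParams(ka = 1, ke = 0.1, V = 1, doseAmount = 100)
  expect_error(simulateProfile(p, doseEvents(0, 100), numeric(0)), "non-empty")
  short <- concentrationSeries(1:3, c(5, 4, 3))
  expect_error(fitPKParams(short), "4 positive")
  zeros <- concentrationSeries(1:10, c(5, 4, 3, rep(0, 7)))
  expect_error(fitPKParams(zeros), "4 positive")
})

test_that("noise-free parameter recovery is exact to within 1%", {
  truth <- pkParams(ka = 1.2, ke = 0.12, V = 1, F = 1, fu = 1,
                    doseAmount = 200)  # dose/V * F * fu = 200 nM
  obs <- simulateProfile(truth, doseEvents(0, 200), 1:24)
  obs <- concentrationSeries(obsTimes(obs), concentrations(obs))
  fit <- fitPKParams(obs, dose = doseEvents(0, 200))
  expect_true(fit$converged)
  expect_lt(abs(fit$params@ka - 1.2) / 1.2, 0.01)
  expect_lt(abs(fit$params@ke - 0.12) / 0.12, 0.01)
})

test_that("ke is recovered within 15% under multiplicative noise", {
  truth <- pkParams(ka = 1.2, ke = 0.12, V = 1, doseAmount = 200)
  clean <- simulateProfile(truth, doseEvents(0, 200), 1:24)
  set.seed(20240811)
  noisy <- concentrationSeries(
    obsTimes(clean), concentrations(clean) * exp(rnorm(24, 0, 0.1)))
  fit <- fitPKParams(noisy, dose = doseEvents(0, 200))
  expect_true(fit$converged)
  expect_lt(abs(fit$params@ke - 0.12) / 0.12, 0.15)
})

test_that("refitting from recovered parameters does not worsen the fit", {
  truth <- pkParams(ka = 0.9, ke = 0.2, V = 1, doseAmount = 150)
  clean <- simulateProfile(truth, doseEvents(0, 150), 1:24)
  set.seed(7)
  noisy <- concentrationSeries(
    obsTimes(clean), concentrations(clean) * exp(rnorm(24, 0, 0.15)))
  f1 <- fitPKParams(noisy, dose = doseEvents(0, 150))
  f2 <- fitPKParams(noisy, dose = doseEvents(0, 150), init = f1$params)
  expect_lte(f2$residualNorm, f1$residualNorm + 1e-8)
})

test_that("fit to the packaged ATMi series reproduces the observed peak", {
  az <- referenceSeries("AZD0156")
  fit <- fitPKParams(az, dose = doseEvents(0, 1))
  expect_true(fit$converged)
  sim <- simulateProfile(fit$params, doseEvents(0, 1), seq(0, 24, 0.01))
  obs_max <- max(concentrations(az))
  expect_lt(abs(max(concentrations(sim)) - obs_max) / obs_max, 0.05)
})

test_that("fitted parameters round-trip through the key-value config", {
  p <- pkParams(ka = 1.5, ke = 0.2, V = 3, F = 0.8, fu = 0.5,
                doseAmount = 10)
  f <- tempfile(fileext = ".yaml")
  writePKParams(p, f)
  q <- readPKParams(f)
  expect_equal(q@ka, p@ka)
  expect_equal(q@ke, p@ke)
  expect_equal(q@V, p@V)
  expect_equal(q@fu, p@fu)
})
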