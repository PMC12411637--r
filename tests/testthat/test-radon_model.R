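dry_nodules <- radon_material_props(c_ra226 = 2317)
cargo_hold <- radon_environment(volume = 4500, area = 900, ventilation = 1)

test_that("bulk diffusion is molecular diffusion scaled by porosity", {
  expect_equal(bulk_diffusion(dry_nodules), 6e-6)
})

test_that("exhalation rate for dry nodules is ~10 Bq/(m2 s)", {
  P <- exhalation_rate(dry_nodules)
  expect_equal(P, 2317 * 0.36 * 3300 * sqrt(6e-6 / 2.1e-6) * 2.1e-6)
  expect_equal(round(P), 10)
})

test_that("exhalation scales as sqrt(D_bulk) and vanishes without emanation", {
  quad <- radon_material_props(2317, d_ma = 4e-5)  # 4x D_bulk
  expect_equal(exhalation_rate(quad), 2 * exhalation_rate(dry_nodules))
  none <- radon_material_props(2317, emanation = 0)
  expect_equal(exhalation_rate(none), 0)
  # wet nodules exhale about half as much: halved P halves the
  # surface-driven steady-state concentration
  P <- exhalation_rate(dry_nodules)
  c_dry <- steady_state_concentration(entry_rate_surface(P, cargo_hold),
                                      cargo_hold)
  c_wet <- steady_state_concentration(entry_rate_surface(P / 2, cargo_hold),
                                      cargo_hold)
  expect_equal(c_wet, c_dry / 2)
})

test_that("material property validation rejects non-physical inputs", {
  expect_error(radon_material_props(-1))
  expect_error(radon_material_props(2317, emanation = 1.5))
  expect_error(radon_material_props(2317, porosity = 0))
  expect_error(radon_material_props(2317, bulk_density = -3300))
})

test_that("surface entry rate is P*A/V with the expected cargo-hold value", {
  P <- exhalation_rate(dry_nodules)
  e <- entry_rate_surface(P, cargo_hold)
  expect_equal(e, P * 900 / 4500)
  expect_equal(round(e), 2)
  # A -> 0 limit via a tiny area; doubling V halves e'
  tiny <- radon_environment(4500, 1e-9, 1)
  expect_lt(entry_rate_surface(P, tiny), 1e-11)
  big <- radon_environment(9000, 900, 1)
  expect_equal(entry_rate_surface(P, big), e / 2)
})

test_that("comminution source term reproduces the published 66 kBq/s chain", {
  hall <- radon_environment(45000, area = 3000, ventilation = 10)
  src <- comminution_source(pc = 95)
  out <- entry_rate_comminution(nodules, src, hall)
  expect_equal(out$R_source, 2317 * 0.3 * 95)
  expect_equal(round(out$R_source / 1000), 66)
  expect_equal(out$e_prime, out$R_source * 0.5 / 45000)
  expect_equal(round(out$e_prime, 2), 0.73)
  # no comminution release -> no source
  none <- entry_rate_comminution(nodules, comminution_source(95, f_com = 0),
                                 hall)
  expect_equal(none$R_source, 0)
  expect_error(
    entry_rate_comminution(nuclide_vector(c("Pb-210" = 1)), src, hall),
    "Ra-226")
})

test_that("steady state reproduces the published indoor concentrations", {
  P <- exhalation_rate(dry_nodules)
  e <- entry_rate_surface(P, cargo_hold)
  # natural ventilation 1/h -> ~7000 Bq/m3 in the hold head space
  expect_equal(round(steady_state_concentration(e, cargo_hold), -3), 7000)
  # opened hold, 24/h -> ~300 Bq/m3
  vented <- radon_environment(4500, 900, 24)
  expect_equal(round(steady_state_concentration(e, vented), -2), 300)
  # production hall: 66 kBq/s source, half indoors, 45000 m3, 10/h -> ~264
  hall <- radon_environment(45000, 3000, 10)
  e_hall <- entry_rate_comminution(nodules, comminution_source(pc = 95),
                                   hall)$e_prime
  expect_equal(round(steady_state_concentration(e_hall, hall)), 264)
})

test_that("steady state has the correct ventilation limits", {
  e <- 2
  sealed <- radon_environment(4500, 900, 0)
  expect_equal(steady_state_concentration(e, sealed), e / LAMBDA_RN222)
  gale <- radon_environment(4500, 900, 1e9, vent_unit = "per_second")
  expect_lt(steady_state_concentration(e, gale), 1e-6)
  # strictly decreasing in v
  vs <- c(0.5, 1, 2, 6, 24)
  cs <- vapply(vs, function(v) {
    steady_state_concentration(e, radon_environment(4500, 900, v))
  }, numeric(1))
  expect_true(all(diff(cs) < 0))
  # outdoor radon adds v*C_a to the source balance
  outdoor <- radon_environment(4500, 900, 24, outdoor_conc = 10)
  base <- radon_environment(4500, 900, 24)
  expect_gt(steady_state_concentration(e, outdoor),
            steady_state_concentration(e, base))
})

test_that("transient solution has the right limits and satisfies the ODE", {
  e <- 2
  env <- radon_environment(4500, 900, 1)
  c_ss <- steady_state_concentration(e, env)
  expect_equal(transient_concentration(e, env, c0 = 123, t = 0), 123)
  # ten relaxation times from empty: within 0.005% of steady state
  k <- LAMBDA_RN222 + 1 / 3600
  c10 <- transient_concentration(e, env, 0, 10 / k)
  expect_equal(c10, c_ss, tolerance = 5e-5)
  # no source, no ventilation: pure radioactive decay
  sealed <- radon_environment(4500, 900, 0)
  t <- c(0, 1e5, 5e5)
  expect_equal(transient_concentration(0, sealed, 1000, t),
               1000 * exp(-LAMBDA_RN222 * t))
  expect_error(transient_concentration(e, env, 0, -1), ">= 0")

  # independent small-step integrator oracle (lsoda on the balance ODE)
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) {
    list(parms$e + parms$v * parms$ca - (parms$lambda + parms$v) * y)
  }
  parms <- list(e = e, v = 1 / 3600, ca = 0, lambda = LAMBDA_RN222)
  times <- seq(0, 4 * 3600, by = 60)
  num <- deSolve::lsoda(c(C = 500), times, rhs, parms,
                        rtol = 1e-10, atol = 1e-8)[, "C"]
  ana <- transient_concentration(e, env, 500, times)
  expect_lt(max(abs(num - ana) / pmax(ana, 1)), 1e-6)
})

test_that("radon dose reproduces the published 1.87 mSv/a and is linear", {
  ref <- radon_dose_config(c_rn = 300, t_exp = 2000)
  expect_equal(round(radon_dose(ref), 2), 1.87)
  expect_equal(radon_dose(ref), 300 * 2000 * 0.4 * 7.8e-6)
  expect_equal(radon_dose(radon_dose_config(300, 0)), 0)
  # linearity in each factor
  expect_equal(radon_dose(radon_dose_config(600, 2000)), 2 * radon_dose(ref))
  expect_equal(radon_dose(radon_dose_config(300, 1000)), radon_dose(ref) / 2)
  expect_equal(radon_dose(radon_dose_config(300, 2000,
                                            equilibrium_factor = 0.8)),
               2 * radon_dose(ref))
})

test_that("ordinance unit-exposure rule: 0.32 MBq h/m3 corresponds to 1 mSv", {
  # unit-algebra oracle: an integrated radon gas exposure C*t of
  # 0.32e6 Bq h/m3 at F = 0.4 and the ICRP 65 coefficient gives ~1 mSv
  dose <- radon_dose(radon_dose_config(c_rn = 0.32e6, t_exp = 1))
  expect_equal(dose, 0.32e6 * 1 * 0.4 * DCF_ICRP65)
  expect_equal(dose, 1, tolerance = 0.002)
})
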