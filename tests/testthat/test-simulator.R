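test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(dt = 0.02), "dt <= Tr/20")
  expect_error(simulation_config(n_cycles = 1), "n_cycles > discard_cycles")
  expect_error(simulation_config(n_cycles = 3, discard_cycles = 0),
               "discard_cycles >= 1")
  expect_error(simulation_config(compliance = -1))
  expect_error(update_config(simulation_config(), "XYZ", 1), "unknown parameter")
  # update rebuilds derived SI fields
  cfg2 <- update_config(simulation_config(), "d", 4.0)
  expect_equal(cfg2$geom$Ae, pi * (4e-3)^2 / 4)
})

test_that("trace satisfies its structural invariants", {
  cfg <- fast_config()
  tr <- simulate_pcv(cfg)
  per <- cycle_period(cfg$settings)
  expect_s3_class(tr, "pcv_trace")
  expect_equal(nrow(tr), round(cfg$n_cycles * per / cfg$dt) + 1)
  expect_named(tr, c("t", "p_vent", "p_lung", "q", "Q", "Re", "lambda",
                     "Rr", "p_loss"))
  # p_loss column is the actual throttle drop at every sample
  expect_equal(tr$p_loss, abs(tr$p_vent - tr$p_lung))
  # q = rho_std * Q exactly (Q reported in L/s)
  expect_equal(tr$q, 1.2 * tr$Q * 1e-3, tolerance = 1e-15)
  # flow direction follows the drive difference
  expect_true(all(sign(tr$q) == sign(tr$p_vent - tr$p_lung)))
  # lambda defined whenever there is flow, NA otherwise
  expect_true(all(is.na(tr$lambda) == (tr$Re == 0)))
  expect_true(all(tr$Rr > 0))
})

test_that("the fixed-step integrator matches an independent RK4 solver", {
  cfg <- fast_config()
  tr <- simulate_pcv(cfg)
  gas <- cfg$gas
  RT <- gas$R_specific * gas$T
  p0 <- gas$p_atm + cfg$epap * CMH2O_PA
  rhs <- function(t, y, parms) {
    pv <- gas$p_atm + CMH2O_PA * pcv_pressure(cfg$settings, t)
    dp <- pv - y
    pu <- pmax(pv, y)
    phi <- pmin(pv, y) / pu
    q <- sign(dp) * 0.0048 * cfg$geom$Ae * pu * sqrt(phi * (1 - phi))
    list(RT * q / (cfg$V0_si + cfg$C_si * (2 * y - p0)))
  }
  oracle <- deSolve::ode(y = p0, times = tr$t, func = rhs, parms = NULL,
                         method = "rk4")
  expect_lt(max(abs(oracle[, 2] - (gas$p_atm + tr$p_lung * CMH2O_PA))), 1e-6)
})

test_that("lung pressure lags the ventilator and stays within the plateaus", {
  cfg <- simulation_config(dt = 5e-4)
  tr <- simulate_pcv(cfg)
  per <- attr(tr, "period")
  for (k in cfg$discard_cycles:(cfg$n_cycles - 1)) {
    w <- tr$t >= k * per - 1e-9 & tr$t <= (k + 1) * per + 1e-9
    t_pk_vent <- tr$t[w][which.max(tr$p_vent[w])]
    t_pk_lung <- tr$t[w][which.max(tr$p_lung[w])]
    expect_gte(t_pk_lung, t_pk_vent)
  }
  eps <- 0.005 * (cfg$ipap - cfg$epap)
  post <- tr$t >= cfg$discard_cycles * per
  expect_true(all(tr$p_lung[post] >= cfg$epap - eps))
  expect_true(all(tr$p_lung[post] <= cfg$ipap + eps))
  expect_true(attr(tr, "converged"))
})

test_that("pressure rate along the trace is self-consistent with the model", {
  cfg <- simulation_config(dt = 5e-4)
  tr <- simulate_pcv(cfg)
  gas <- cfg$gas
  RT <- gas$R_specific * gas$T
  pabs <- gas$p_atm + tr$p_lung * CMH2O_PA
  V <- cfg$V0_si + cfg$C_si * (pabs - pabs[1])
  rate <- RT * tr$q / (V + cfg$C_si * pabs)
  num <- diff(pabs) / diff(tr$t) # centred between samples
  mid <- (rate[-1] + rate[-length(rate)]) / 2
  w <- which(tr$t[-1] >= 3 & tr$t[-1] <= 6)
  rms <- sqrt(mean((num[w] - mid[w])^2)) / sqrt(mean(mid[w]^2))
  expect_lt(rms, 0.01)
})

test_that("breath summary extracts consistent extrema", {
  tr <- simulate_pcv(fast_config())
  s <- breath_summary(tr)
  expect_s3_class(s, "breath_summary")
  expect_lte(s$p_min, s$p_peak)
  expect_gt(s$Q_peak_insp, 0)
  expect_gt(s$Q_peak_exp, 0)
  expect_gt(s$tidal_volume, 0)
  # at vanishing flow the resistance is pinned at the laminar floor
  gas <- gas_properties()
  geom <- throttle_geometry()
  floor_cl <- 128 * gas$mu * geom$l / (pi * geom$d^4) / RR_SI_PER_CLINICAL
  expect_equal(s$Rr_min, floor_cl, tolerance = 1e-9)
  expect_gt(s$Rr_max_insp, s$Rr_min)
  expect_gt(s$Rr_max_exp, s$Rr_min)
})

test_that("sweeps preserve ordering and reproduce the sensitivity directions", {
  cfg <- fast_config()
  sw <- sweep_parameter(cfg, "IPAP", c(18, 22, 24))
  expect_equal(sw$value, c(18, 22, 24))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$p_peak) > 0))
  swE <- sweep_parameter(cfg, "EPAP", c(4, 6, 8))
  expect_true(all(diff(swE$p_min) > 0))
  swC <- sweep_parameter(cfg, "C", c(5, 10, 15))
  expect_true(all(diff(swC$p_peak) <= 1e-9)) # non-increasing in C
  swd <- sweep_parameter(cfg, "d", c(2.4, 3.2, 4.0))
  expect_true(all(diff(swd$p_peak) >= -1e-9)) # non-decreasing in d
})

test_that("threshold finder returns boundary values and handles edge cases", {
  cfg <- simulation_config(dt = 2e-3, n_cycles = 2)
  # a single passing value is returned as the threshold
  expect_equal(as.numeric(threshold_find(cfg, "C", 5)), 5)
  # no scanned value reaching IPAP yields NA with a message (the short,
  # far-from-steady run also warns about convergence, which is expected here)
  expect_message(res <- suppressWarnings(threshold_find(cfg, "d", 1.6)),
                 "no scanned")
  expect_true(is.na(res))
  expect_s3_class(attr(res, "sweep"), "data.frame")
  expect_error(threshold_find(cfg, "C", numeric(0)), "empty")
  expect_error(threshold_find(cfg, "C", c(10, 5)), "sorted")
})

test_that("a run still far from periodic steady state is flagged", {
  cfg <- simulation_config(compliance = 120, dt = 1e-3, n_cycles = 2)
  expect_warning(tr <- simulate_pcv(cfg), "periodic steady state")
  expect_false(attr(tr, "converged"))
})
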