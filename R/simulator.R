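# Closed-loop time integration of ventilator -> throttle -> lung, per-breath
# summaries, one-at-a-time parameter sweeps and peak-pressure threshold
# finders.

#' Configuration of a simulation run
#'
#' Bundles the ventilator settings, gas properties, throttle geometry, lung
#' parameters and integrator controls, all in clinical units. Defaults are
#' the baseline operating point: IPAP 22 / EPAP 4 cmH2O, 20 breaths/min,
#' Ti 1 s, Tr 0.2 s, compliance 10 mL/cmH2O, orifice diameter 3.2 mm,
#' throttle length 10 mm, resident volume 1 L, classical RK4 with
#' dt = 1e-4 s over 4 cycles of which the first is discarded as transient.
#'
#' @param ipap,epap,bpm,ti,tr ventilator settings, see
#'   [ventilator_settings()].
#' @param compliance respiratory compliance, mL/cmH2O.
#' @param d equivalent orifice diameter, mm.
#' @param l throttle length, mm (Darcy resistance bookkeeping only).
#' @param v0 resident gas volume of the container at the start of the run, L.
#'   The dynamics depend on `V + C p` and the pneumatic capacity
#'   `C p` (about 10 L at the defaults) dominates, so the result is
#'   insensitive to this choice.
#' @param dt integrator step, s; must not exceed `tr / 20`.
#' @param n_cycles breaths to simulate.
#' @param discard_cycles initial breaths dropped from all summaries
#'   (transient; the run starts from `p_lung = EPAP`).
#' @param gas a [gas_properties()] object.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config()
#' @export
simulation_config <- function(ipap = 22, epap = 4, bpm = 20, ti = 1,
                              tr = 0.2, compliance = 10, d = 3.2, l = 10,
                              v0 = 1, dt = 1e-4, n_cycles = 4,
                              discard_cycles = 1, gas = gas_properties()) {
  settings <- ventilator_settings(ipap = ipap, epap = epap, bpm = bpm,
                                  ti = ti, tr = tr)
  stopifnot(compliance > 0, d > 0, l > 0, v0 > 0, dt > 0)
  if (dt > tr / 20) {
    stop("integrator step too coarse: need dt <= Tr/20 = ", tr / 20, " s")
  }
  n_cycles <- as.integer(n_cycles)
  discard_cycles <- as.integer(discard_cycles)
  if (!(n_cycles > discard_cycles && discard_cycles >= 1)) {
    stop("need n_cycles > discard_cycles >= 1")
  }
  structure(
    list(ipap = ipap, epap = epap, bpm = bpm, ti = ti, tr = tr,
         compliance = compliance, d = d, l = l, v0 = v0, dt = dt,
         n_cycles = n_cycles, discard_cycles = discard_cycles,
         gas = gas,
         settings = settings,
         geom = throttle_geometry(d = d * 1e-3, l = l * 1e-3),
         C_si = compliance * COMPLIANCE_SI_PER_CLINICAL,
         V0_si = v0 * 1e-3),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  print(x$settings)
  cat(sprintf("  C = %g mL/cmH2O, d = %g mm, l = %g mm, V0 = %g L\n",
              x$compliance, x$d, x$l, x$v0))
  cat(sprintf("  RK4 dt = %g s, %d cycles (%d discarded)\n",
              x$dt, x$n_cycles, x$discard_cycles))
  invisible(x)
}

#' Replace one parameter of a simulation configuration
#'
#' Rebuilds the configuration (revalidating all invariants) with a single
#' field replaced. Parameter names follow the conventional symbols:
#' `"IPAP"`, `"EPAP"`, `"BPM"`, `"Ti"`, `"Tr"`, `"C"` (compliance,
#' mL/cmH2O), `"d"` (orifice diameter, mm).
#'
#' @param config a [simulation_config()] object.
#' @param param parameter name (see above).
#' @param value new value in the parameter's clinical unit.
#' @return A new `simulation_config`.
#' @export
update_config <- function(config, param, value) {
  stopifnot(inherits(config, "simulation_config"))
  field <- .sweep_fields[[param]]
  if (is.null(field)) {
    stop("unknown parameter '", param, "'; expected one of ",
         paste(names(.sweep_fields), collapse = ", "))
  }
  args <- config[c("ipap", "epap", "bpm", "ti", "tr", "compliance", "d",
                   "l", "v0", "dt", "n_cycles", "discard_cycles", "gas")]
  args[[field]] <- value
  do.call(simulation_config, args)
}

.sweep_fields <- list(IPAP = "ipap", EPAP = "epap", BPM = "bpm", Ti = "ti",
                      Tr = "tr", C = "compliance", d = "d")

#' Simulate the ventilator-throttle-lung system
#'
#' Integrates the closed loop with a fixed-step classical Runge-Kutta scheme:
#' at every instant the throttle carries the orifice flow of
#' [mass_flow_simplified()] between the ventilator waveform pressure
#' ([pcv_pressure()]) and the container, whichever is higher being upstream,
#' and the container pressure obeys the isothermal rate of
#' [pressure_derivative()] with volume slaved to pressure through
#' `dV = C dp`. The run starts from `p_lung = EPAP`.
#'
#' Periodic steady state is checked by comparing the peak lung pressure of
#' the last two cycles (relative change below 0.1%); failure flags the trace
#' (`attr(trace, "converged")`) and raises a warning.
#'
#' @param config a [simulation_config()] object.
#' @return A data frame of class `pcv_trace` with one row per time sample and
#'   columns `t` (s), `p_vent` and `p_lung` (cmH2O gauge), `q` (kg/s,
#'   signed, positive into the lung), `Q` (L/s at standard state), `Re`,
#'   `lambda` (`NA` at zero flow), `Rr` (cmH2O/(L/s)), and `p_loss` (cmH2O,
#'   the actual throttle drop `|p_vent - p_lung|`). The configuration,
#'   cycle period and convergence flag travel as attributes.
#' @examples
#' tr <- simulate_pcv(simulation_config(n_cycles = 2, dt = 1e-3))
#' head(tr)
#' @export
simulate_pcv <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gas <- config$gas
  geom <- config$geom
  st <- config$settings
  per <- cycle_period(st)
  dt <- config$dt
  n <- as.integer(round(config$n_cycles * per / dt))
  t <- seq.int(0L, n) * dt

  # drive pressure on the half-step grid for the RK4 stages
  pv_half <- gas$p_atm + CMH2O_PA * pcv_pressure(st, seq.int(0L, 2L * n) * (dt / 2))

  RT <- gas$R_specific * gas$T
  kq <- K_MASS_FLOW * geom$Ae
  Cc <- config$C_si
  V0 <- config$V0_si
  p0 <- gas$p_atm + CMH2O_PA * st$epap

  rate <- function(p, pv) {
    dp <- pv - p
    if (dp == 0) return(0)
    pu <- if (dp > 0) pv else p
    phi <- (pu - abs(dp)) / pu
    q <- sign(dp) * kq * pu * sqrt(phi * (1 - phi))
    RT * q / (V0 + Cc * (2 * p - p0))
  }

  p <- numeric(n + 1L)
  p[1L] <- p0
  pc <- p0
  h <- dt
  for (i in seq_len(n)) {
    j <- 2L * i
    k1 <- rate(pc, pv_half[j - 1L])
    k2 <- rate(pc + 0.5 * h * k1, pv_half[j])
    k3 <- rate(pc + 0.5 * h * k2, pv_half[j])
    k4 <- rate(pc + h * k3, pv_half[j + 1L])
    pc <- pc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p[i + 1L] <- pc
  }

  pv_abs <- pv_half[seq.int(1L, 2L * n + 1L, by = 2L)]
  dp <- pv_abs - p
  pu <- pmax(pv_abs, p)
  phi <- pmin(pv_abs, p) / pu
  q <- sign(dp) * kq * pu * sqrt(phi * (1 - phi))
  Re <- reynolds_number(q, geom$d, gas$mu)
  lam <- rep(NA_real_, length(Re))
  pos <- Re > 0
  lam[pos] <- friction_coefficient(Re[pos])
  Rr_cl <- resistance(gas, geom, q) / RR_SI_PER_CLINICAL

  p_vent <- (pv_abs - gas$p_atm) / CMH2O_PA
  p_lung <- (p - gas$p_atm) / CMH2O_PA
  trace <- data.frame(
    t = t, p_vent = p_vent, p_lung = p_lung, q = q,
    Q = 1e3 * q / gas$rho_std, Re = Re, lambda = lam, Rr = Rr_cl,
    p_loss = abs(p_vent - p_lung)
  )

  # periodic steady state: peak pressure of the last two cycles
  pk <- vapply(seq_len(config$n_cycles), function(k) {
    max(p_lung[t >= (k - 1) * per - 1e-9 & t <= k * per + 1e-9])
  }, numeric(1))
  nc <- config$n_cycles
  converged <- abs(pk[nc] - pk[nc - 1L]) <= 1e-3 * abs(pk[nc - 1L])
  if (!converged) {
    warning("simulation did not reach a periodic steady state ",
            "(peak pressure still drifting in the final cycle)")
  }

  structure(trace,
            config = config, period = per, converged = converged,
            class = c("pcv_trace", "data.frame"))
}

#' Per-breath summary of a simulated trace
#'
#' Extrema over the post-transient cycles, with inspiration defined as the
#' `[cycle start, cycle start + Ti]` window and expiration as the remainder
#' of the cycle. Resistance extrema exclude samples with `|Q| < 1 mL/s`,
#' where the Darcy value is pinned at the laminar limit.
#'
#' @param trace a `pcv_trace` from [simulate_pcv()].
#' @param settings optional [ventilator_settings()] override; defaults to the
#'   settings the trace was produced with.
#' @return A one-row data frame of class `breath_summary` with columns
#'   `p_peak`, `p_min` (cmH2O), `Rr_max_insp`, `Rr_max_exp`, `Rr_min`
#'   (cmH2O/(L/s)), `Q_peak_insp`, `Q_peak_exp` (L/s, magnitudes) and
#'   `tidal_volume` (mL, delivered standard volume per inspiration).
#' @examples
#' tr <- simulate_pcv(simulation_config(n_cycles = 2, dt = 1e-3))
#' breath_summary(tr)
#' @export
breath_summary <- function(trace, settings = NULL) {
  cfg <- attr(trace, "config")
  if (is.null(cfg)) stop("trace carries no configuration")
  if (is.null(settings)) settings <- cfg$settings
  per <- cycle_period(settings)
  ti <- settings$ti
  eps <- 1e-9
  t <- trace$t
  post <- t >= cfg$discard_cycles * per - eps
  if (!any(post)) stop("no post-transient samples in trace")
  tm <- t - floor(t / per + eps) * per
  insp <- tm <= ti + eps
  flowing <- abs(trace$Q) >= 1e-3 # exclude near-zero flow (Rr pinned)

  sel_ri <- post & insp & flowing
  sel_re <- post & !insp & flowing
  if (!any(sel_ri) || !any(sel_re)) {
    stop("empty inspiration or expiration window after flow masking")
  }

  vt <- vapply(.cycle_windows(trace, cfg, "insp", cfg$discard_cycles),
               function(w) {
                 1e3 * pracma::trapz(t[w], pmax(trace$Q[w], 0)) # mL
               }, numeric(1))

  structure(
    data.frame(
      p_peak = max(trace$p_lung[post]),
      p_min = min(trace$p_lung[post]),
      Rr_max_insp = max(trace$Rr[sel_ri]),
      Rr_max_exp = max(trace$Rr[sel_re]),
      Rr_min = min(trace$Rr[post & flowing]),
      Q_peak_insp = max(trace$Q[post & insp]),
      Q_peak_exp = max(-trace$Q[post & !insp]),
      tidal_volume = mean(vt)
    ),
    class = c("breath_summary", "data.frame")
  )
}

#' One-at-a-time parameter sweep
#'
#' Re-simulates the configuration with one parameter set to each of the given
#' values, all others held constant, and collects the per-breath summaries.
#'
#' @param config the base [simulation_config()].
#' @param param one of `"IPAP"`, `"EPAP"`, `"BPM"`, `"Ti"`, `"Tr"`, `"C"`,
#'   `"d"`.
#' @param values numeric vector of values in the parameter's clinical unit.
#' @return A data frame with columns `param`, `value` and the
#'   [breath_summary()] columns, one row per value, in the order given.
#' @examples
#' sweep_parameter(simulation_config(n_cycles = 2, dt = 1e-3),
#'                 "IPAP", c(18, 22, 24))
#' @export
sweep_parameter <- function(config, param, values) {
  stopifnot(length(values) >= 1)
  rows <- lapply(values, function(v) {
    s <- breath_summary(simulate_pcv(update_config(config, param, v)))
    cbind(data.frame(param = param, value = v), s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold of a scanned parameter for reaching IPAP
#'
#' Scans the given values and reports the boundary value at which the peak
#' lung pressure still reaches IPAP (within `reach_tol`, default 2%): for a
#' parameter that impedes pressurisation as it grows (compliance `C`), the
#' largest reaching value; for one that aids it (diameter `d`), the smallest
#' reaching value. Equality at the tolerance boundary counts as reaching.
#'
#' @inheritParams sweep_parameter
#' @param values scanned values, sorted increasingly.
#' @param reach_tol allowed shortfall as a fraction of IPAP.
#' @return The threshold value, or `NA` (with a message) if no scanned value
#'   reaches IPAP. The sweep table travels in attribute `"sweep"`.
#' @examples
#' \donttest{
#' threshold_find(simulation_config(), "C", c(5, 10, 15)) # 10
#' }
#' @export
threshold_find <- function(config, param, values, reach_tol = 0.02) {
  if (length(values) == 0) stop("empty scan")
  if (is.unsorted(values)) stop("values must be sorted increasingly")
  sw <- sweep_parameter(config, param, values)
  target <- config$ipap * (1 - reach_tol)
  reach <- sw$p_peak >= target - 1e-12
  if (!any(reach)) {
    message("no scanned ", param, " reaches IPAP within ",
            100 * reach_tol, "%")
    return(structure(NA_real_, sweep = sw))
  }
  # direction of the p_peak trend over the scan decides which boundary
  # of the reaching set is the threshold
  decreasing <- sw$p_peak[length(values)] <= sw$p_peak[1]
  thr <- if (decreasing) max(values[reach]) else min(values[reach])
  structure(thr, sweep = sw)
}

#' @export
print.pcv_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("PCV trace: %d samples, %d cycles of %g s (dt = %g s)%s\n",
              nrow(x), cfg$n_cycles, attr(x, "period"), cfg$dt,
              if (isTRUE(attr(x, "converged"))) "" else " [not converged]"))
  print.data.frame(utils::head(as.data.frame(x), 5))
  cat("...\n")
  invisible(x)
}

#' Diagnostic plot of a simulated trace
#'
#' Stacked base-graphics panels of the pressure curves (ventilator and lung),
#' the volume flow, and the respiratory resistance.
#'
#' @param x a `pcv_trace`.
#' @param which subset of `c("pressure", "flow", "resistance")`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pcv_trace <- function(x, which = c("pressure", "flow", "resistance"),
                           ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4.5, 1, 1))
  on.exit(graphics::par(op))
  if ("pressure" %in% which) {
    graphics::plot(x$t, x$p_vent, type = "l", col = "grey40",
                   xlab = "t (s)", ylab = "pressure (cmH2O)", ...)
    graphics::lines(x$t, x$p_lung, col = "firebrick")
    graphics::legend("topright", c("ventilator", "lung"), bty = "n",
                     col = c("grey40", "firebrick"), lty = 1)
  }
  if ("flow" %in% which) {
    graphics::plot(x$t, x$Q, type = "l", xlab = "t (s)", ylab = "Q (L/s)",
                   ...)
    graphics::abline(h = 0, lty = 3)
  }
  if ("resistance" %in% which) {
    graphics::plot(x$t, x$Rr, type = "l", xlab = "t (s)",
                   ylab = "Rr (cmH2O/L/s)", ...)
  }
  invisible(x)
}
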