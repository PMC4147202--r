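# The variable-volume container standing in for the lung: isothermal ideal-gas
# pressure dynamics coupled to a constant compliance, plus compliance
# estimation from pressure/flow traces.

#' State of the variable-volume lung container
#'
#' Absolute pressure, gas volume and compliance of the container; the gas
#' mass is maintained consistently as `m = p V / (R T)` (ideal gas,
#' isothermal).
#'
#' @param p absolute pressure, Pa.
#' @param V gas volume, m^3.
#' @param C compliance, m^3/Pa (multiply mL/cmH2O by
#'   [COMPLIANCE_SI_PER_CLINICAL]).
#' @param gas a [gas_properties()] object.
#' @return An object of class `lung_state` with fields `p`, `V`, `C`, `m`.
#' @examples
#' lung_state(p = 101325, V = 1e-3, C = 10 * COMPLIANCE_SI_PER_CLINICAL)
#' @export
lung_state <- function(p, V, C, gas = gas_properties()) {
  stopifnot(p > 0, V > 0, C > 0)
  structure(
    list(p = p, V = V, C = C, m = p * V / (gas$R_specific * gas$T)),
    class = "lung_state"
  )
}

#' @export
print.lung_state <- function(x, ...) {
  cat(sprintf("Lung state: p = %.1f Pa (%.2f cmH2O gauge), V = %.1f mL, C = %.2f mL/cmH2O\n",
              x$p, abs_to_gauge(x$p), x$V * 1e6,
              x$C / COMPLIANCE_SI_PER_CLINICAL))
  invisible(x)
}

#' Rate of change of lung pressure
#'
#' Differentiating the isothermal ideal-gas law `p V = m R T` with
#' `dV = C dp` gives
#' \deqn{\frac{dp}{dt} = \frac{R T q V}{V^2 + C m R T},}
#' which, with `m = p V / (R T)`, is algebraically identical to
#' `R T q / (V + C p)`. The sign of the rate equals the sign of the mass
#' flow. When the pneumatic capacity `C p` dominates the resident volume `V`,
#' the rate approaches the familiar `Q_local / C` with `Q_local = q R T / p`
#' the volumetric flow at container conditions.
#'
#' @param state a [lung_state()] object.
#' @param gas a [gas_properties()] object.
#' @param q signed mass flow into the container, kg/s.
#' @return dp/dt in Pa/s.
#' @export
pressure_derivative <- function(state, gas, q) {
  stopifnot(inherits(state, "lung_state"))
  RT <- gas$R_specific * gas$T
  RT * q * state$V / (state$V^2 + state$C * state$m * RT)
}

#' Volume increment from a pressure increment
#'
#' The defining relation of compliance: `dV = C dp`.
#'
#' @param state a [lung_state()] object.
#' @param dp pressure increment, Pa.
#' @return Volume increment, m^3.
#' @export
volume_update <- function(state, dp) {
  stopifnot(inherits(state, "lung_state"))
  state$C * dp
}

#' Advance the lung one integrator step under a constant drive pressure
#'
#' Single fixed-step update of the coupled orifice-flow/pressure system with
#' the ventilator pressure held at `p_vent` for the step: the flow through
#' the throttle follows [mass_flow_simplified()] with the upstream side
#' whichever pressure is higher, and the container pressure advances by the
#' isothermal rate of [pressure_derivative()]. If the step would cross the
#' drive pressure (the equilibrium is reached in finite time because the
#' orifice law is a square root in the pressure difference), the state is
#' clamped at `p_vent`.
#'
#' @param state a [lung_state()] object.
#' @param p_vent ventilator (drive) pressure for the step, Pa absolute.
#' @param geom a [throttle_geometry()] object.
#' @param dt step size, s.
#' @param gas a [gas_properties()] object.
#' @param method `"rk4"` (classical 4th-order Runge-Kutta, the default) or
#'   `"euler"` (forward Euler).
#' @return A list with elements `state` (the advanced [lung_state()]),
#'   `flow` (list `q`, `Q`, `ni`, `pu`, `pd` at the start of the step) and
#'   `resistance` (list `Re`, `lam`, `Rr`, `p_loss`, SI units; `lam` is `NA`
#'   at zero flow where the Darcy coefficient is undefined).
#' @export
lung_step <- function(state, p_vent, geom, dt,
                      gas = gas_properties(), method = c("rk4", "euler")) {
  stopifnot(inherits(state, "lung_state"), dt > 0, p_vent > 0)
  method <- match.arg(method)
  RT <- gas$R_specific * gas$T
  C <- state$C
  V1 <- state$V
  p1 <- state$p

  rate <- function(p) {
    dp <- p_vent - p
    if (dp == 0) return(0)
    pu <- max(p_vent, p)
    pd <- min(p_vent, p)
    q <- mass_flow_simplified(geom$Ae, pu, pd, ni = sign(dp))
    # V tracks p through dV = C dp within the step
    RT * q / (V1 + C * (p - p1) + C * p)
  }

  p_new <- if (method == "euler") {
    p1 + dt * rate(p1)
  } else {
    k1 <- rate(p1)
    k2 <- rate(p1 + dt / 2 * k1)
    k3 <- rate(p1 + dt / 2 * k2)
    k4 <- rate(p1 + dt * k3)
    p1 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  # no overshoot past the drive pressure within one step
  if ((p_vent - p1) * (p_vent - p_new) < 0) p_new <- p_vent

  ni <- sign(p_vent - p1)
  pu <- max(p_vent, p1)
  pd <- min(p_vent, p1)
  q <- if (ni == 0) 0 else mass_flow_simplified(geom$Ae, pu, pd, ni = ni)
  Re <- reynolds_number(q, geom$d, gas$mu)
  Rr <- resistance(gas, geom, q)
  out_state <- lung_state(p = p_new, V = V1 + C * (p_new - p1), C = C,
                          gas = gas)
  list(
    state = out_state,
    flow = list(q = q, Q = q / gas$rho_std, ni = ni, pu = pu, pd = pd),
    resistance = list(Re = Re,
                      lam = if (Re > 0) friction_coefficient(Re) else NA_real_,
                      Rr = Rr,
                      p_loss = pressure_loss(Rr, q / gas$rho_std))
  )
}

#' Estimate respiratory compliance from a pressure/flow trace
#'
#' Recovers the compliance of the container from a simulated trace or a
#' (noisy) synthetic recording, using the inspiratory windows of all
#' post-transient cycles and averaging the per-cycle estimates.
#'
#' Two estimators are available. `"volume_ratio"` is the desk calculation
#' \deqn{C \approx \frac{\int_{insp} Q\,dt}{p_{lung,end} - p_{lung,start}},}
#' the delivered (standard-state) volume over the pressure swing. Because
#' part of the delivered gas is compressed into the volume already resident
#' in the container rather than expanding it, this ratio overestimates the
#' true compliance by a factor of roughly `1 + V/(C p)` (about 10% at the
#' default operating point). The default `"mass_balance"` estimator inverts
#' the isothermal mass balance
#' \deqn{\rho_{std} \int Q\,dt \; R T = (C \bar p + \bar V)\, \Delta p,}
#' which recovers the configured compliance to well under a percent on
#' noiseless traces.
#'
#' @param trace a `pcv_trace` from [simulate_pcv()], a `pcv_recording` from
#'   [generate_recording()], or any data frame with columns `t`, `p_lung`
#'   (cmH2O gauge) and `Q` (L/s). Without cycle metadata the whole span is
#'   used as a single window.
#' @param method `"mass_balance"` (default) or `"volume_ratio"`.
#' @param v0 resident gas volume at the start of the run, L; only used by the
#'   mass-balance correction when the trace does not carry its configuration.
#' @param min_swing smallest usable pressure swing, cmH2O; windows below it
#'   are rejected and a trace with no usable window is an error.
#' @param gas a [gas_properties()] object (ignored if the trace carries one).
#' @return Compliance estimate in mL/cmH2O, with the per-cycle estimates in
#'   attribute `"per_cycle"`.
#' @examples
#' cfg <- simulation_config(n_cycles = 2, dt = 5e-4)
#' tr <- simulate_pcv(cfg)
#' estimate_compliance(tr) # ~10 mL/cmH2O
#' @export
estimate_compliance <- function(trace,
                                method = c("mass_balance", "volume_ratio"),
                                v0 = 1, min_swing = 0.5,
                                gas = gas_properties()) {
  method <- match.arg(method)
  stopifnot(all(c("t", "p_lung", "Q") %in% names(trace)))
  cfg <- attr(trace, "config")
  if (!is.null(cfg)) {
    gas <- cfg$gas
    v0 <- cfg$v0
    windows <- .cycle_windows(trace, cfg, phase = "insp",
                              from_cycle = cfg$discard_cycles)
    p_start_run <- cfg$settings$epap
  } else {
    windows <- list(seq_len(nrow(trace)))
    p_start_run <- trace$p_lung[1]
  }
  RT <- gas$R_specific * gas$T
  V0 <- v0 * 1e-3

  per_cycle <- vapply(windows, function(w) {
    tw <- trace$t[w]
    pl <- trace$p_lung[w]
    dp_cm <- pl[length(pl)] - pl[1]
    if (abs(dp_cm) < min_swing) return(NA_real_)
    vol_l <- pracma::trapz(tw, trace$Q[w]) # standard litres delivered
    if (method == "volume_ratio") {
      vol_l * 1e3 / dp_cm
    } else {
      M <- gas$rho_std * vol_l * 1e-3 # kg
      dp_pa <- dp_cm * CMH2O_PA
      pbar <- gas$p_atm + mean(pl) * CMH2O_PA
      pstart <- gas$p_atm + p_start_run * CMH2O_PA
      # M RT / dp = C pbar + V0 + C (pbar - pstart)
      C_si <- (M * RT / dp_pa - V0) / (2 * pbar - pstart)
      C_si / COMPLIANCE_SI_PER_CLINICAL
    }
  }, numeric(1))

  per_cycle <- per_cycle[is.finite(per_cycle)]
  if (length(per_cycle) == 0) {
    stop("degenerate trace: no window with a pressure swing of at least ",
         min_swing, " cmH2O")
  }
  if (any(per_cycle <= 0)) {
    stop("compliance estimate is non-positive; trace is inconsistent with the model")
  }
  structure(mean(per_cycle), per_cycle = per_cycle)
}

# Indices of per-cycle windows of a trace. phase = "insp" gives
# [cycle start, cycle start + Ti]; "exp" the remainder; "all" whole cycles.
.cycle_windows <- function(trace, cfg, phase = c("insp", "exp", "all"),
                           from_cycle = 0) {
  phase <- match.arg(phase)
  per <- cycle_period(cfg$settings)
  ti <- cfg$settings$ti
  eps <- 1e-9
  lapply(seq.int(from_cycle, cfg$n_cycles - 1L), function(k) {
    lo <- k * per
    hi <- switch(phase, insp = lo + ti, exp = (k + 1) * per, all = (k + 1) * per)
    if (phase == "exp") {
      which(trace$t > lo + ti + eps & trace$t <= hi + eps)
    } else {
      which(trace$t >= lo - eps & trace$t <= hi + eps)
    }
  })
}
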