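# Compressible flow through the equivalent throttle and the
# Reynolds-dependent Darcy resistance model.
#
# The whole airway (tube + respiratory tract, or the test lung's inlet) is
# lumped into a single orifice of diameter d and effective area Ae = pi d^2/4.
# Flow through it follows the isentropic converging-nozzle law; in the
# operating range of PCV (a few tens of cmH2O of drive pressure) the
# downstream/upstream ratio stays above the critical ratio b, so the flow is
# always subsonic and a one-term square-root approximation is accurate to a
# few percent.

# Coefficients of the approximate mass/volume flow laws. The mass-flow
# coefficient 0.0048 (SI: kg/s per m^2·Pa) matches the exact nozzle law at
# room temperature; the volume-flow coefficient is 0.0048/rho_std with
# rho_std = 1.2 kg/m^3, making q = rho_std * Q an exact identity.
K_MASS_FLOW <- 0.0048
K_VOL_FLOW <- 0.004

#' Physical properties of the ventilated gas
#'
#' Defaults describe air at room temperature. The model treats the gas as
#' ideal and the circuit as isothermal, so a single temperature applies
#' everywhere.
#'
#' @param kappa adiabatic index (dimensionless, > 1).
#' @param R_specific specific gas constant, J/(kg·K).
#' @param T absolute temperature, K.
#' @param mu dynamic viscosity, Pa·s.
#' @param rho_std standard-state density, kg/m^3. Reported volume flow is
#'   referred to this state, so `q = rho_std * Q` exactly.
#' @param p_atm atmospheric reference pressure, Pa absolute.
#' @return An object of class `gas_properties`.
#' @examples
#' gas_properties()
#' @export
gas_properties <- function(kappa = 1.4, R_specific = 287, T = 293.15,
                           mu = 1.82e-5, rho_std = 1.2, p_atm = P_ATM_PA) {
  stopifnot(kappa > 1, R_specific > 0, T > 0, mu > 0, rho_std > 0, p_atm > 0)
  structure(
    list(kappa = kappa, R_specific = R_specific, T = T, mu = mu,
         rho_std = rho_std, p_atm = p_atm),
    class = "gas_properties"
  )
}

#' @export
print.gas_properties <- function(x, ...) {
  cat("Gas properties (ideal, isothermal):\n")
  cat(sprintf("  kappa = %g, R = %g J/(kg K), T = %g K\n",
              x$kappa, x$R_specific, x$T))
  cat(sprintf("  mu = %g Pa s, rho_std = %g kg/m^3, p_atm = %g Pa\n",
              x$mu, x$rho_std, x$p_atm))
  invisible(x)
}

#' Geometry of the equivalent throttle
#'
#' A single orifice lumping the flow restriction of tube plus respiratory
#' tract (experimentally, the inlet of the test lung). The effective area is
#' derived as `Ae = pi * d^2 / 4`.
#'
#' @param d orifice diameter, m. Default 3.2 mm, the test-lung inlet.
#' @param l throttle length, m, entering only the Darcy resistance
#'   bookkeeping. Default 10 mm, calibrated so that the laminar-limit
#'   resistance at d = 3.2 mm equals 0.72 cmH2O/(L/s).
#' @return An object of class `throttle_geometry` with fields `d`, `l`, `Ae`.
#' @examples
#' throttle_geometry(d = 3.2e-3, l = 10e-3)
#' @export
throttle_geometry <- function(d = 3.2e-3, l = 10e-3) {
  stopifnot(is.numeric(d), is.numeric(l), d > 0, l > 0)
  structure(list(d = d, l = l, Ae = pi * d^2 / 4), class = "throttle_geometry")
}

#' @export
print.throttle_geometry <- function(x, ...) {
  cat(sprintf("Equivalent throttle: d = %g mm, l = %g mm, Ae = %.4g mm^2\n",
              x$d * 1e3, x$l * 1e3, x$Ae * 1e6))
  invisible(x)
}

#' Critical pressure ratio of the converging nozzle
#'
#' The downstream/upstream pressure ratio below which orifice flow chokes
#' (goes sonic): `b = (2/(kappa+1))^(kappa/(kappa-1))`, about 0.528 for air.
#' PCV drive pressures are a tiny fraction of atmospheric, so the simulator
#' operates far above `b`; the ratio is still used to pin the choked plateau
#' of [mass_flow_exact()].
#'
#' @param gas a [gas_properties()] object, or a bare numeric adiabatic index.
#' @return The ratio `b` in (0, 1).
#' @examples
#' critical_pressure_ratio(gas_properties()) # ~0.528
#' @export
critical_pressure_ratio <- function(gas = gas_properties()) {
  kappa <- if (is.numeric(gas)) gas else gas$kappa
  if (any(kappa <= 1)) stop("adiabatic index kappa must exceed 1")
  (2 / (kappa + 1))^(kappa / (kappa - 1))
}

#' Orifice mass flow, exact nozzle law
#'
#' Isentropic converging-nozzle mass flow through the equivalent throttle:
#' \deqn{q = A_e p_u \sqrt{\frac{2\kappa}{(\kappa-1) R T}
#'   \left[\phi^{2/\kappa} - \phi^{(\kappa+1)/\kappa}\right]}, \quad
#'   \phi = p_d/p_u,}
#' with the ratio pinned at the critical value `b` when `phi <= b` (choked,
#' sonic flow). Continuous in `phi`, including at the sonic boundary.
#'
#' @param gas a [gas_properties()] object.
#' @param Ae effective orifice area, m^2.
#' @param pu,pd upstream and downstream absolute pressures, Pa (`pu >= pd`).
#' @param ni flow direction coefficient: +1 into the lung, -1 out of it.
#' @return Signed mass flow, kg/s (sign of `ni`). Vectorised over pressures.
#' @seealso [mass_flow_simplified()] for the square-root approximation used
#'   inside the simulator.
#' @export
mass_flow_exact <- function(gas, Ae, pu, pd, ni = 1) {
  stopifnot(Ae > 0)
  if (any(pu <= 0) || any(pd <= 0)) {
    stop("absolute pressures must be positive")
  }
  if (any(pd > pu)) {
    stop("pd must not exceed pu; swap the pressures and set ni = -1 for reverse flow")
  }
  b <- critical_pressure_ratio(gas)
  phi <- pmax(pd / pu, b)
  bracket <- phi^(2 / gas$kappa) - phi^((gas$kappa + 1) / gas$kappa)
  q <- Ae * pu *
    sqrt(2 * gas$kappa / ((gas$kappa - 1) * gas$R_specific * gas$T) *
           pmax(bracket, 0))
  ni * q
}

#' Orifice mass flow, square-root approximation
#'
#' Room-temperature approximation to [mass_flow_exact()] in SI units:
#' \deqn{q = 0.0048 \, n_i A_e p_u \sqrt{\phi (1 - \phi)}, \quad
#'   \phi = p_d/p_u.}
#' Within 3% of the exact law over the whole subsonic range
#' `phi` in \[0.528, 0.995\] at room temperature. This is the flow law the
#' simulator integrates.
#'
#' @inheritParams mass_flow_exact
#' @return Signed mass flow, kg/s. Vectorised over pressures.
#' @examples
#' geom <- throttle_geometry()
#' mass_flow_simplified(geom$Ae, pu = 103483, pd = 101325) # ~5.7e-4 kg/s
#' @export
mass_flow_simplified <- function(Ae, pu, pd, ni = 1) {
  stopifnot(Ae > 0)
  if (any(pu <= 0) || any(pd <= 0)) {
    stop("absolute pressures must be positive")
  }
  if (any(pd > pu)) {
    stop("pd must not exceed pu; swap the pressures and set ni = -1 for reverse flow")
  }
  phi <- pd / pu
  ni * K_MASS_FLOW * Ae * pu * sqrt(phi * (1 - phi))
}

#' Orifice volume flow at standard state
#'
#' Standard-state volume flow corresponding to [mass_flow_simplified()]:
#' `Q = 0.004 ni Ae pu sqrt(phi (1 - phi))`. The coefficient ratio
#' 0.004 = 0.0048 / 1.2 makes `q = rho_std * Q` hold exactly.
#'
#' @inheritParams mass_flow_exact
#' @return Signed volume flow, m^3/s at standard state.
#' @export
volume_flow <- function(Ae, pu, pd, ni = 1) {
  mass_flow_simplified(Ae, pu, pd, ni) * (K_VOL_FLOW / K_MASS_FLOW)
}

#' Reynolds number of pipe flow from mass flow
#'
#' For a circular duct of diameter `d`, `Re = 4 |q| / (pi d mu)`; linear in
#' the magnitude of the mass flow.
#'
#' @param q mass flow, kg/s (sign ignored).
#' @param d duct diameter, m.
#' @param mu dynamic viscosity, Pa·s.
#' @return Reynolds number (dimensionless, >= 0). Vectorised over `q`.
#' @export
reynolds_number <- function(q, d, mu) {
  stopifnot(d > 0, mu > 0)
  4 * abs(q) / (pi * d * mu)
}

#' Darcy friction coefficient (Moody-diagram piecewise law)
#'
#' Three-branch friction law for a hydraulically smooth pipe:
#' \deqn{\lambda = \begin{cases}
#'   64/Re & Re < 2000 \\
#'   0.032 + 0.013\,(Re-2000)/1000 & 2000 \le Re \le 3000 \\
#'   0.045 - 0.015\,(Re-3000)/10000 & Re > 3000
#' \end{cases}}
#' Continuous at both branch boundaries (0.032 at Re = 2000, 0.045 at
#' Re = 3000). Undefined at Re = 0; at vanishing flow use the laminar-limit
#' closed form built into [resistance()] instead.
#'
#' @param Re Reynolds number(s), > 0.
#' @return Friction coefficient lambda. Vectorised.
#' @export
friction_coefficient <- function(Re) {
  if (any(Re <= 0)) {
    stop("Re must be positive; at zero flow use the laminar-limit resistance")
  }
  ifelse(Re < 2000, 64 / Re,
         ifelse(Re <= 3000,
                0.032 + (Re - 2000) / 1000 * 0.013,
                0.045 - (Re - 3000) / 10000 * 0.015))
}

#' Respiratory resistance of the equivalent throttle
#'
#' Darcy pressure-loss bookkeeping of the throttle,
#' \deqn{R_r = \frac{8 \lambda l |q|}{\pi^2 d^5},}
#' with lambda from [friction_coefficient()]. For Re < 2000 this reduces
#' algebraically (lambda = 64/Re) to the Poiseuille closed form
#' `128 mu l / (pi d^4)`, which is used directly so that the resistance is
#' finite and continuous down to zero flow — consistent with the observation
#' that the resistance levels off as the flow vanishes.
#'
#' @param gas a [gas_properties()] object (viscosity enters the laminar limit
#'   and the Reynolds number).
#' @param geom a [throttle_geometry()] object.
#' @param q mass flow, kg/s (sign ignored). Vectorised.
#' @return Resistance in SI units, Pa·s/m^3. Divide by
#'   [RR_SI_PER_CLINICAL] for cmH2O/(L/s).
#' @examples
#' # laminar floor at the default geometry, in clinical units (~0.72):
#' resistance(gas_properties(), throttle_geometry(), 0) / RR_SI_PER_CLINICAL
#' @export
resistance <- function(gas, geom, q) {
  Re <- reynolds_number(q, geom$d, gas$mu)
  out <- rep.int(128 * gas$mu * geom$l / (pi * geom$d^4), length(Re))
  turb <- Re >= 2000
  if (any(turb)) {
    lam <- friction_coefficient(Re[turb])
    out[turb] <- 8 * lam * geom$l * abs(q[turb]) / (pi^2 * geom$d^5)
  }
  out
}

#' Pressure loss across the throttle from resistance and flow
#'
#' Darcy estimate `p_loss = Rr * |Q|`. Note that the simulated trace also
#' carries the actual throttle drop `|p_vent - p_lung|` implied by the
#' orifice flow law; the two differ at high flow because the Darcy friction
#' formula and the nozzle law are distinct models of the same restriction
#' (see the package vignette).
#'
#' @param Rr resistance, Pa·s/m^3 (or any unit; the result is `Rr * |Q|`).
#' @param Q volume flow (sign ignored).
#' @return Non-negative pressure loss in units consistent with the inputs.
#' @export
pressure_loss <- function(Rr, Q) {
  if (any(Rr < 0)) stop("Rr must be non-negative")
  Rr * abs(Q)
}
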