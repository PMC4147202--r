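# Every quantity is held internally in SI (absolute Pa, m, kg/s, m^3/Pa) and
# presented to the user in clinical units (gauge cmH2O, mm, L/s, mL/cmH2O).
# Each conversion is defined exactly once so CSV output stays bit-stable.

#' Unit conversion constants
#'
#' Named constants tying the internal SI representation to the clinical units
#' used in all user-facing input and output.
#'
#' * `CMH2O_PA` — pascal per centimetre of water (98.0665).
#' * `RR_SI_PER_CLINICAL` — Pa·s/m^3 per cmH2O/(L/s) (98066.5), the
#'   resistance conversion.
#' * `COMPLIANCE_SI_PER_CLINICAL` — m^3/Pa per mL/cmH2O (1e-6/98.0665).
#' * `P_ATM_PA` — reference atmospheric pressure, Pa absolute (101325).
#'
#' @name units
#' @rdname units
NULL

#' @rdname units
#' @export
CMH2O_PA <- 98.0665

#' @rdname units
#' @export
RR_SI_PER_CLINICAL <- 98066.5

#' @rdname units
#' @export
COMPLIANCE_SI_PER_CLINICAL <- 1e-6 / 98.0665

#' @rdname units
#' @export
P_ATM_PA <- 101325

#' Pressure unit helpers
#'
#' Convert between gauge cmH2O (the clinical convention for airway pressures)
#' and absolute pascal (the internal representation).
#'
#' @param p pressure value(s); gauge cmH2O for `cmh2o_to_pa()` and
#'   `gauge_to_abs()`, Pa for the inverses.
#' @param p_atm atmospheric reference pressure in Pa.
#' @return numeric vector in the target unit.
#' @export
cmh2o_to_pa <- function(p) p * CMH2O_PA

#' @rdname cmh2o_to_pa
#' @export
pa_to_cmh2o <- function(p) p / CMH2O_PA

#' @rdname cmh2o_to_pa
#' @export
gauge_to_abs <- function(p, p_atm = P_ATM_PA) p_atm + p * CMH2O_PA

#' @rdname cmh2o_to_pa
#' @export
abs_to_gauge <- function(p, p_atm = P_ATM_PA) (p - p_atm) / CMH2O_PA
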