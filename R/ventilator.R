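# The ideal PCV pressure source: a periodic trapezoid between EPAP and IPAP.

#' Ventilator settings for pressure-controlled ventilation
#'
#' The five settings that define the PCV output-pressure waveform. Defaults
#' are the baseline operating point used throughout: IPAP 22, EPAP 4 cmH2O,
#' 20 breaths/min, 1 s inspiration, 0.2 s rise time.
#'
#' @param ipap inspiratory positive airway pressure, cmH2O gauge.
#' @param epap expiratory positive airway pressure, cmH2O gauge.
#' @param bpm breaths per minute.
#' @param ti inspiratory time, s (inspiration window is `[0, ti]` within each
#'   cycle).
#' @param tr pressure rise time, s; also the duration of the expiratory fall
#'   (symmetric trapezoid).
#' @return An object of class `ventilator_settings`.
#' @examples
#' ventilator_settings()
#' @export
ventilator_settings <- function(ipap = 22, epap = 4, bpm = 20, ti = 1,
                                tr = 0.2) {
  stopifnot(is.numeric(ipap), is.numeric(epap), is.numeric(bpm),
            is.numeric(ti), is.numeric(tr))
  if (!(ipap > epap && epap >= 0)) {
    stop("need IPAP > EPAP >= 0 (cmH2O gauge)")
  }
  if (bpm <= 0) stop("BPM must be positive")
  period <- 60 / bpm
  if (!(tr > 0 && tr < ti && ti < period)) {
    stop("need 0 < Tr < Ti < 60/BPM; got Tr = ", tr, ", Ti = ", ti,
         ", period = ", period)
  }
  if (ti + tr >= period) {
    stop("inspiration plus fall (Ti + Tr) must fit inside the cycle")
  }
  structure(list(ipap = ipap, epap = epap, bpm = bpm, ti = ti, tr = tr),
            class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf(
    "PCV settings: IPAP %g / EPAP %g cmH2O, %g bpm (period %g s), Ti %g s, Tr %g s\n",
    x$ipap, x$epap, x$bpm, 60 / x$bpm, x$ti, x$tr))
  invisible(x)
}

#' Ventilation cycle period
#'
#' @param settings a [ventilator_settings()] object.
#' @return Period of one breath, `60 / BPM`, in seconds.
#' @export
cycle_period <- function(settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  60 / settings$bpm
}

#' Ideal PCV output-pressure waveform
#'
#' Piecewise-linear periodic trapezoid: linear rise EPAP -> IPAP over
#' `[0, Tr]`, plateau at IPAP over `[Tr, Ti]`, linear fall IPAP -> EPAP over
#' `[Ti, Ti + Tr]`, then EPAP until the end of the period. Each cycle starts
#' at the beginning of the inspiratory rise. Continuous and bounded by
#' `[EPAP, IPAP]`.
#'
#' @param settings a [ventilator_settings()] object.
#' @param t time(s) since the start of the run, s (>= 0). Vectorised.
#' @return Ventilator output pressure, cmH2O gauge.
#' @examples
#' s <- ventilator_settings()
#' pcv_pressure(s, c(0, 0.1, 0.2, 1, 1.1, 1.2, 3))
#' @export
pcv_pressure <- function(settings, t) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (any(t < 0)) stop("t must be non-negative")
  per <- cycle_period(settings)
  tm <- t - floor(t / per) * per
  ipap <- settings$ipap
  epap <- settings$epap
  ti <- settings$ti
  tr <- settings$tr
  ifelse(tm < tr, epap + (ipap - epap) * tm / tr,
         ifelse(tm <= ti, ipap,
                ifelse(tm < ti + tr,
                       ipap - (ipap - epap) * (tm - ti) / tr,
                       epap)))
}
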