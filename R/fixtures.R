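#' Synthetic volumetric-flowrate waveform for one cardiac cycle
#'
#' Builds a smooth two-lobe flowrate (positive filling lobe, negative
#' ejection lobe, both `sin^2`-shaped) that is exactly zero during the
#' two isovolumic windows and integrates to zero over the period.  The
#' phase layout is filling, isovolumic contraction, ejection,
#' isovolumic relaxation, then a zero-flow diastasis filling the
#' remainder of the cycle.
#'
#' @param period cycle period (s).
#' @param edv target end-diastolic volume (mL); together with `ef` it
#'   sets the stroke volume `ef * edv` carried by each lobe.
#' @param ef ejection fraction in (0, 1).
#' @param ivc_frac,ivr_frac isovolumic contraction/relaxation durations
#'   as fractions of the period.
#' @param fill_frac,eject_frac filling and ejection durations as
#'   fractions of the period.
#' @return An object of class `"cycle_drive"`: list with the phase
#'   table, stroke volume, period, and `q`, a vectorised function
#'   `t -> mL/s` (periodic).
#' @export
#' @examples
#' d <- make_flowrate(period = 0.17, edv = 0.5, ef = 0.6)
#' integrate(d$q, 0, d$period)$value   # ~ 0
make_flowrate <- function(period = 0.17, edv = 0.5, ef = 0.6,
                          ivc_frac = 0.08, ivr_frac = 0.08,
                          fill_frac = 0.40, eject_frac = 0.30) {
  stopifnot(period > 0, ef > 0, ef < 1, edv > 0)
  if (fill_frac + ivc_frac + eject_frac + ivr_frac >= 1)
    stop("phase fractions must sum to less than 1 ",
         "(a diastasis window must remain)")
  sv <- ef * edv
  t_fill <- fill_frac * period
  t_ivc <- ivc_frac * period
  t_eject <- eject_frac * period
  bounds <- cumsum(c(fill = t_fill, ivc = t_ivc, eject = t_eject,
                     ivr = ivr_frac * period))
  q_fill <- 2 * sv / t_fill        # peak of a sin^2 lobe with area sv
  q_eject <- 2 * sv / t_eject
  q <- function(t) {
    tt <- t %% period
    ifelse(tt < bounds[1],
           q_fill * sin(pi * tt / t_fill)^2,
    ifelse(tt < bounds[2], 0,
    ifelse(tt < bounds[3],
           -q_eject * sin(pi * (tt - bounds[2]) / t_eject)^2,
           0)))
  }
  phases <- data.frame(
    phase = c("filling", "ivc", "ejection", "ivr", "diastasis"),
    start = c(0, bounds), end = c(bounds, period))
  structure(list(q = q, period = period, stroke_volume = sv,
                 edv = edv, ef = ef, phases = phases),
            class = "cycle_drive")
}

#' @method print cycle_drive
#' @export
print.cycle_drive <- function(x, ...) {
  cat(sprintf("cycle drive: period %.3f s, stroke volume %.3f mL (EF %.0f%%)\n",
              x$period, x$stroke_volume, 100 * x$ef))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Phase label at given times within the cycle
#'
#' @param drive a [make_flowrate()] object.
#' @param t times (s); reduced modulo the period.
#' @return Character vector of phase labels.
#' @export
cycle_phase <- function(drive, t) {
  tt <- t %% drive$period
  ph <- drive$phases
  out <- character(length(tt))
  for (i in seq_len(nrow(ph)))
    out[tt >= ph$start[i] & tt < ph$end[i]] <- ph$phase[i]
  out[out == ""] <- ph$phase[nrow(ph)]
  out
}

#' Synthetic intracellular calcium transient
#'
#' Two-exponential rise/decay template: the shape
#' `exp(-u / tau_decay) - exp(-u / tau_rise)` (normalised to unit peak)
#' scaled between `baseline` and `peak`, periodic with the cycle period
#' and starting at `onset` (aligned to the start of isovolumic
#' contraction in the ventricle model).  The default time constants are
#' referenced to a 0.5 s cycle and scale proportionally with the period,
#' emulating the temporal rescaling of a recorded transient to the
#' animal's heart rate.
#'
#' @param period cycle period (s).
#' @param peak peak calcium (nM).
#' @param baseline diastolic calcium (nM).
#' @param tau_rise,tau_decay rise/decay time constants (s) at the
#'   reference period; `NULL` means 0.010 and 0.050 scaled by
#'   `period / 0.34` (the template constants are referenced to an
#'   intact-heart recording at a 0.34 s cycle).
#' @param onset start time of the transient within the cycle (s).
#' @return An object of class `"calcium_transient"` with fields and a
#'   vectorised evaluator available through [ca_at()].
#' @export
make_calcium <- function(period = 0.17, peak = 1000, baseline = 100,
                         tau_rise = NULL, tau_decay = NULL, onset = 0) {
  stopifnot(period > 0, peak >= baseline, baseline >= 0)
  scale <- period / 0.34
  if (is.null(tau_rise)) tau_rise <- 0.010 * scale
  if (is.null(tau_decay)) tau_decay <- 0.050 * scale
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  # peak value of the unnormalised two-exponential shape
  t_pk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  s_pk <- exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise)
  structure(list(period = period, peak = peak, baseline = baseline,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 onset = onset, t_peak = t_pk, s_peak = s_pk),
            class = "calcium_transient")
}

#' Evaluate a calcium transient
#'
#' @param ca a [make_calcium()] object.
#' @return A vectorised function `t -> nM`.
#' @export
ca_at <- function(ca) {
  force(ca)
  function(t) {
    u <- (t - ca$onset) %% ca$period
    s <- (exp(-u / ca$tau_decay) - exp(-u / ca$tau_rise)) / ca$s_peak
    ca$baseline + (ca$peak - ca$baseline) * pmax(s, 0)
  }
}

#' @method print calcium_transient
#' @export
print.calcium_transient <- function(x, ...) {
  cat(sprintf("calcium transient: period %.3f s, %g -> %g nM, tau %g/%g ms, onset %.3f s\n",
              x$period, x$baseline, x$peak, 1e3 * x$tau_rise,
              1e3 * x$tau_decay, x$onset))
  invisible(x)
}
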