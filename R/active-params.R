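#' Parameters of the two-state cross-bridge model
#'
#' Bundles every constant governing attachment/detachment kinetics,
#' calcium activation, cooperativity, filament overlap and the conversion
#' of the bound-head distribution to fiber stress.  Defaults are the
#' fixed stress-conversion constants used throughout
#' (`rho = 6.9e16` heads/m^2, `k_cb = 0.001` N/m, `x_ps = 5` nm) plus the
#' first optimized rate-constant set of [optimized_cases()].
#'
#' @param rho number density of myosin heads in a half-sarcomere of 1 m^2
#'   cross-section (m^-2).
#' @param k_cb cross-bridge stiffness (N/m).
#' @param x_ps power-stroke offset: cross-bridge length when a head binds
#'   a directly opposed site (nm).
#' @param a_on activation rate constant (s^-1 nM^-1).
#' @param a_off deactivation rate constant (s^-1).
#' @param k_plus positive-cooperativity constant (s^-1): bound heads
#'   recruit further binding sites.
#' @param k_minus negative-cooperativity constant (s^-1): inactive
#'   neighbours suppress activation.
#' @param Ck_pos,Ck_neg attachment-rate amplitude for strain bins with
#'   x >= 0 / x < 0 (s^-1 nm^-1).
#' @param kd_pos,kd_neg baseline detachment rate for x >= 0 / x < 0 (s^-1).
#' @param kdb_pos,kdb_neg strain-dependent detachment coefficient for
#'   x >= 0 / x < 0 (s^-1 nm^-4).
#' @param kT thermal energy scale in the attachment Boltzmann factor (J).
#'   Default is body temperature, 1.381e-23 * 310 K.
#' @param bins ordered strain-bin centres (nm); must be 21 uniformly
#'   spaced values, 1 nm apart, symmetric about zero.
#' @param sl_floor sarcomere length below which active stress is forced
#'   to zero (nm).
#' @param overlap_knots four half-sarcomere lengths (nm) defining the
#'   piecewise-linear single-peaked overlap function: zero below the
#'   first knot, rising to the plateau between knots 2 and 3, zero above
#'   the fourth.
#' @param shift_fraction fraction of the half-sarcomere length change by
#'   which the bound distribution is displaced each step.  The default
#'   1/2 implements the stated convention literally; 1 applies the full
#'   filament sliding for sensitivity checks.
#' @param clamp_negative_stress if `TRUE`, active stress is clamped at
#'   zero instead of being allowed transiently negative during rapid
#'   shortening.
#' @param coop_form form of the negative-cooperativity sink in the
#'   activation ODE: `"inactive"` (the as-written `-k_minus (N_overlap -
#'   N)`), `"active"` (`-k_minus N`) or `"unbound"` (`-k_minus (N -
#'   N_bound)`).  The alternatives exist for structural sensitivity
#'   analysis; see the methods vignette.
#'
#' @return An object of class `"active_params"` (a validated list).
#' @seealso [optimized_cases()], [attachment_rate()], [active_stress()]
#' @export
#' @examples
#' p <- active_params()
#' attachment_rate(0, p)   # equals Ck_pos at zero strain
active_params <- function(rho = 6.9e16, k_cb = 0.001, x_ps = 5,
                          a_on = 0.019, a_off = 211,
                          k_plus = 54, k_minus = 12,
                          Ck_pos = 1544, Ck_neg = 264,
                          kd_pos = 293, kd_neg = 195,
                          kdb_pos = 26, kdb_neg = 47,
                          kT = 1.380649e-23 * 310,
                          bins = seq(-10, 10, by = 1),
                          sl_floor = 1200,
                          overlap_knots = c(600, 850, 1170, 1500),
                          shift_fraction = 0.5,
                          clamp_negative_stress = FALSE,
                          coop_form = c("inactive", "active", "unbound")) {
  coop_form <- match.arg(coop_form)
  p <- list(rho = rho, k_cb = k_cb, x_ps = x_ps,
            a_on = a_on, a_off = a_off,
            k_plus = k_plus, k_minus = k_minus,
            Ck_pos = Ck_pos, Ck_neg = Ck_neg,
            kd_pos = kd_pos, kd_neg = kd_neg,
            kdb_pos = kdb_pos, kdb_neg = kdb_neg,
            kT = kT, bins = bins, sl_floor = sl_floor,
            overlap_knots = overlap_knots,
            shift_fraction = shift_fraction,
            clamp_negative_stress = clamp_negative_stress,
            coop_form = coop_form)
  validate_active_params(p)
  class(p) <- "active_params"
  p
}

validate_active_params <- function(p) {
  stopifnot(length(p$bins) == 21L)
  dx <- diff(p$bins)
  if (any(abs(dx - 1) > 1e-12))
    stop("strain bins must be uniformly spaced 1 nm apart")
  if (abs(p$bins[1] + p$bins[21]) > 1e-12)
    stop("strain bins must be symmetric about zero")
  if (p$rho <= 0 || p$k_cb <= 0)
    stop("rho and k_cb must be strictly positive")
  if (p$kT <= 0)
    stop("thermal energy kT must be strictly positive")
  rates <- c(p$a_on, p$a_off, p$k_plus, p$k_minus,
             p$Ck_pos, p$Ck_neg, p$kd_pos, p$kd_neg,
             p$kdb_pos, p$kdb_neg)
  if (any(rates < 0)) stop("rate constants must be non-negative")
  if (length(p$overlap_knots) != 4L || is.unsorted(p$overlap_knots))
    stop("overlap_knots must be four non-decreasing lengths (nm)")
  if (!(p$shift_fraction %in% c(0.5, 1)) &&
      (p$shift_fraction <= 0 || p$shift_fraction > 1))
    stop("shift_fraction must lie in (0, 1]")
  invisible(p)
}

#' Optimized rate-constant sets for the five study hearts
#'
#' The ten activation/cooperativity/kinetics constants estimated for
#' each of the five animal hearts, merged with the fixed
#' stress-conversion constants, as a list of [active_params()] objects.
#'
#' @param case integer vector selecting cases (1 to 5); default all five.
#' @param ... further arguments (e.g. `coop_form`, `shift_fraction`)
#'   passed on to [active_params()].
#' @return A named list of `"active_params"` objects (`case1` ... `case5`),
#'   or a single object when `case` has length one.
#' @export
#' @examples
#' p1 <- optimized_cases(1)
#' p1$a_on
optimized_cases <- function(case = 1:5, ...) {
  tab <- data.frame(
    a_on    = c(0.019, 0.020, 0.028, 0.024, 0.021),
    a_off   = c(211,   348,   309,   460,   206),
    Ck_pos  = c(1544,  1735,  1885,  2085,  2015),
    Ck_neg  = c(264,   1345,  1166,  1113,  529),
    kd_pos  = c(293,   343,   280,   190,   247),
    kd_neg  = c(195,   74,    51,    290,   267),
    kdb_pos = c(26,    49,    47,    42,    36),
    kdb_neg = c(47,    19,    28,    18,    19),
    k_plus  = c(54,    50,    40,    72,    35),
    k_minus = c(12,    14,    19,    18,    13))
  stopifnot(all(case %in% 1:5))
  out <- lapply(case, function(i) {
    do.call(active_params, c(as.list(tab[i, ]), list(...)))
  })
  names(out) <- paste0("case", case)
  if (length(out) == 1L) out[[1L]] else out
}

#' Initial parameter search ranges for the ten optimized constants
#'
#' The per-parameter lower/upper bounds within which the hybrid optimizer
#' searches, as used to initialise the fits that produced
#' [optimized_cases()].
#'
#' @return A data frame with columns `name`, `lower`, `upper`.
#' @seealso [fit_contraction()]
#' @export
param_bounds <- function() {
  data.frame(
    name  = c("a_on", "a_off", "Ck_pos", "Ck_neg", "kd_pos", "kd_neg",
              "kdb_pos", "kdb_neg", "k_plus", "k_minus"),
    lower = c(0.001, 100, 0, 0, 0, 0, 0, 0, 0, 0),
    upper = c(0.04, 1000, 2100, 2100, 400, 400, 50, 50, 100, 20),
    stringsAsFactors = FALSE)
}

#' @method print active_params
#' @export
print.active_params <- function(x, ...) {
  cat("Two-state cross-bridge model parameters\n")
  cat(sprintf("  stress scale : rho = %.3g m^-2, k_cb = %.3g N/m, x_ps = %g nm\n",
              x$rho, x$k_cb, x$x_ps))
  cat(sprintf("  activation   : a_on = %.3g /s/nM, a_off = %.3g /s, k_plus = %.3g /s, k_minus = %.3g /s (%s)\n",
              x$a_on, x$a_off, x$k_plus, x$k_minus, x$coop_form))
  cat(sprintf("  attachment   : Ck = %g (x>=0) / %g (x<0) /s/nm, kT = %.3g J\n",
              x$Ck_pos, x$Ck_neg, x$kT))
  cat(sprintf("  detachment   : kd = %g/%g /s, kdb = %g/%g /s/nm^4\n",
              x$kd_pos, x$kd_neg, x$kdb_pos, x$kdb_neg))
  cat(sprintf("  bins         : %d bins, %g..%g nm; SL floor %g nm\n",
              length(x$bins), min(x$bins), max(x$bins), x$sl_floor))
  invisible(x)
}
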