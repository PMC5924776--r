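#' Half-sarcomere state
#'
#' The cellular state at one material point: half-sarcomere length, the
#' activated binding-site fraction `N_on`, and the bound-head fraction
#' `A` over the 21 cross-bridge strain bins.
#'
#' @param hsl half-sarcomere length (nm).
#' @param N_on activated binding-site fraction in `[0, 1]`.
#' @param A bound-head fraction per strain bin (length 21, each >= 0).
#' @param t simulation time (s).
#' @return An object of class `"hs_state"`.
#' @export
hs_state <- function(hsl = 1150, N_on = 0, A = numeric(21), t = 0) {
  stopifnot(hsl > 0, length(A) == 21L)
  if (any(A < -1e-14)) stop("bound-head fractions must be non-negative")
  A <- pmax(A, 0)
  if (N_on < sum(A) - 1e-10)
    stop("N_on must not be smaller than the bound fraction sum(A)")
  s <- list(hsl = hsl, N_on = max(N_on, sum(A)), A = A, t = t)
  class(s) <- "hs_state"
  s
}

#' @method print hs_state
#' @export
print.hs_state <- function(x, ...) {
  cat(sprintf("half-sarcomere state @ t = %.4g s\n", x$t))
  cat(sprintf("  hsl = %.1f nm (SL %.1f nm)\n", x$hsl, 2 * x$hsl))
  cat(sprintf("  N_on = %.4f, N_bound = %.4f, D = %.4f\n",
              x$N_on, sum(x$A), x$N_on - sum(x$A)))
  invisible(x)
}

#' Strain-dependent attachment rate density
#'
#' Boltzmann-weighted attachment: `Ck * exp(-k_cb x^2 / (2 kT))`, with
#' the amplitude `Ck_pos` for bins at `x >= 0` and `Ck_neg` for `x < 0`.
#' `x` is the cross-bridge strain in nm (converted to metres inside the
#' exponent).
#'
#' @param x cross-bridge strain (nm); vectorised.
#' @param p an [active_params()] object.
#' @return Attachment rate density (s^-1 nm^-1).
#' @export
attachment_rate <- function(x, p) {
  if (p$kT <= 0) stop("kT must be positive")
  Ck <- ifelse(x >= 0, p$Ck_pos, p$Ck_neg)
  Ck * exp(-p$k_cb * (x * 1e-9)^2 / (2 * p$kT))
}

#' Strain-dependent detachment rate
#'
#' `kd + kdb * x^4` with the positive-side constants for `x >= 0` and the
#' negative-side constants for `x < 0`; the quartic makes highly strained
#' heads detach rapidly in either direction.
#'
#' @inheritParams attachment_rate
#' @return Detachment rate (s^-1).
#' @export
detachment_rate <- function(x, p) {
  kd <- ifelse(x >= 0, p$kd_pos, p$kd_neg)
  kdb <- ifelse(x >= 0, p$kdb_pos, p$kdb_neg)
  kd + kdb * x^4
}

#' Thick/thin filament overlap fraction
#'
#' Piecewise-linear single-peaked function of half-sarcomere length:
#' zero at and below the first knot, rising linearly to the full-overlap
#' plateau between the middle knots, and declining to zero at the fourth
#' knot.  The default knots (600, 850, 1170, 1500 nm) place the
#' 2300 nm-sarcomere protocols on the plateau and make active stress
#' vanish as the sarcomere approaches the 1200 nm floor.
#'
#' @param hsl half-sarcomere length (nm); vectorised.
#' @param p an [active_params()] object (only `overlap_knots` is used).
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(hsl, p) {
  stopifnot(all(hsl > 0))
  k <- p$overlap_knots
  up <- (hsl - k[1]) / (k[2] - k[1])
  down <- (k[4] - hsl) / (k[4] - k[3])
  pmax(0, pmin(1, pmin(up, down)))
}

coop_sink <- function(p, N, Nb, Nov) {
  switch(p$coop_form,
         inactive = p$k_minus * (Nov - N),
         active   = p$k_minus * N,
         unbound  = p$k_minus * (N - Nb))
}

#' Advance the activated-site fraction by one forward-Euler step
#'
#' Integrates
#' `dN/dt = a_on [Ca] (N_overlap - N) - a_off (N - N_bound)
#'          + k_plus N_bound - k_minus (N_overlap - N)`
#' with one explicit Euler step, then clamps the result to
#' `[N_bound, N_overlap]` so that the activated fraction can neither drop
#' below the bound fraction nor exceed the sites in reach.
#'
#' @param s an [hs_state()] object.
#' @param ca free calcium concentration (nM).
#' @param dt time step (s).
#' @param p an [active_params()] object.
#' @return The updated `"hs_state"`.
#' @export
evolve_activation <- function(s, ca, dt, p) {
  stopifnot(dt > 0, ca >= 0)
  Nov <- overlap_fraction(s$hsl, p)
  Nb <- sum(s$A)
  dN <- p$a_on * ca * (Nov - s$N_on) -
    p$a_off * (s$N_on - Nb) +
    p$k_plus * Nb -
    coop_sink(p, s$N_on, Nb, Nov)
  N_new <- s$N_on + dt * dN
  # conditions (i)-(iii): N >= 0, N >= N_bound, D >= 0
  s$N_on <- min(max(N_new, Nb, 0), max(Nov, Nb))
  s
}

#' Advance the bound-head distribution by one adaptive RK4 macro step
#'
#' Integrates the 21 coupled bin equations
#' `dA_i/dt = k1(x_i) dx D - k-1(x_i) A_i` over `dt` with classical RK4
#' and step-doubling error control (two half steps against one full
#' step).  The detached pool `D = N_on - sum(A)` is recomputed inside
#' every Runge-Kutta stage, and the attachment density `k1` is multiplied
#' by the 1 nm bin width to yield a per-bin flux.
#'
#' @inheritParams evolve_activation
#' @param tol absolute per-bin error tolerance for the step-doubling
#'   control.
#' @param max_sub maximum number of sub-steps the macro step may be
#'   divided into.
#' @return The updated `"hs_state"` (time advanced by `dt`).
#' @export
evolve_bound <- function(s, dt, p, tol = 1e-8, max_sub = 1024L) {
  stopifnot(dt > 0)
  k1 <- attachment_rate(p$bins, p) * 1   # bin width 1 nm
  km1 <- detachment_rate(p$bins, p)
  N <- s$N_on

  deriv <- function(A) k1 * max(N - sum(A), 0) - km1 * A
  rk4 <- function(A, h) {
    f1 <- deriv(A)
    f2 <- deriv(A + h / 2 * f1)
    f3 <- deriv(A + h / 2 * f2)
    f4 <- deriv(A + h * f3)
    A + h / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
  }

  # start near the RK4 stability limit of the stiffest bin
  n_sub <- 1L
  while (n_sub < max_sub && dt / n_sub > 2.5 / max(km1)) n_sub <- n_sub * 2L
  repeat {
    h <- dt / n_sub
    A <- s$A
    ok <- TRUE
    for (i in seq_len(n_sub)) {
      full <- rk4(A, h)
      half <- rk4(rk4(A, h / 2), h / 2)
      err <- max(abs(full - half))
      if (is.na(err) || err > tol) { ok <- FALSE; break }
      A <- half
    }
    if (ok) break
    if (n_sub >= max_sub)
      stop("evolve_bound: error control failed to reach tolerance within ",
           max_sub, " sub-steps")
    n_sub <- n_sub * 2L
  }
  s$A <- pmax(A, 0)
  s$t <- s$t + dt
  s
}

#' Displace the bound distribution by interfilamentary sliding
#'
#' When the half-sarcomere length changes by `delta_hsl` between steps,
#' the strains of all attached heads change together; the distribution is
#' resampled onto the fixed bin grid displaced by
#' `shift_fraction * delta_hsl` (default half) using linear
#' interpolation.  Mass carried past either end of the +-10 nm grid is
#' dropped: heads pulled to extreme strain detach.
#'
#' @param s an [hs_state()] object.
#' @param delta_hsl change in half-sarcomere length over the step (nm);
#'   positive = lengthening.
#' @param p an [active_params()] object.
#' @return The updated `"hs_state"` (note: `hsl` itself is not changed
#'   here; the caller owns the kinematics).
#' @export
shift_distribution <- function(s, delta_hsl, p) {
  shift <- p$shift_fraction * delta_hsl
  span <- max(p$bins) - min(p$bins)
  if (abs(shift) >= span)
    stop("distribution shift of ", signif(shift, 3),
         " nm exceeds the bin-grid span; reduce the step size")
  if (shift == 0) return(s)
  # a head formerly at strain x now sits at x + shift; sample the old
  # distribution at x - shift on the fixed grid
  src <- p$bins - shift
  lo <- floor(src - min(p$bins))      # index offset of left neighbour
  w <- src - min(p$bins) - lo         # interpolation weight
  i0 <- lo + 1L
  get <- function(idx) ifelse(idx >= 1L & idx <= 21L, s$A[pmax(pmin(idx, 21L), 1L)], 0)
  A_new <- (1 - w) * get(i0) + w * get(i0 + 1L)
  s$A <- pmax(A_new, 0)
  s
}

#' Active fiber stress from the bound-head distribution
#'
#' `T = rho k_cb sum_i A(x_i) (x_i + x_ps)` with lengths converted to
#' metres.  Stress is forced to zero when the sarcomere length
#' `2 * hsl` is at or below the floor (default 1200 nm); negative totals
#' during rapid shortening are permitted unless
#' `clamp_negative_stress = TRUE`.
#'
#' @param s an [hs_state()] object.
#' @param p an [active_params()] object.
#' @return Fiber stress (Pa).
#' @export
active_stress <- function(s, p) {
  if (2 * s$hsl <= p$sl_floor) return(0)
  T_fib <- p$rho * p$k_cb * sum(s$A * (p$bins + p$x_ps) * 1e-9)
  if (p$clamp_negative_stress) T_fib <- max(T_fib, 0)
  T_fib
}

#' One coupled macro step of the half-sarcomere engine
#'
#' Applies, in order: the distribution shift for the imposed length
#' change, the half-sarcomere length update, the adaptive-RK4 bound-head
#' update, and the forward-Euler activation update.
#'
#' @param s an [hs_state()] object.
#' @param ca calcium concentration over the step (nM).
#' @param delta_hsl imposed half-sarcomere length change (nm).
#' @param dt macro time step (s).
#' @param p an [active_params()] object.
#' @return The updated `"hs_state"`.
#' @export
step_half_sarcomere <- function(s, ca, delta_hsl, dt, p) {
  if (delta_hsl != 0) {
    s <- shift_distribution(s, delta_hsl, p)
    s$hsl <- s$hsl + delta_hsl
  }
  s <- evolve_bound(s, dt, p)
  s <- evolve_activation(s, ca, dt, p)
  s
}

# pack an active_params object into the flat numeric vector consumed by
# the C++ stepper; order must match kinetics.cpp
pack_active <- function(p) {
  c(p$rho, p$k_cb, p$x_ps, p$a_on, p$a_off, p$k_plus, p$k_minus,
    p$Ck_pos, p$Ck_neg, p$kd_pos, p$kd_neg, p$kdb_pos, p$kdb_neg,
    p$kT, p$sl_floor, p$overlap_knots, p$shift_fraction,
    as.numeric(p$clamp_negative_stress),
    match(p$coop_form, c("inactive", "active", "unbound")))
}

#' Simulate the half-sarcomere engine along a prescribed schedule
#'
#' Fast path for the cellular protocols: advances the coupled
#' activation/distribution system along per-step schedules of calcium
#' and half-sarcomere length, using the same algorithm as
#' [step_half_sarcomere()] (compiled).
#'
#' @param p an [active_params()] object.
#' @param ca calcium schedule (nM), one value per macro step.
#' @param hsl half-sarcomere length schedule (nm), one value per macro
#'   step; length changes between consecutive steps shift the bound
#'   distribution.
#' @param dt macro time step (s).
#' @param state optional initial [hs_state()]; defaults to the rested
#'   state at `hsl[1]`.
#' @return A list with `trace` (data frame: `t`, `hsl`, `N_on`,
#'   `N_bound`, `T` in Pa) and `state` (final `"hs_state"`).
#' @export
simulate_half_sarcomere <- function(p, ca, hsl, dt, state = NULL) {
  n <- length(ca)
  stopifnot(length(hsl) == n, dt > 0)
  if (is.null(state)) state <- hs_state(hsl = hsl[1])
  out <- xb_simulate_cpp(pack_active(p), p$bins, ca, hsl, dt,
                         state$N_on, state$A, state$hsl)
  trace <- data.frame(t = state$t + dt * seq_len(n),
                      hsl = hsl, N_on = out$N, N_bound = out$Nb,
                      T = out$T)
  final <- hs_state(hsl = hsl[n], N_on = out$N[n], A = out$A_final,
                    t = state$t + dt * n)
  list(trace = trace, state = final)
}
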