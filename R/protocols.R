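#' Convert pCa to free calcium in nM
#'
#' @param pca -log10 of molar calcium.
#' @return Calcium concentration (nM).
#' @export
pca_to_nM <- function(pca) 10^(-pca) * 1e9

run_to_plateau <- function(p, ca, hsl, dt = 1e-4, max_duration = 5,
                           chunk = 0.25, rel_tol = 1e-5, abs_tol = 1e-3,
                           state = NULL) {
  # advance in chunks until the tension change per chunk is negligible
  n_chunk <- max(2L, round(chunk / dt))
  elapsed <- 0
  T_last <- NA_real_
  converged <- FALSE
  trace <- NULL
  while (elapsed < max_duration) {
    sim <- simulate_half_sarcomere(p, rep(ca, n_chunk), rep(hsl, n_chunk),
                                   dt, state = state)
    state <- sim$state
    trace <- if (is.null(trace)) sim$trace else rbind(trace, sim$trace)
    elapsed <- elapsed + n_chunk * dt
    T_now <- sim$trace$T[n_chunk]
    if (!is.na(T_last) &&
        abs(T_now - T_last) < abs_tol + rel_tol * abs(T_now)) {
      converged <- TRUE
      break
    }
    T_last <- T_now
  }
  list(state = state, trace = trace, converged = converged,
       tension = active_stress(state, p))
}

#' Steady isometric tension at fixed sarcomere length
#'
#' Holds the half-sarcomere at `sl/2` under constant calcium, integrates
#' the coupled activation/distribution system from the rested state to a
#' tension plateau, and returns the plateau stress.  With the default
#' saturating calcium (pCa 4.5) this is the maximal tension protocol.
#'
#' @param p an [active_params()] object.
#' @param sl sarcomere length (nm); the engine works on `sl/2`.
#' @param ca calcium concentration (nM); default saturating (pCa 4.5).
#' @param duration maximum integration time (s).
#' @param dt macro time step (s).
#' @return An object of class `"isometric_run"`: list with `T_max` (kPa),
#'   `converged`, `state` and the tension `trace`.
#' @export
run_isometric <- function(p, sl = 2300, ca = pca_to_nM(4.5),
                          duration = 5, dt = 1e-4) {
  out <- run_to_plateau(p, ca, sl / 2, dt = dt, max_duration = duration)
  if (!out$converged)
    warning("isometric run did not reach |dT/dt| tolerance within ",
            duration, " s; returning the last value")
  structure(list(T_max = out$tension / 1e3, converged = out$converged,
                 state = out$state, trace = out$trace,
                 sl = sl, ca = ca),
            class = "isometric_run")
}

#' @method print isometric_run
#' @export
print.isometric_run <- function(x, ...) {
  cat(sprintf("isometric protocol: SL %g nm, [Ca] %.3g nM\n", x$sl, x$ca))
  cat(sprintf("  plateau tension %.2f kPa (%s)\n", x$T_max,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the Hill equation to a force-pCa relation
#'
#' Fits `T = T_max [Ca]^n / ([Ca]^n + Ca50^n)` by nonlinear least
#' squares on tensions normalised to the plateau, parameterised in
#' log-calcium space for conditioning.
#'
#' @param pca vector of pCa values.
#' @param tension steady tensions (any consistent unit).
#' @return A list with `pCa50`, `hill_n`, the `fit` object and the
#'   normalised residual sum of squares.
#' @export
hill_fit <- function(pca, tension) {
  if (max(tension) <= 0)
    stop("Hill fit failed: no tension developed at any calcium level",
         "\n  tensions: ", paste(signif(tension, 4), collapse = ", "))
  t_rel <- tension / max(tension)
  logca <- -pca  # log10 of molar calcium
  hill <- function(A, p50, n) A / (1 + 10^(-n * (p50 + logca)))
  sse <- function(par) sum((t_rel - hill(par[1], par[2], par[3]))^2)
  # robust pre-fit (handles near-step curves), then Gauss-Newton polish;
  # the plateau amplitude A is free so an unsaturated top level does not
  # bias the midpoint
  start <- c(A = 1, p50 = pca[which.min(abs(t_rel - 0.5))], n = 2)
  pre <- optim(start, sse, method = "L-BFGS-B",
               lower = c(0.5, 3, 0.05), upper = c(2, 9, 200),
               control = list(factr = 1e3, maxit = 500))
  df <- data.frame(logca = logca, t_rel = t_rel)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      t_rel ~ A / (1 + 10^(-n * (p50 + logca))),
      data = df, start = as.list(pre$par),
      lower = c(A = 0.5, p50 = 3, n = 0.05),
      upper = c(A = 2, p50 = 9, n = 200),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit) && sum(residuals(fit)^2) <= pre$value + 1e-12) {
    est <- coef(fit)
    list(pCa50 = unname(est["p50"]), hill_n = unname(est["n"]),
         fit = fit, rss = sum(residuals(fit)^2))
  } else {
    list(pCa50 = unname(pre$par["p50"]), hill_n = unname(pre$par["n"]),
         fit = pre, rss = pre$value)
  }
}

#' Steady force-calcium relation with Hill fit
#'
#' Computes the steady tension at each pCa on the grid (each from a
#' rested start), then summarises the curve by its Hill fit: calcium
#' sensitivity `pCa50` and Hill coefficient.
#'
#' @inheritParams run_isometric
#' @param pca_grid grid of pCa values; must span at least 7.5 to 4.5.
#' @param warn_nonmonotone warn if steady tension is not non-decreasing
#'   in calcium.
#' @return An object of class `"force_pca"`: list with `pca`, `tension`
#'   (kPa), `pCa50`, `hill_n` and the fit.
#' @export
run_force_pca <- function(p, sl = 2300, pca_grid = seq(7.5, 4.5, by = -0.25),
                          duration = 5, dt = 1e-4, warn_nonmonotone = TRUE) {
  if (min(pca_grid) > 4.5 || max(pca_grid) < 7.5)
    stop("pca_grid must span at least pCa 7.5 to 4.5")
  pca_grid <- sort(pca_grid, decreasing = TRUE)
  tension <- vapply(pca_grid, function(pca) {
    run_to_plateau(p, pca_to_nM(pca), sl / 2, dt = dt,
                   max_duration = duration)$tension / 1e3
  }, numeric(1))
  if (warn_nonmonotone && any(diff(tension) < -1e-6 * max(tension)))
    warning("steady tension is not monotone in calcium; Hill summary ",
            "may be unreliable")
  hf <- hill_fit(pca_grid, tension)
  structure(list(pca = pca_grid, tension = tension,
                 pCa50 = hf$pCa50, hill_n = hf$hill_n, fit = hf$fit,
                 sl = sl),
            class = "force_pca")
}

#' @method print force_pca
#' @export
print.force_pca <- function(x, ...) {
  cat(sprintf("force-pCa protocol at SL %g nm (%d levels)\n",
              x$sl, length(x$pca)))
  cat(sprintf("  plateau %.2f kPa, pCa50 = %.3f, Hill n = %.3f\n",
              max(x$tension), x$pCa50, x$hill_n))
  invisible(x)
}

#' @method plot force_pca
#' @export
plot.force_pca <- function(x, ...) {
  graphics::plot(x$pca, x$tension, xlim = rev(range(x$pca)),
                 xlab = "pCa", ylab = "steady tension (kPa)",
                 main = "Force-pCa", ...)
  pca_fine <- seq(max(x$pca), min(x$pca), length.out = 200)
  t_fit <- max(x$tension) / (1 + 10^(-x$hill_n * (x$pCa50 - pca_fine)))
  graphics::lines(pca_fine, t_fit, col = "grey40")
  invisible(x)
}

#' Tension redevelopment rate after release-restretch
#'
#' From the steady activated state the half-sarcomere is slackened by
#' `release_frac` (the bound distribution shifting accordingly, which
#' drives the strained heads off the grid), held for `hold` seconds,
#' restretched to the original length in one step, and the
#' re-developing tension fitted with
#' `T(t) = T_ss - (T_ss - T0) exp(-ktr t)`.
#'
#' @inheritParams run_isometric
#' @param release_frac fractional length release in (0, 1).
#' @param hold hold duration at the short length (s).
#' @param recovery recorded recovery window after restretch (s).
#' @param r2_warn warn if the mono-exponential fit has R^2 below this.
#' @return An object of class `"ktr_run"`: list with `ktr` (s^-1), the
#'   recovery trace, fit and `r_squared`.
#' @export
run_ktr <- function(p, sl = 2300, ca = pca_to_nM(4.5),
                    release_frac = 0.2, hold = 0.02, recovery = 0.25,
                    duration = 5, dt = 1e-4, r2_warn = 0.95) {
  stopifnot(release_frac > 0, release_frac < 1)
  hsl0 <- sl / 2
  pre <- run_to_plateau(p, ca, hsl0, dt = dt, max_duration = duration)
  # the release and restretch are ramped over a few macro steps so that
  # each per-step distribution shift stays within the bin grid; the ramp
  # (~2 ms) is quasi-instantaneous relative to the recovery
  hsl_short <- (1 - release_frac) * hsl0
  span <- (max(p$bins) - min(p$bins)) / p$shift_fraction
  n_ramp <- max(2L, ceiling(abs(hsl_short - hsl0) / (0.9 * span)))
  ramp_dn <- seq(hsl0, hsl_short, length.out = n_ramp + 1L)[-1L]
  ramp_up <- seq(hsl_short, hsl0, length.out = n_ramp + 1L)[-1L]
  n_hold <- max(1L, round(hold / dt))
  sched_hsl <- c(ramp_dn, rep(hsl_short, n_hold), ramp_up)
  hold_sim <- simulate_half_sarcomere(p, rep(ca, length(sched_hsl)),
                                      sched_hsl, dt, state = pre$state)
  n_rec <- max(5L, round(recovery / dt))
  rec <- simulate_half_sarcomere(p, rep(ca, n_rec), rep(hsl0, n_rec), dt,
                                 state = hold_sim$state)
  tt <- dt * seq_len(n_rec)
  TT <- rec$trace$T / 1e3
  df <- data.frame(tt = tt, TT = TT)
  fit <- minpack.lm::nlsLM(TT ~ Tss - (Tss - T0) * exp(-k * tt),
                           data = df,
                           start = list(Tss = TT[n_rec], T0 = TT[1],
                                        k = 5 / recovery),
                           lower = c(Tss = 0, T0 = -Inf, k = 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  r2 <- 1 - sum(residuals(fit)^2) / sum((TT - mean(TT))^2)
  if (r2 < r2_warn)
    warning(sprintf(
      "ktr recovery fit R^2 = %.3f below %.2f; residual range %.3g kPa",
      r2, r2_warn, diff(range(residuals(fit)))))
  est <- coef(fit)
  structure(list(ktr = unname(est["k"]), T_ss = unname(est["Tss"]),
                 trace = data.frame(t = tt, T = TT),
                 fit = fit, r_squared = r2, sl = sl, ca = ca),
            class = "ktr_run")
}

#' @method print ktr_run
#' @export
print.ktr_run <- function(x, ...) {
  cat(sprintf("ktr protocol: SL %g nm, [Ca] %.3g nM\n", x$sl, x$ca))
  cat(sprintf("  ktr = %.2f /s (fit R^2 = %.4f), T_ss = %.2f kPa\n",
              x$ktr, x$r_squared, x$T_ss))
  invisible(x)
}

#' Twitch contraction driven by a calcium transient
#'
#' Runs the half-sarcomere engine through one or more calcium
#' transients.  Under `load = "isometric"` the length is held fixed;
#' under `load = "unloaded"` the half-sarcomere shortens each step to
#' the length at which the active stress balances a vanishing load
#' (zero-tension isotonic limit), subject to a maximum shortening
#' velocity so the distribution shift stays within the bin grid.
#'
#' @param p an [active_params()] object.
#' @param ca a [make_calcium()] transient (or any function `t -> nM`).
#' @param load `"isometric"` or `"unloaded"`.
#' @param sl initial sarcomere length (nm).
#' @param n_cycles number of transient periods to simulate.
#' @param dt macro time step (s).
#' @param v_max maximum half-sarcomere shortening/re-lengthening speed
#'   (nm/s) for the unloaded case.
#' @return An object of class `"twitch_run"` with the trace
#'   (`t`, `hsl`, `N_on`, `N_bound`, `T` in kPa).
#' @export
run_twitch <- function(p, ca, load = c("isometric", "unloaded"),
                       sl = 2300, n_cycles = 1, dt = 1e-4,
                       v_max = 5e4) {
  load <- match.arg(load)
  ca_fun <- if (is.function(ca)) ca else ca_at(ca)
  period <- if (is.function(ca)) NULL else ca$period
  if (is.null(period)) stop("run_twitch needs a transient with a period; ",
                            "pass a make_calcium() object")
  n <- round(n_cycles * period / dt)
  tt <- dt * seq_len(n)
  ca_sched <- ca_fun(tt)
  hsl0 <- sl / 2
  if (load == "isometric") {
    sim <- simulate_half_sarcomere(p, ca_sched, rep(hsl0, n), dt)
    trace <- sim$trace
  } else {
    state <- hs_state(hsl = hsl0)
    pp <- pack_active(p)
    trace <- data.frame(t = tt, hsl = NA_real_, N_on = NA_real_,
                        N_bound = NA_real_, T = NA_real_)
    max_step <- v_max * dt
    for (i in seq_len(n)) {
      step_T <- function(d_hsl) {
        out <- xb_simulate_cpp(pp, p$bins, ca_sched[i],
                               state$hsl + d_hsl, dt,
                               state$N_on, state$A, state$hsl)
        out$T[1]
      }
      d <- 0
      if (step_T(0) > 0) {
        # shorten until stress balances the (zero) load
        lo <- -min(max_step, state$hsl - p$sl_floor / 2 - 1)
        d <- if (step_T(lo) > 0) lo else
          stats::uniroot(step_T, c(lo, 0), tol = 1e-3)$root
      } else if (state$hsl < hsl0) {
        # re-lengthen toward the slack length while stress stays zero-
        hi <- min(max_step, hsl0 - state$hsl)
        d <- if (step_T(hi) <= 0) hi else
          stats::uniroot(step_T, c(0, hi), tol = 1e-3)$root
      }
      out <- xb_simulate_cpp(pp, p$bins, ca_sched[i], state$hsl + d, dt,
                             state$N_on, state$A, state$hsl)
      state <- hs_state(hsl = state$hsl + d, N_on = out$N[1],
                        A = out$A_final, t = tt[i])
      trace[i, ] <- c(tt[i], state$hsl, out$N[1], out$Nb[1], out$T[1])
    }
  }
  trace$T <- trace$T / 1e3
  structure(list(trace = trace, load = load, sl = sl, dt = dt),
            class = "twitch_run")
}

#' @method print twitch_run
#' @export
print.twitch_run <- function(x, ...) {
  cat(sprintf("twitch (%s), SL0 %g nm, %.3g s\n", x$load, x$sl,
              max(x$trace$t)))
  cat(sprintf("  peak T %.2f kPa, peak N_on %.3f, peak N_bound %.3f\n",
              max(x$trace$T), max(x$trace$N_on), max(x$trace$N_bound)))
  if (x$load == "unloaded")
    cat(sprintf("  min SL %.0f nm\n", 2 * min(x$trace$hsl)))
  invisible(x)
}

#' @method plot twitch_run
#' @export
plot.twitch_run <- function(x, ...) {
  graphics::plot(x$trace$t, x$trace$T, type = "l", xlab = "time (s)",
                 ylab = "tension (kPa)", main = "Twitch", ...)
  invisible(x)
}

#' Run all single-element protocols for one parameter set
#'
#' Convenience wrapper: maximal tension, force-pCa (with Hill summary)
#' and tension redevelopment at saturating and low calcium.  The low
#' calcium level for `ktr_min` is the lowest pCa on the force-pCa grid
#' whose steady tension reaches `low_frac` of the plateau.
#'
#' @inheritParams run_isometric
#' @param low_frac threshold fraction of maximal tension defining the
#'   "low calcium" level for the minimum-ktr run.
#' @param ... passed to the individual protocols.
#' @return A list with `T_max` (kPa), `pCa50`, `hill_n`, `ktr_max`,
#'   `ktr_min` (s^-1) and the underlying protocol objects.
#' @export
run_cell_protocols <- function(p, sl = 2300, low_frac = 0.05, ...) {
  iso <- run_isometric(p, sl = sl, ...)
  fpca <- run_force_pca(p, sl = sl, ...)
  ktr_hi <- run_ktr(p, sl = sl, ca = pca_to_nM(4.5), ...)
  above <- which(fpca$tension >= low_frac * max(fpca$tension))
  pca_low <- max(fpca$pca[above])
  ktr_lo <- run_ktr(p, sl = sl, ca = pca_to_nM(pca_low), ...)
  list(T_max = iso$T_max, pCa50 = fpca$pCa50, hill_n = fpca$hill_n,
       ktr_max = ktr_hi$ktr, ktr_min = ktr_lo$ktr, pca_low = pca_low,
       isometric = iso, force_pca = fpca,
       ktr_sat = ktr_hi, ktr_low = ktr_lo)
}
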