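#' Objective combining strain and pressure mismatch
#'
#' The fitting objective is the sum over strain points of squared
#' absolute component errors (all nine tensor slots, so off-diagonal
#' shears count twice) plus the sum over the six pressure points of
#' squared relative errors:
#' `Phi = sum_n sum_ij (E_ij,n - E*_ij,n)^2 + sum_m ((P_m - P*_m)/P*_m)^2`.
#'
#' @param pred list with `strains` (data frame with columns `E_cc`,
#'   `E_rr`, `E_ll`, `E_cr`, `E_cl`, `E_rl`) and `pressures` (numeric,
#'   same length as the targets).
#' @param targets an [objective_targets()] object (or a list of the same
#'   shape).
#' @return List with `phi`, `phi_strain`, `phi_pressure` and
#'   `phi_strain_per_point`.
#' @export
objective_phi <- function(pred, targets) {
  comps <- c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl")
  w <- c(1, 1, 1, 2, 2, 2)           # off-diagonals occupy two slots
  Sp <- as.matrix(pred$strains[, comps])
  St <- as.matrix(targets$strains[, comps])
  if (!all(dim(Sp) == dim(St)))
    stop("strain predictions and targets are misaligned: ",
         nrow(Sp), " vs ", nrow(St), " points")
  if (length(pred$pressures) != length(targets$pressures))
    stop("pressure predictions and targets are misaligned")
  phi_s <- sum(sweep((Sp - St)^2, 2, w, `*`))
  phi_p <- sum(((pred$pressures - targets$pressures) /
                  targets$pressures)^2)
  list(phi = phi_s + phi_p, phi_strain = phi_s, phi_pressure = phi_p,
       phi_strain_per_point = phi_s / nrow(St))
}

#' Bundle strain and pressure targets for the optimizer
#'
#' @param strains data frame of strain components at the comparison
#'   points (>= 250 mid-layer points for organ-scale fits).
#' @param pressures the six target pressures (kPa): end-IVC, three
#'   ejection points (including the peak), end-systole, end-IVR.
#' @param min_points minimum strain point count enforced.
#' @return An object of class `"objective_targets"`.
#' @export
objective_targets <- function(strains, pressures, min_points = 250) {
  if (length(pressures) != 6)
    stop("exactly 6 pressure points are required")
  if (nrow(strains) < min_points)
    stop("at least ", min_points, " strain points are required; got ",
         nrow(strains))
  structure(list(strains = strains, pressures = pressures),
            class = "objective_targets")
}

#' Simulated-annealing global search
#'
#' Metropolis annealing on parameters scaled to the unit box by their
#' bounds: Gaussian proposals (sd `sigma` of the range) reflected at the
#' bounds, geometric cooling.  Deterministic for a fixed seed.
#'
#' @param fn objective: function of a named parameter vector.
#' @param lower,upper named bounds.
#' @param seed RNG seed.
#' @param control list: `t0` initial temperature (default the spread of
#'   a pilot sample), `ratio` cooling factor per stage, `moves` proposals
#'   per stage, `n_temps` stages, `sigma` proposal sd, `region_half`
#'   half-width (fraction of range) of the trust region handed to the
#'   local search.
#' @return List with `par`, `value`, `region` (lower/upper), `n_eval`
#'   and the acceptance trace.
#' @export
simulated_annealing <- function(fn, lower, upper, seed = 1,
                                control = list()) {
  ctl <- modifyList(list(t0 = NULL, ratio = 0.9, moves = 20,
                         n_temps = 15, sigma = 0.1, region_half = 0.15),
                    control)
  stopifnot(all(lower < upper))
  d <- length(lower)
  rng <- upper - lower
  unscale <- function(x) lower + x * rng
  set.seed(seed)
  x <- runif(d)
  fx <- fn(setNames(unscale(x), names(lower)))
  n_eval <- 1L
  if (is.null(ctl$t0)) {
    pilot <- replicate(5, fn(setNames(unscale(runif(d)), names(lower))))
    n_eval <- n_eval + 5L
    ctl$t0 <- max(stats::sd(c(pilot, fx)), abs(fx), 1e-8)
  }
  best_x <- x; best_f <- fx
  temp <- ctl$t0
  acc <- numeric(0)
  for (stage in seq_len(ctl$n_temps)) {
    n_acc <- 0L
    for (mv in seq_len(ctl$moves)) {
      prop <- x + rnorm(d, sd = ctl$sigma)
      # reflect into [0, 1]
      prop <- abs(prop)
      prop <- ifelse(prop %% 2 > 1, 2 - prop %% 2, prop %% 2)
      fp <- fn(setNames(unscale(prop), names(lower)))
      n_eval <- n_eval + 1L
      if (fp <= fx || runif(1) < exp(-(fp - fx) / temp)) {
        x <- prop; fx <- fp; n_acc <- n_acc + 1L
        if (fx < best_f) { best_x <- x; best_f <- fx }
      }
    }
    acc <- c(acc, n_acc / ctl$moves)
    temp <- temp * ctl$ratio
  }
  par <- setNames(unscale(best_x), names(lower))
  region <- list(
    lower = pmax(lower, par - ctl$region_half * rng),
    upper = pmin(upper, par + ctl$region_half * rng))
  list(par = par, value = best_f, region = region, n_eval = n_eval,
       acceptance = acc)
}

quad_terms <- function(X) {
  d <- ncol(X)
  out <- X
  nm <- colnames(X)
  for (i in seq_len(d)) for (j in i:d) {
    out <- cbind(out, X[, i] * X[, j])
    nm <- c(nm, paste0("q", i, "_", j))
  }
  colnames(out) <- nm
  out
}

#' Sequential response-surface local search
#'
#' Iteratively fits a full quadratic surrogate to a Latin-hypercube
#' design over the current region, moves the region centre to the
#' surrogate minimiser, and shrinks the region, until the region is
#' smaller than `tol` (fraction of the global range) or the iteration
#' cap is reached.
#'
#' @inheritParams simulated_annealing
#' @param region list with `lower`/`upper` start region (within bounds).
#' @param control list: `shrink` region contraction per iteration,
#'   `grow` re-expansion factor when the optimum sits on the region
#'   boundary, `n_iter` iteration cap, `n_pts` design points per
#'   iteration (default `2 d^2 + 1`), `tol` stopping size, `log_obj`
#'   whether the surrogate is fitted to the log objective.
#' @return List with `par`, `value`, `n_eval` and the per-iteration
#'   history.
#' @export
sequential_response_surface <- function(fn, region, lower, upper,
                                        seed = 1, control = list()) {
  d <- length(lower)
  ctl <- modifyList(list(shrink = 0.7, grow = 1.5, n_iter = 8,
                         n_pts = 2 * d^2 + 1, tol = 1e-3,
                         log_obj = TRUE), control)
  set.seed(seed)
  lo <- region$lower; hi <- region$upper
  rng_glob <- upper - lower
  best_par <- NULL; best_f <- Inf; n_eval <- 0L
  hist <- list()
  for (it in seq_len(ctl$n_iter)) {
    n_pts <- ctl$n_pts
    for (attempt in 1:2) {
      D <- lhs::randomLHS(n_pts, d)
      X <- sweep(sweep(D, 2, hi - lo, `*`), 2, lo, `+`)
      colnames(X) <- names(lower)
      if (!is.null(best_par))       # keep the incumbent in every design
        X <- rbind(X, pmin(pmax(best_par, lo), hi))
      y <- apply(X, 1, function(r) fn(setNames(r, names(lower))))
      n_eval <- n_eval + nrow(X)
      # quadratic surrogate on the unit-scaled region; the objective is
      # fitted on a log scale, which compresses its dynamic range and
      # keeps the surrogate informative over wide regions (the
      # minimiser is unchanged by the transform)
      Z <- sweep(sweep(X, 2, lo, `-`), 2, pmax(hi - lo, 1e-12), `/`)
      # log scale only while the objective spans decades across the
      # region; near the minimum a quadratic is exact on the linear
      # scale but cusped on the log scale
      spread <- (max(y) + 1e-300) / (min(y) + 1e-300)
      use_log <- ctl$log_obj && spread > 1e3
      yt <- if (use_log) log(y + 1e-10 * max(abs(y), 1)) else y
      df <- data.frame(y = yt, quad_terms(Z))
      fit <- lm(y ~ ., data = df)
      if (fit$rank == length(coef(fit))) break
      if (attempt == 2)
        stop("response-surface fit is rank-deficient even after ",
             "enlarging the design")
      n_pts <- 2 * n_pts
    }
    i_best <- which.min(y)
    if (y[i_best] < best_f) { best_f <- y[i_best]; best_par <- X[i_best, ] }
    # minimise the surrogate inside the region
    pr <- function(z) {
      zz <- matrix(z, 1, d, dimnames = list(NULL, names(lower)))
      unname(predict(fit, data.frame(quad_terms(zz))))
    }
    opt <- optim(Z[i_best, ], pr, method = "L-BFGS-B",
                 lower = rep(0, d), upper = rep(1, d))
    centre <- lo + opt$par * (hi - lo)
    # accept the surrogate minimiser through a short backtracking line
    # search from the incumbent: in curved narrow valleys the full step
    # overshoots the valley wall while a partial step still descends
    anchor <- if (is.null(best_par)) (lo + hi) / 2 else best_par
    f_inc <- best_f
    for (alpha in c(1, 0.5, 0.25)) {
      trial <- anchor + alpha * (centre - anchor)
      f_trial <- fn(setNames(trial, names(lower)))
      n_eval <- n_eval + 1L
      if (f_trial < best_f) { best_f <- f_trial; best_par <- trial }
      if (f_trial < f_inc) break      # successful step; stop backtracking
    }
    hist[[it]] <- list(size = max((hi - lo) / rng_glob), best = best_f)
    # domain reduction with panning and expansion: an interior optimum
    # contracts the region; an optimum on the boundary means the
    # minimum lies outside, so the region moves and grows again (this
    # lets the search walk along curved, nearly flat valleys instead of
    # inching along them at a frozen small size)
    move <- abs(best_par - (lo + hi) / 2) / pmax((hi - lo) / 2, 1e-300)
    eta <- ifelse(pmin(move, 1) > 0.9, ctl$grow,
                  ctl$shrink + (1 - ctl$shrink) * pmin(move, 1))
    half <- pmin((hi - lo) * eta / 2, rng_glob / 4)
    lo <- pmax(lower, best_par - half)
    hi <- pmin(upper, best_par + half)
    if (max((hi - lo) / rng_glob) < ctl$tol) break
  }
  list(par = setNames(best_par, names(lower)), value = best_f,
       n_eval = n_eval, history = hist)
}

#' Hybrid parameter estimation: annealing then response surface
#'
#' The estimation procedure used to fit the contractile parameters:
#' simulated annealing locates the promising region of parameter space,
#' then the sequential response-surface method refines to the local
#' minimum by iteratively shrinking the region.
#'
#' @param objective function of a named parameter vector returning the
#'   scalar objective (see [objective_phi()]).
#' @param bounds data frame with columns `name`, `lower`, `upper`
#'   (default [param_bounds()] restricted to `free`).
#' @param free names of the parameters to optimise.
#' @param seed master RNG seed; each chain derives its own stream.
#' @param chains number of independent annealing + response-surface
#'   chains; the best final point wins.  Restarting the stochastic
#'   search a few times is the standard guard against an unlucky
#'   trajectory.
#' @param sa_control,rs_control control lists for the two stages.
#' @return An object of class `"myofit"` with `coef`, `value`,
#'   `sa`, `rs` and call metadata for the winning chain.
#' @export
fit_contraction <- function(objective, bounds = param_bounds(),
                            free = bounds$name, seed = 1, chains = 3,
                            sa_control = list(), rs_control = list()) {
  bounds <- bounds[bounds$name %in% free, , drop = FALSE]
  lower <- setNames(bounds$lower, bounds$name)
  upper <- setNames(bounds$upper, bounds$name)
  run_chain <- function(chain_seed) {
    sa <- simulated_annealing(objective, lower, upper, seed = chain_seed,
                              control = sa_control)
    rs <- sequential_response_surface(objective, sa$region, lower, upper,
                                      seed = chain_seed + 1L,
                                      control = rs_control)
    est <- if (rs$value <= sa$value) rs$par else sa$par
    best_val <- min(rs$value, sa$value)
    # convergence pass: pure contraction (no re-expansion) in a tight
    # region about the incumbent polishes the final digits
    tight <- list(lower = pmax(lower, est - 0.02 * (upper - lower)),
                  upper = pmin(upper, est + 0.02 * (upper - lower)))
    polish_ctl <- modifyList(rs_control, list(grow = 1, n_iter = 25))
    rs2 <- sequential_response_surface(objective, tight, lower, upper,
                                       seed = chain_seed + 2L,
                                       control = polish_ctl)
    if (rs2$value < best_val) { best_val <- rs2$value; est <- rs2$par }
    # final simplex descent on the true objective (scaled coordinates):
    # the surrogate search localises the optimum, the simplex polishes
    # the last digits
    rng <- upper - lower
    fscaled <- function(z) {
      if (any(z < 0 | z > 1)) return(Inf)
      objective(setNames(lower + z * rng, names(lower)))
    }
    nm <- optim((est - lower) / rng, fscaled, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-14))
    if (nm$value < best_val) {
      best_val <- nm$value
      est <- setNames(lower + nm$par * rng, names(lower))
    }
    list(est = est, value = best_val, sa = sa, rs = rs, rs_polish = rs2)
  }
  runs <- lapply(seed + 1000L * (seq_len(chains) - 1L), run_chain)
  win <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  structure(list(coefficients = win$est, value = win$value,
                 sa = win$sa, rs = win$rs, rs_polish = win$rs_polish,
                 chain_values = vapply(runs, `[[`, numeric(1), "value"),
                 bounds = bounds, seed = seed),
            class = "myofit")
}

#' @method coef myofit
#' @export
coef.myofit <- function(object, ...) object$coefficients

#' @method print myofit
#' @export
print.myofit <- function(x, ...) {
  cat("hybrid SA + response-surface fit\n")
  cat(sprintf("  final objective Phi = %.6g (%d + %d evaluations)\n",
              x$value, x$sa$n_eval, x$rs$n_eval))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @method summary myofit
#' @export
summary.myofit <- function(object, ...) {
  b <- object$bounds
  rel <- (object$coefficients - b$lower) / (b$upper - b$lower)
  out <- data.frame(name = b$name, estimate = object$coefficients,
                    lower = b$lower, upper = b$upper,
                    position_in_range = rel)
  rownames(out) <- NULL
  cat(sprintf("final Phi = %.6g; SA best %.6g -> RS best %.6g\n",
              object$value, object$sa$value, object$rs$value))
  out
}

# single-element forward model used by the recovery study: an
# isometric twitch carrying a brief 10% release-restretch around its
# peak; returns the sampled tension trace (kPa).  The release empties
# the bound pool, which momentarily decouples the deactivation rate
# from the cooperative recruitment and makes the two separately
# identifiable (at fixed length they act only through one effective
# combination).
twitch_forward <- function(par_named, base = optimized_cases(1),
                           ca = make_calcium(), sl = 2300, dt = 2e-4,
                           release_at = 0.04, release_dur = 0.02,
                           release_frac = 0.1) {
  args <- base[intersect(names(base), names(formals(active_params)))]
  for (nm in names(par_named)) args[[nm]] <- unname(par_named[nm])
  p <- do.call(active_params, args)
  n <- round(ca$period / dt)
  tt <- dt * seq_len(n)
  hsl0 <- sl / 2
  hsl <- rep(hsl0, n)
  if (!is.null(release_at)) {
    span <- (max(p$bins) - min(p$bins)) / p$shift_fraction
    n_ramp <- max(2L, ceiling(release_frac * hsl0 / (0.9 * span)))
    i0 <- round(release_at / dt)
    i1 <- round((release_at + release_dur) / dt)
    lowv <- (1 - release_frac) * hsl0
    hsl[i0:(i0 + n_ramp - 1L)] <- seq(hsl0, lowv, length.out = n_ramp)
    hsl[(i0 + n_ramp):(i1 - n_ramp)] <- lowv
    hsl[(i1 - n_ramp + 1L):i1] <- seq(lowv, hsl0, length.out = n_ramp)
  }
  sim <- simulate_half_sarcomere(p, ca_at(ca)(tt), hsl, dt)
  sim$trace$T / 1e3
}

#' Parameter-recovery study for the hybrid optimizer
#'
#' Generates synthetic targets from known ("true") contractile
#' parameters with the single-element twitch forward model, optionally
#' adds Gaussian noise, runs the hybrid estimation on a subset of free
#' parameters, and reports per-parameter recovery errors (as fractions
#' of the search range), the final objective, and a local sensitivity
#' ranking of the free parameters.
#'
#' @param true an [active_params()] object supplying the true values.
#' @param free names of parameters to recover.
#' @param noise sd of Gaussian noise added to the target tensions (kPa).
#' @param seed RNG seed (noise and both optimizer stages).
#' @param ca calcium transient driving the twitch.  The default is a
#'   brief sub-saturating transient chosen so the twitch stays below
#'   the cooperative latch threshold: a smooth, information-rich trace
#'   in every free parameter.
#' @param chains independent optimizer chains (see [fit_contraction()]).
#' @param sa_control,rs_control optimizer control lists.
#' @return An object of class `"recovery_report"`.
#' @export
recover_parameters <- function(true = optimized_cases(1),
                               free = c("a_on", "a_off", "k_plus", "k_minus"),
                               noise = 0, seed = 1,
                               ca = make_calcium(period = 0.17, peak = 800,
                                                 baseline = 100,
                                                 tau_rise = 0.004,
                                                 tau_decay = 0.012),
                               chains = 2,
                               sa_control = list(n_temps = 15, moves = 20,
                                                 region_half = 0.25),
                               rs_control = list(n_iter = 25, tol = 1e-10)) {
  dt <- 2e-4
  # two release timings sample the activation at different levels,
  # which separates the deactivation rate from the cooperative
  # recruitment (a single fixed-length twitch constrains only their
  # effective combination)
  forward <- function(par) {
    c(twitch_forward(par, base = true, ca = ca, dt = dt,
                     release_at = 0.015, release_dur = 0.012),
      twitch_forward(par, base = true, ca = ca, dt = dt,
                     release_at = 0.035, release_dur = 0.012))
  }
  target_T <- forward(setNames(numeric(0), character(0)))
  set.seed(seed)
  if (noise > 0) target_T <- target_T + rnorm(length(target_T), sd = noise)
  T_ref <- max(abs(target_T), 1)
  objective <- function(par) {
    pred <- forward(par)
    sum(((pred - target_T) / T_ref)^2)
  }
  fit <- fit_contraction(objective, free = free, seed = seed,
                         chains = chains,
                         sa_control = sa_control, rs_control = rs_control)
  b <- fit$bounds
  true_v <- setNames(vapply(b$name, function(nm) true[[nm]], numeric(1)),
                     b$name)
  rel_err <- abs(coef(fit) - true_v) / (b$upper - b$lower)
  # one-at-a-time sensitivity of Phi around the true parameters
  sens <- vapply(b$name, function(nm) {
    h <- 0.05 * (b$upper[b$name == nm] - b$lower[b$name == nm])
    pv <- setNames(true_v[nm] + h, nm)
    objective(pv)
  }, numeric(1))
  structure(list(fit = fit, true = true_v, estimate = coef(fit),
                 rel_error = rel_err, phi = fit$value,
                 sensitivity = sort(sens, decreasing = TRUE),
                 noise = noise, seed = seed),
            class = "recovery_report")
}

#' @method print recovery_report
#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery (noise sd %.3g, seed %d): Phi = %.3g\n",
              x$noise, x$seed, x$phi))
  df <- data.frame(true = x$true, estimate = x$estimate,
                   rel_error_of_range = x$rel_error)
  print(signif(df, 4))
  cat("sensitivity ranking (Phi at +5% range):\n")
  print(signif(x$sensitivity, 4))
  invisible(x)
}

#' Synthetic strain/pressure targets from a forward LV run
#'
#' Runs the full ventricle model with the given parameters, extracts
#' end-systolic Green strains (relative to end diastole) at the Gauss
#' points of every mid-layer element, and the six target pressures
#' (end-IVC, three during ejection including the peak, end-systole,
#' end-IVR), optionally perturbed by Gaussian noise.
#'
#' @param ap,pp active and passive parameters.
#' @param mesh,drive,calcium the study fixtures ([build_lv_mesh()],
#'   [make_flowrate()], [make_calcium()]).
#' @param seed RNG seed for the noise.
#' @param noise list with `strain` (absolute sd) and `pressure`
#'   (relative sd) noise levels.
#' @param ... further arguments to [solve_cycle()].
#' @return List with the [objective_targets()] object and the
#'   underlying cycle simulation.
#' @export
make_synthetic_targets <- function(ap, pp, mesh, drive, calcium,
                                   seed = 1,
                                   noise = list(strain = 0, pressure = 0),
                                   ...) {
  cyc <- solve_cycle(mesh, drive, calcium, pp, ap, ...)
  ed <- phase_frame(cyc, "filling")
  es <- phase_frame(cyc, "ejection")
  strains <- gauss_strain_tracking(mesh, ed$u, es$u,
                                   subset = mesh$layer == "mid")
  s <- cyc$summary
  per <- drive$period
  last <- s$t > (cyc$n_cycles - 1) * per
  pick <- function(ph, frac = 1) {
    idx <- which(last & s$phase == ph)
    idx[max(1L, ceiling(frac * length(idx)))]
  }
  ej <- which(last & s$phase == "ejection")
  p6 <- c(pick("ivc"),                       # end of IVC
          ej[ceiling(0.25 * length(ej))],    # early ejection
          ej[which.max(s$P[ej])],            # peak pressure
          ej[ceiling(0.75 * length(ej))],    # late ejection
          pick("ejection"),                  # end systole
          pick("ivr"))                       # end of IVR
  pressures <- s$P[p6]
  set.seed(seed)
  if (noise$strain > 0) {
    comps <- c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl")
    strains[, comps] <- strains[, comps] +
      matrix(rnorm(nrow(strains) * 6, sd = noise$strain), ncol = 6)
  }
  if (noise$pressure > 0)
    pressures <- pressures * (1 + rnorm(6, sd = noise$pressure))
  list(targets = objective_targets(strains, pressures),
       times = s$t[p6], cycle = cyc)
}

# Green strains at all Gauss points of selected elements, relative to a
# reference displacement field, in local wall coordinates
gauss_strain_tracking <- function(mesh, u_ref, u_target, subset = NULL) {
  ne <- nrow(mesh$elem)
  sel <- if (is.null(subset)) seq_len(ne) else which(subset)
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g),
                              zeta = c(-g, g)))
  rows <- vector("list", length(sel) * nrow(gp))
  cnt <- 0L
  for (e in sel) {
    idx <- mesh$elem[e, ]
    X <- mesh$nodes[idx, , drop = FALSE]
    Q <- mesh$wall_axes[[e]]
    for (q in seq_len(nrow(gp))) {
      dN <- hex_shape_grad_ref(gp[q, 1], gp[q, 2], gp[q, 3])
      J0 <- t(X) %*% dN
      dNdX <- dN %*% solve(J0)
      F_ref <- diag(3) + t(u_ref[idx, , drop = FALSE]) %*% dNdX
      F_tgt <- diag(3) + t(u_target[idx, , drop = FALSE]) %*% dNdX
      F_rel <- F_tgt %*% solve(F_ref)
      E <- (t(F_rel) %*% F_rel - diag(3)) / 2
      El <- t(Q) %*% E %*% Q
      cnt <- cnt + 1L
      rows[[cnt]] <- data.frame(
        element = e, gauss = q,
        E_cc = El[1, 1], E_rr = El[3, 3], E_ll = El[2, 2],
        E_cr = (El[1, 3] + El[3, 1]) / 2,
        E_cl = (El[1, 2] + El[2, 1]) / 2,
        E_rl = (El[2, 3] + El[3, 2]) / 2)
    }
  }
  do.call(rbind, rows[seq_len(cnt)])
}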