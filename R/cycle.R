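# Quasi-static finite-element solution of the LV cardiac cycle.
# The prescribed-volume constraint is enforced with the cavity pressure
# as a Lagrange multiplier; the per-element half-sarcomere engines are
# co-stepped with the mechanics (staggered by one time step).

fe_setup <- function(mesh) {
  ne <- nrow(mesh$elem)
  nn <- nrow(mesh$nodes)
  Xs <- numeric(24 * ne)
  Rfs <- numeric(9 * ne)
  dof <- matrix(0L, 24, ne)
  for (e in seq_len(ne)) {
    idx <- mesh$elem[e, ]
    Xs[(24 * (e - 1) + 1):(24 * e)] <- as.vector(mesh$nodes[idx, ])
    Rfs[(9 * (e - 1) + 1):(9 * e)] <- as.vector(mesh$fiber[[e]])
    dof[, e] <- as.integer(outer(idx, c(0L, nn, 2L * nn), `+`))
  }
  # triplet pattern for the global tangent
  Ki <- matrix(0L, 576, ne)
  Kj <- matrix(0L, 576, ne)
  for (e in seq_len(ne)) {
    Ki[, e] <- rep(dof[, e], times = 24)
    Kj[, e] <- rep(dof[, e], each = 24)
  }
  # reduction operator: basal nodes keep only the in-plane radial dof
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  col <- 0L
  for (nd in seq_len(nn)) {
    if (nd %in% mesh$basal_nodes) {
      r <- mesh$nodes[nd, 1:2]
      r <- r / sqrt(sum(r^2))
      col <- col + 1L
      trip_i <- c(trip_i, nd, nd + nn)
      trip_j <- c(trip_j, col, col)
      trip_x <- c(trip_x, r[1], r[2])
    } else {
      trip_i <- c(trip_i, nd, nd + nn, nd + 2L * nn)
      trip_j <- c(trip_j, col + 1L, col + 2L, col + 3L)
      trip_x <- c(trip_x, 1, 1, 1)
      col <- col + 3L
    }
  }
  P <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(3L * nn, col))
  list(ne = ne, nn = nn, Xs = Xs, Rfs = Rfs, dof = dof,
       Ki = as.integer(Ki), Kj = as.integer(Kj), P = P)
}

# sparse Hessian of the cavity volume (mm^3) wrt nodal coordinates.
# V = sum_tri x_a.(x_b x x_c)/6 is trilinear, so the Hessian blocks are
# skew matrices of the opposite vertex; the basal-cap centroid is a
# mean of the rim nodes and is folded in by the chain rule at the
# triplet level.
cavity_hessian <- function(mesh, u = NULL) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  nn <- nrow(x)
  tr <- cavity_triangulation(mesh)
  cen <- tr$centroid_id
  nr <- length(tr$rim)
  verts <- rbind(x, colMeans(x[tr$rim, , drop = FALSE]))
  all_tris <- rbind(tr$tris, tr$cap)
  sgn <- sign(closed_surface_volume(verts, all_tris))

  acc <- vector("list", 6L * nrow(all_tris))
  nacc <- 0L
  # one skew block: d(g_arow)/d(x_bcol) += skew(v)/6
  push <- function(a, b, v) {
    ia <- if (a == cen) tr$rim else a
    jb <- if (b == cen) tr$rim else b
    w <- 1 / (length(ia) * length(jb))
    grid <- expand.grid(ia = ia, jb = jb)
    dim_i <- c(1L, 1L, 2L, 2L, 3L, 3L)
    dim_j <- c(2L, 3L, 1L, 3L, 1L, 2L)
    vals <- c(-v[3], v[2], v[3], -v[1], -v[2], v[1]) / 6
    nacc <<- nacc + 1L
    acc[[nacc]] <<- list(
      i = rep(grid$ia, each = 6L) + (dim_i - 1L) * nn,
      j = rep(grid$jb, each = 6L) + (dim_j - 1L) * nn,
      x = rep(vals, nrow(grid)) * w)
  }
  for (t_ in seq_len(nrow(all_tris))) {
    a <- all_tris[t_, 1]; b <- all_tris[t_, 2]; c_ <- all_tris[t_, 3]
    xa <- verts[a, ]; xb <- verts[b, ]; xc <- verts[c_, ]
    push(a, c_, xb); push(b, a, xc); push(c_, b, xa)
    push(a, b, -xc); push(b, c_, -xa); push(c_, a, -xb)
  }
  acc <- acc[seq_len(nacc)]
  Matrix::sparseMatrix(
    i = unlist(lapply(acc, `[[`, "i")),
    j = unlist(lapply(acc, `[[`, "j")),
    x = sgn * unlist(lapply(acc, `[[`, "x")),
    dims = c(3L * nn, 3L * nn))
}

assemble_global <- function(fe, u_vec, mats, tangent = TRUE) {
  out <- assemble_elements_cpp(fe$Xs, u_vec[as.vector(fe$dof)], fe$Rfs,
                               mats, fe$ne, tangent)
  # accumulate with rowsum: collapsed apex elements carry repeated
  # node indices, which plain indexed assignment would drop
  f <- numeric(3 * fe$nn)
  acc <- rowsum(as.vector(out$f), group = as.vector(fe$dof))
  f[as.integer(rownames(acc))] <- acc
  K <- NULL
  if (tangent)
    K <- Matrix::sparseMatrix(i = fe$Ki, j = fe$Kj, x = out$K,
                              dims = c(3 * fe$nn, 3 * fe$nn))
  list(f = f, K = K)
}

solve_volume_step <- function(mesh, fe, u, p_mult, mats, V_target_mm3,
                              vol_tol = 1e-4, tol_f = 1e-6, max_iter = 30) {
  nn <- fe$nn
  for (it in seq_len(max_iter)) {
    umat <- matrix(u, nn, 3)
    V <- 1000 * cavity_volume(mesh, umat)
    g <- 1000 * as.vector(cavity_volume_grad(mesh, umat))
    asm <- assemble_global(fe, u, mats, tangent = TRUE)
    r <- asm$f - p_mult * g
    c_res <- V - V_target_mm3
    rr <- as.vector(Matrix::crossprod(fe$P, r))
    f_scale <- max(1, max(abs(asm$f)), p_mult * max(abs(g)))
    if (max(abs(rr)) < tol_f * f_scale &&
        abs(c_res) < vol_tol * V_target_mm3)
      return(list(u = u, p = p_mult, converged = TRUE, iters = it - 1L,
                  V_mm3 = V))
    H <- cavity_hessian(mesh, umat)
    Kr <- Matrix::crossprod(fe$P, (asm$K - p_mult * H) %*% fe$P)
    gr <- as.vector(Matrix::crossprod(fe$P, g))
    nf <- ncol(fe$P)
    # residuals: r(u, p) = f_int - p g,  c(u) = V - V_target
    M <- rbind(cbind(Kr, -gr), c(gr, 0))
    rhs <- -c(rr, c_res)
    sol <- tryCatch(Matrix::solve(M, rhs), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)))
      return(list(u = u, p = p_mult, converged = FALSE, iters = it))
    du <- as.vector(fe$P %*% sol[seq_len(nf)])
    dp <- sol[nf + 1L]
    # damp very large increments (mm scale), then backtrack on element
    # inversion
    step_max <- max(abs(du))
    if (step_max > 0.5) { du <- du * 0.5 / step_max; dp <- dp * 0.5 / step_max }
    alpha <- 1
    for (ls in 1:8) {
      ok <- tryCatch({
        assemble_global(fe, u + alpha * du, mats, tangent = FALSE)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      alpha <- alpha / 2
    }
    if (!ok) return(list(u = u, p = p_mult, converged = FALSE, iters = it))
    u <- u + alpha * du
    p_mult <- p_mult + alpha * dp
  }
  list(u = u, p = p_mult, converged = FALSE, iters = max_iter)
}

#' Simulate full cardiac cycles of the left-ventricle model
#'
#' Drives the LV through `n_cycles` of the prescribed volumetric
#' flowrate, starting from the unloaded state.  At every time step the
#' target cavity volume advances by the integrated flowrate; a Newton
#' solve finds the quasi-static displacement field and the cavity
#' pressure (the Lagrange multiplier enforcing the volume).  Each
#' element's half-sarcomere engine is advanced with the element fiber
#' stretch (`hsl = hsl0 * lambda_fiber`, distribution shifting
#' included) and the resulting active stress (plus 25% cross-fiber
#' components) enters the element stress.
#'
#' @param mesh a [build_lv_mesh()] object.
#' @param drive a [make_flowrate()] object.
#' @param ca a [make_calcium()] object (onset is interpreted relative
#'   to the cycle; align it with the start of isovolumic contraction).
#' @param pp a [passive_params()] object.
#' @param ap an [active_params()] object.
#' @param n_cycles number of cycles.
#' @param dt time step (s).
#' @param cross_frac active cross-fiber stress fraction.
#' @param vol_tol relative cavity-volume constraint tolerance.
#' @param verbose print per-step convergence information.
#' @return An object of class `"lv_cycle"`: `summary` data frame
#'   (`t`, `V` mL, `P` kPa, `phase`), per-element trajectories `hsl`,
#'   `N_on`, `N_bound`, `T_kPa` (matrices ne x nt), displacement array
#'   `u` (nn x 3 x nt), and the inputs.
#' @export
solve_cycle <- function(mesh, drive, ca, pp, ap, n_cycles = 2,
                        dt = 1e-3, cross_frac = 0.25, vol_tol = 1e-4,
                        verbose = FALSE) {
  fe <- fe_setup(mesh)
  ne <- fe$ne; nn <- fe$nn
  ca_fun <- ca_at(ca)
  nt <- round(n_cycles * drive$period / dt)
  tt <- dt * seq_len(nt)

  # target volumes by per-step Simpson quadrature of the flowrate
  V0 <- 1000 * cavity_volume(mesh)
  dV <- vapply(seq_len(nt), function(k) {
    a <- tt[k] - dt
    1000 * dt * (drive$q(a) + 4 * drive$q(a + dt / 2) + drive$q(tt[k])) / 6
  }, numeric(1))
  V_target <- V0 + cumsum(dV)

  # per-element kinetics state
  hsl <- mesh$sl0 / 2
  N <- numeric(ne)
  A <- matrix(0, ne, 21)
  pk <- pack_active(ap)

  u <- numeric(3 * nn)
  p_mult <- 0
  base_mats <- rep(c(pp$C, pp$b_f, pp$b_t, pp$b_fs, pp$kappa, 0, cross_frac),
                   ne)

  sum_df <- data.frame(t = tt, V = NA_real_, V_target = V_target / 1000,
                       P = NA_real_, phase = cycle_phase(drive, tt),
                       newton_iters = NA_integer_)
  hsl_tr <- matrix(NA_real_, ne, nt)
  N_tr <- matrix(NA_real_, ne, nt)
  Nb_tr <- matrix(NA_real_, ne, nt)
  T_tr <- matrix(NA_real_, ne, nt)
  u_tr <- array(NA_real_, c(nn, 3, nt))

  for (k in seq_len(nt)) {
    # fiber stretch from the last converged configuration
    Fg <- centre_def_grad_cpp(fe$Xs, u[as.vector(fe$dof)], ne)
    lam_f <- vapply(seq_len(ne), function(e) {
      Fm <- matrix(Fg[(9 * (e - 1) + 1):(9 * e)], 3, 3)
      sqrt(sum((Fm %*% mesh$fiber[[e]][, 1])^2))
    }, numeric(1))
    hsl_new <- (mesh$sl0 / 2) * lam_f
    # the kinetic co-step count doubles if the RK4 error control cannot
    # reach tolerance within its sub-step cap (rapid shifts stiffen the
    # wing bins)
    n_kin <- 4L
    repeat {
      st <- tryCatch(
        xb_step_batch_cpp(pk, ap$bins, ca_fun(tt[k]), hsl_new, dt,
                          N, A, hsl, n_kin = n_kin),
        error = function(e) NULL)
      if (!is.null(st) || n_kin >= 256L) break
      n_kin <- n_kin * 2L
    }
    if (is.null(st))
      stop("kinetics integration failed at t = ", signif(tt[k], 4), " s")
    N <- st$N; A <- st$A; hsl <- hsl_new
    T_act_kPa <- st$T / 1e3

    mats <- base_mats
    mats[seq(6, by = 7, length.out = ne)] <- T_act_kPa
    sol <- solve_volume_step(mesh, fe, u, p_mult, mats, V_target[k],
                             vol_tol = vol_tol)
    if (!sol$converged) {
      # substep the load: both the volume increment and the active
      # tension ramp are applied in fractions
      V_prev <- if (k == 1) V0 else V_target[k - 1]
      T_prev <- if (k == 1) numeric(ne) else T_tr[, k - 1]
      nsub <- 2L
      repeat {
        ok <- TRUE
        us <- u; ps <- p_mult
        for (s in seq_len(nsub)) {
          frac <- s / nsub
          Vt <- V_prev + (V_target[k] - V_prev) * frac
          msub <- base_mats
          msub[seq(6, by = 7, length.out = ne)] <-
            T_prev + (T_act_kPa - T_prev) * frac
          sub <- solve_volume_step(mesh, fe, us, ps, msub, Vt,
                                   vol_tol = vol_tol)
          if (!sub$converged) { ok <- FALSE; break }
          us <- sub$u; ps <- sub$p
        }
        if (ok) { sol <- sub; break }
        nsub <- nsub * 2L
        if (nsub > 64L)
          stop("Newton failed to converge at t = ", signif(tt[k], 4),
               " s even with load substepping")
      }
    }
    u <- sol$u; p_mult <- sol$p
    sum_df$V[k] <- sol$V_mm3 / 1000
    sum_df$P[k] <- p_mult
    sum_df$newton_iters[k] <- sol$iters
    hsl_tr[, k] <- hsl
    N_tr[, k] <- N
    Nb_tr[, k] <- st$Nb
    T_tr[, k] <- T_act_kPa
    u_tr[, , k] <- matrix(u, nn, 3)
    if (verbose)
      cat(sprintf("t=%.3f  V=%.3f mL  P=%.3f kPa  (%d it, %s)\n",
                  tt[k], sum_df$V[k], p_mult, sol$iters, sum_df$phase[k]))
  }
  structure(list(summary = sum_df, hsl = hsl_tr, N_on = N_tr,
                 N_bound = Nb_tr, T_kPa = T_tr, u = u_tr,
                 mesh = mesh, drive = drive, calcium = ca,
                 passive = pp, active = ap, dt = dt,
                 n_cycles = n_cycles),
            class = "lv_cycle")
}

#' @method print lv_cycle
#' @export
print.lv_cycle <- function(x, ...) {
  s <- x$summary
  cat(sprintf("LV cycle simulation: %d cycles, %d steps of %.1f ms\n",
              x$n_cycles, nrow(s), 1e3 * x$dt))
  cat(sprintf("  volume %.3f-%.3f mL, pressure %.2f-%.2f kPa\n",
              min(s$V), max(s$V), min(s$P), max(s$P)))
  cat(sprintf("  peak element tension %.1f kPa\n", max(x$T_kPa)))
  invisible(x)
}

#' @method plot lv_cycle
#' @export
plot.lv_cycle <- function(x, which = c("pv", "traces"), ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "pv") {
    graphics::plot(s$V, s$P * 7.50062, type = "l", xlab = "volume (mL)",
                   ylab = "pressure (mmHg)", main = "PV loop", ...)
  } else {
    graphics::par(mfrow = c(2, 1))
    graphics::plot(s$t, s$V, type = "l", xlab = "t (s)", ylab = "V (mL)")
    graphics::plot(s$t, s$P, type = "l", xlab = "t (s)", ylab = "P (kPa)")
  }
  invisible(x)
}

#' Displacement snapshot at the end of a named phase
#'
#' @param cyc an [solve_cycle()] result.
#' @param phase phase whose final frame is wanted (e.g. `"filling"` for
#'   end diastole, `"ejection"` for end systole).
#' @param cycle which cycle (default the last).
#' @return List with `u` (nn x 3) and the frame `index`.
#' @export
phase_frame <- function(cyc, phase = "filling", cycle = cyc$n_cycles) {
  s <- cyc$summary
  per <- cyc$drive$period
  in_cycle <- s$t > (cycle - 1) * per & s$t <= cycle * per + 1e-12
  idx <- which(in_cycle & s$phase == phase)
  if (!length(idx)) stop("no frames in phase '", phase, "' of cycle ", cycle)
  i <- max(idx)
  list(u = cyc$u[, , i], index = i, t = s$t[i])
}

#' Onset of sarcomere re-lengthening per element
#'
#' Finds, for each element, the time at which the sarcomere reaches its
#' minimum length and begins to re-lengthen.  The search window runs
#' from the start of ejection to the end of the cycle, so that
#' post-systolic shortening extends the onset but the short
#' sarcomere lengths at the start of filling do not masquerade as one.
#'
#' @param cyc an [solve_cycle()] result.
#' @param cycle which cycle to analyse (default the last).
#' @return Numeric vector (s), one onset time per element.
#' @export
relengthening_onset <- function(cyc, cycle = cyc$n_cycles) {
  s <- cyc$summary
  per <- cyc$drive$period
  ej <- cyc$drive$phases$start[cyc$drive$phases$phase == "ejection"]
  idx <- which(s$t >= (cycle - 1) * per + ej & s$t <= cycle * per + 1e-12)
  vapply(seq_len(nrow(cyc$hsl)), function(e) {
    tr <- cyc$hsl[e, idx]
    s$t[idx[which.min(tr)]]
  }, numeric(1))
}
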