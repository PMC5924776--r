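test_that("attachment rate follows the Boltzmann-weighted form", {
  expect_equal(attachment_rate(0, case1), 1544)
  # direct evaluation: exponent -k_cb (5 nm)^2 / (2 kT)
  ex5 <- exp(-case1$k_cb * (5e-9)^2 / (2 * case1$kT))
  expect_equal(attachment_rate(5, case1), 1544 * ex5)
  expect_equal(attachment_rate(5, case1), 83.2, tolerance = 1e-2)
  expect_equal(attachment_rate(-5, case1), 264 * ex5)
  expect_equal(attachment_rate(-5, case1), 14.2, tolerance = 1e-2)
  expect_error(attachment_rate(0, modifyList(case1, list(kT = -1))),
               "kT")
})

test_that("detachment rate is baseline plus quartic strain term", {
  expect_equal(detachment_rate(0, case1), 293)
  expect_equal(detachment_rate(2, case1), 293 + 26 * 16)
  expect_equal(detachment_rate(-1, case1), 195 + 47)
})

test_that("overlap fraction is a single-peaked trapezoid of length", {
  expect_equal(overlap_fraction(1150, case1), 1)
  expect_equal(overlap_fraction(600, case1), 0)
  # active stress is zero at the short-length floor (SL 1200 nm)
  s <- hs_state(hsl = 600, N_on = 0.5, A = rep(0.02, 21))
  expect_equal(active_stress(s, case1), 0)
  # monotone non-decreasing from the floor up to the plateau
  hh <- seq(600, 1150, by = 10)
  expect_true(all(diff(overlap_fraction(hh, case1)) >= 0))
})

test_that("activation ODE decays exponentially without calcium or cooperativity", {
  p <- active_params(a_on = 0.02, a_off = 40, k_plus = 0, k_minus = 0)
  s <- hs_state(hsl = 1150, N_on = 0.5)
  dt <- 1e-5
  for (i in seq_len(round(1 / p$a_off / dt))) s <- evolve_activation(s, 0, dt, p)
  expect_equal(s$N_on, 0.5 / exp(1), tolerance = 1e-3)
})

test_that("activation ODE stays at zero with no sources", {
  p <- active_params(k_minus = 0)
  s <- hs_state(hsl = 1150, N_on = 0)
  for (i in 1:100) s <- evolve_activation(s, 0, 1e-4, p)
  expect_equal(s$N_on, 0)
})

test_that("activation reaches the algebraic steady state at saturating calcium", {
  # no cooperativity, no binding: N* = a_on ca Nov / (a_on ca + a_off)
  p <- active_params(a_on = 0.02, a_off = 200, k_plus = 0, k_minus = 0,
                     Ck_pos = 0, Ck_neg = 0)
  ca <- pca_to_nM(4.5)
  s <- hs_state(hsl = 1150)
  for (i in 1:5000) s <- evolve_activation(s, ca, 1e-5, p)
  expect_equal(s$N_on, p$a_on * ca / (p$a_on * ca + p$a_off),
               tolerance = 1e-6)
})

test_that("bound distribution stays empty with no detached heads", {
  p <- mild_params()
  s <- hs_state(hsl = 1150, N_on = 0, A = numeric(21))
  s2 <- evolve_bound(s, 1e-3, p)
  expect_equal(s2$A, numeric(21))
})

test_that("frozen-activation long-time limit matches the per-bin balance", {
  p <- case1
  s <- hs_state(hsl = 1150, N_on = 0.6)
  for (i in 1:4000) s <- evolve_bound(s, 1e-4, p)   # N held at 0.6
  k1 <- attachment_rate(p$bins, p)
  km1 <- detachment_rate(p$bins, p)
  D_final <- s$N_on - sum(s$A)
  A_star <- k1 * 1 * D_final / km1
  expect_equal(s$A, A_star, tolerance = 1e-6)
})

test_that("RK4 path matches a dense fixed-step Euler reference", {
  p <- mild_params()
  ca <- pca_to_nM(5.5)
  ref <- euler_reference(p, ca, 1150, t_end = 0.05, h = 2e-7,
                         save_every = 2500)   # every 0.5 ms
  sim <- simulate_half_sarcomere(p, rep(ca, 5000), rep(1150, 5000), 1e-5)
  keep <- seq(50, 5000, by = 50)
  T_sim <- sim$trace$T[keep]
  expect_lt(max(abs(T_sim - ref$T)) / max(abs(ref$T)), 1e-3)
  expect_lt(max(abs(sim$trace$N_on[keep] - ref$N)) / max(ref$N), 1e-3)
})

test_that("R and compiled kinetics paths agree", {
  p <- case1
  ca <- pca_to_nM(5.0)
  dt <- 1e-4
  s <- hs_state(hsl = 1150)
  hsl_sched <- 1150 + cumsum(c(rep(0.5, 25), rep(-0.5, 25)))
  for (k in 1:50)
    s <- step_half_sarcomere(s, ca, hsl_sched[k] - s$hsl, dt, p)
  cc <- simulate_half_sarcomere(p, rep(ca, 50), hsl_sched, dt)
  expect_equal(cc$state$A, s$A, tolerance = 1e-10)
  expect_equal(cc$state$N_on, s$N_on, tolerance = 1e-10)
})

test_that("distribution shifting resamples and drops off-grid mass", {
  p <- case1
  A <- numeric(21); A[11] <- 0.4         # all mass at x = 0
  s <- hs_state(hsl = 1150, N_on = 0.5, A = A)
  expect_equal(shift_distribution(s, 0, p)$A, A)
  # one full bin (delta_hsl = 2 nm -> shift 1 nm): pure relabeling
  s2 <- shift_distribution(s, 2, p)
  expect_equal(s2$A[12], 0.4)
  expect_equal(sum(s2$A), 0.4)
  # half-bin shift: mean of the straddling bins
  s3 <- shift_distribution(s, 1, p)
  expect_equal(s3$A[11], 0.2)
  expect_equal(s3$A[12], 0.2)
  # mass never increases, and off-grid mass is lost
  A_edge <- numeric(21); A_edge[21] <- 0.3
  s4 <- shift_distribution(hs_state(hsl = 1150, N_on = 0.5, A = A_edge), 4, p)
  expect_lt(sum(s4$A), 0.3)
  expect_error(shift_distribution(s, 50, p), "span")
})

test_that("active stress converts the bound distribution as expected", {
  p <- case1
  expect_equal(active_stress(hs_state(1150, 0, numeric(21)), p), 0)
  A <- numeric(21); A[11] <- 0.4
  expect_equal(active_stress(hs_state(1150, 0.5, A), p),
               6.9e16 * 0.001 * 0.4 * 5e-9)
  A2 <- numeric(21); A2[6] <- 0.2; A2[16] <- 0.2   # x = -5 and +5
  expect_equal(active_stress(hs_state(1150, 0.5, A2), p), 1.38e5)
})

test_that("head conservation and clamps hold along a random walk", {
  p <- case1
  set.seed(42)
  n <- 1e5
  d_hsl <- sample(c(-1, 0, 1), n, replace = TRUE) * runif(n, 0, 1.5)
  hsl <- 1150 + cumsum(d_hsl)
  hsl <- pmin(pmax(hsl, 700), 1174)
  # forced smooth excursion below the stress floor (SL <= 1200 nm)
  dip <- 40000:44000
  hsl[dip] <- approx(c(40000, 41500, 42500, 44000),
                     c(hsl[40000], 570, 570, hsl[44000]), xout = dip)$y
  log_ca <- log(500) + cumsum(rnorm(n, sd = 0.01))
  ca <- pmin(pmax(exp(log_ca), 10), 5e4)
  out <- xb_simulate_cpp(myolv:::pack_active(p), p$bins, ca, hsl, 5e-5,
                         0, numeric(21), 1150)
  expect_true(all(is.finite(out$N)))
  expect_true(all(out$Nb >= 0))
  expect_true(all(out$N - out$Nb >= -1e-12))      # D >= 0
  expect_true(all(out$N <= 1 + 1e-12))
  # zero active stress whenever SL is at or below 1200 nm
  short <- 2 * hsl <= 1200
  expect_true(any(short))
  expect_true(all(out$T[short] == 0))
  # stress never exceeds the all-bound bound
  T_bound <- p$rho * p$k_cb * 1 * (max(p$bins) + p$x_ps) * 1e-9
  expect_true(all(out$T <= T_bound + 1e-9))
})

test_that("zero calcium from the rested state produces no tension", {
  p <- active_params(k_minus = 0)
  sim <- simulate_half_sarcomere(p, rep(0, 2000), rep(1150, 2000), 1e-4)
  expect_true(all(sim$trace$T == 0))
  expect_true(all(sim$trace$N_on == 0))
})
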