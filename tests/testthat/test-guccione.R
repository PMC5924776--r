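pp <- passive_params()

test_that("strain energy matches hand-evaluated cases", {
  expect_equal(strain_energy(matrix(0, 3, 3), pp), 0)
  E <- diag(c(0.1, 0, 0))
  expect_equal(strain_energy(E, pp),
               0.262 / 2 * (exp(18.48 * 0.01) - 1))
  expect_equal(strain_energy(E, pp), 0.0266, tolerance = 2e-3)
  # transverse isotropy: swapping the two transverse axes changes nothing
  E1 <- matrix(c(0.02, 0.01, 0.03,
                 0.01, 0.08, 0.00,
                 0.03, 0.00, -0.04), 3, 3, byrow = TRUE)
  E2 <- E1[c(1, 3, 2), c(1, 3, 2)]
  expect_equal(strain_energy(E1, pp), strain_energy(E2, pp))
  expect_error(strain_energy(matrix(rnorm(9), 3, 3), pp), "symmetric")
})

test_that("analytic stress matches the hand-evaluated fiber case", {
  E <- diag(c(0.1, 0, 0))
  S <- passive_stress(E, pp)
  expect_equal(S[1, 1], 0.262 * 18.48 * 0.1 * exp(18.48 * 0.01))
  expect_equal(S[1, 1], 0.5825, tolerance = 2e-3)
  expect_equal(passive_stress(matrix(0, 3, 3), pp), matrix(0, 3, 3))
})

test_that("analytic stress equals the finite-difference energy gradient", {
  set.seed(7)
  h <- 1e-7
  for (rep in 1:100) {
    A <- matrix(rnorm(9, sd = 0.12), 3, 3)
    E <- (A + t(A)) / 2
    E <- E * min(1, 0.3 / max(abs(E)))
    S <- passive_stress(E, pp)
    for (pair in list(c(1, 1), c(2, 2), c(1, 2), c(2, 3))) {
      i <- pair[1]; j <- pair[2]
      Ep <- E; Em <- E
      Ep[i, j] <- Ep[i, j] + h; Ep[j, i] <- Ep[i, j]
      Em[i, j] <- Em[i, j] - h; Em[j, i] <- Em[i, j]
      fd <- (strain_energy(Ep, pp) - strain_energy(Em, pp)) / (2 * h)
      # symmetric perturbation moves E_ij and E_ji together
      an <- if (i == j) S[i, j] else S[i, j] + S[j, i]
      expect_equal(an, fd, tolerance = 1e-6)
    }
  }
})

test_that("energy is non-negative and convex along rays from zero", {
  set.seed(8)
  for (rep in 1:20) {
    A <- matrix(rnorm(9, sd = 0.1), 3, 3)
    E <- (A + t(A)) / 2
    tt <- seq(0, 1, length.out = 9)
    w <- vapply(tt, function(s) strain_energy(s * E, pp), numeric(1))
    expect_true(all(w >= 0))
    expect_true(all(diff(diff(w)) >= -1e-12))
  }
})

test_that("energy is frame-indifferent under consistent rotation", {
  set.seed(9)
  A <- matrix(rnorm(9, sd = 0.1), 3, 3)
  E <- (A + t(A)) / 2
  # a rotation applied to both the strain and the material frame leaves
  # the fiber-coordinate strain, hence the energy, unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Eg <- R %*% E %*% t(R)              # strain in rotated global axes
  E_back <- t(R) %*% Eg %*% R         # re-expressed on the rotated frame
  expect_equal(strain_energy(E_back, pp), strain_energy(E, pp),
               tolerance = 1e-10)
})

test_that("volumetric penalty stress vanishes at J = 1 and resists dilatation", {
  F1 <- diag(3)
  expect_equal(passive_stress(matrix(0, 3, 3), pp, F = F1),
               matrix(0, 3, 3))
  lam <- 1.02
  Fd <- diag(rep(lam, 3))
  E <- (t(Fd) %*% Fd - diag(3)) / 2
  S <- passive_stress(E, pp, F = Fd)
  expect_gt(S[1, 1], 0)
  expect_error(passive_stress(E, pp, F = diag(c(-1, 1, 1))), "inversion")
})

test_that("total stress adds fiber tension with 25% cross-fiber components", {
  ap <- case1
  s0 <- hs_state(1150, 0, numeric(21))
  E <- matrix(0, 3, 3)
  expect_equal(total_stress(E, s0, pp, ap), passive_stress(E, pp))
  A <- numeric(21); A[11] <- 0.4      # 138 kPa of fiber tension
  s1 <- hs_state(1150, 0.5, A)
  S <- total_stress(E, s1, pp, ap)
  T_kPa <- active_stress(s1, ap) / 1e3
  expect_equal(diag(S), c(T_kPa, 0.25 * T_kPa, 0.25 * T_kPa))
  expect_equal(S - diag(diag(S)), matrix(0, 3, 3))   # no active shear
})

test_that("fiber frames are right-handed orthonormal triads", {
  e_c <- c(0, 1, 0); e_l <- c(0, 0, 1); e_r <- c(1, 0, 0)
  Q <- fiber_frame(e_c, e_l, e_r, 60)
  expect_equal(crossprod(Q), diag(3), tolerance = 1e-12)
  expect_equal(det(Q), 1, tolerance = 1e-12)
  expect_equal(sum(Q[, 1] * e_c), cos(pi / 3), tolerance = 1e-12)
})
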