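# quick static/inflation checks of the FE machinery; full-cycle
# behaviour is exercised by the acceptance suite

test_that("with no load the solver stays in the reference configuration", {
  m <- build_lv_mesh()
  fe <- myolv:::fe_setup(m)
  pp <- passive_params()
  mats <- rep(c(pp$C, pp$b_f, pp$b_t, pp$b_fs, pp$kappa, 0, 0.25), fe$ne)
  V0 <- 1000 * cavity_volume(m)
  sol <- myolv:::solve_volume_step(m, fe, numeric(3 * fe$nn), 0, mats, V0)
  expect_true(sol$converged)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$p, 0)
})

test_that("passive inflation pressure scales linearly with C at small strain", {
  m <- build_lv_mesh()
  fe <- myolv:::fe_setup(m)
  V0 <- 1000 * cavity_volume(m)
  p_at <- function(C_scale) {
    pp <- passive_params(C = 0.262 * C_scale)
    mats <- rep(c(pp$C, pp$b_f, pp$b_t, pp$b_fs, pp$kappa, 0, 0.25), fe$ne)
    sol <- myolv:::solve_volume_step(m, fe, numeric(3 * fe$nn), 0, mats,
                                     V0 * 1.02)
    expect_true(sol$converged)
    sol$p
  }
  p1 <- p_at(1)
  p2 <- p_at(2)
  expect_gt(p1, 0)
  expect_equal(p2 / p1, 2, tolerance = 0.02)
})

test_that("inflation meets the volume constraint and basal conditions", {
  m <- build_lv_mesh()
  fe <- myolv:::fe_setup(m)
  pp <- passive_params()
  mats <- rep(c(pp$C, pp$b_f, pp$b_t, pp$b_fs, pp$kappa, 0, 0.25), fe$ne)
  V0 <- 1000 * cavity_volume(m)
  sol <- myolv:::solve_volume_step(m, fe, numeric(3 * fe$nn), 0, mats,
                                   V0 * 1.10)
  expect_true(sol$converged)
  expect_lt(abs(sol$V_mm3 - V0 * 1.10) / (V0 * 1.10), 1e-4)
  u <- matrix(sol$u, fe$nn, 3)
  # basal nodes move only radially in the basal plane
  b <- m$basal_nodes
  expect_lt(max(abs(u[b, 3])), 1e-12)
  for (nd in b) {
    r_hat <- m$nodes[nd, 1:2] / sqrt(sum(m$nodes[nd, 1:2]^2))
    tang <- c(-r_hat[2], r_hat[1])
    expect_lt(abs(sum(u[nd, 1:2] * tang)), 1e-12)
  }
})

test_that("active tension generates cavity pressure at fixed volume", {
  # inflate gradually (the soft unstretched wall buckles under jumps in
  # load), then ramp a uniform fiber tension at held volume
  m <- build_lv_mesh()
  fe <- myolv:::fe_setup(m)
  pp <- passive_params()
  V0 <- 1000 * cavity_volume(m)
  base <- rep(c(pp$C, pp$b_f, pp$b_t, pp$b_fs, pp$kappa, 0, 0.25), fe$ne)
  u <- numeric(3 * fe$nn); p <- 0
  for (f in seq(1.02, 1.6, by = 0.02)) {
    sol <- myolv:::solve_volume_step(m, fe, u, p, base, V0 * f)
    expect_true(sol$converged)
    u <- sol$u; p <- sol$p
  }
  p_passive <- p
  for (T_act in seq(0.25, 1, by = 0.25)) {   # kPa fiber tension
    mats <- base
    mats[seq(6, by = 7, length.out = fe$ne)] <- T_act
    sol <- myolv:::solve_volume_step(m, fe, u, p, mats, V0 * 1.6,
                                     max_iter = 50)
    expect_true(sol$converged)
    u <- sol$u; p <- sol$p
  }
  expect_gt(p, p_passive + 0.1)
})
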