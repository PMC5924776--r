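test_that("default mesh has the expected size, labels and quality", {
  m <- build_lv_mesh()
  expect_equal(nrow(m$elem), 144)
  expect_gt(myolv:::min_gauss_jacobian(m), 0)
  # initial sarcomere length and helix angle by layer
  expect_equal(unique(m$sl0[m$layer == "endo"]), 1780)
  expect_equal(unique(m$sl0[m$layer == "mid"]), 1850)
  expect_equal(unique(m$sl0[m$layer == "epi"]), 1910)
  for (e in c(which(m$layer == "endo")[1], which(m$layer == "epi")[1])) {
    f <- m$fiber[[e]][, 1]
    e_c <- m$wall_axes[[e]][, "circ"]
    ang <- acos(sum(f * e_c)) * 180 / pi
    expect_equal(ang, 60, tolerance = 1e-6)
  }
  e_mid <- which(m$layer == "mid")[1]
  expect_equal(sum(m$fiber[[e_mid]][, 1] * m$wall_axes[[e_mid]][, "circ"]),
               1, tolerance = 1e-10)
  # four segments with equal element counts
  expect_equal(as.integer(table(m$segment)), rep(36L, 4))
})

test_that("degenerate geometry is rejected", {
  expect_error(build_lv_mesh(r_endo = -1))
  expect_error(build_lv_mesh(n_trans = 4), "n_trans")
})

test_that("surface-integral volume is exact for a box", {
  v <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  tris <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  expect_equal(closed_surface_volume(v, tris), 1)
})

test_that("cavity volume approximates a hemisphere-like analytic value", {
  # fine-resolution half ellipsoid: (2/3) pi a^2 c within discretization
  m <- build_lv_mesh(n_circ = 24, n_long = 18)
  expect_equal(cavity_volume(m), 2 / 3 * pi * 3.2^2 * 6.4 / 1000,
               tolerance = 0.02)
})

test_that("cavity volume is invariant under rigid translation", {
  m <- build_lv_mesh()
  u <- matrix(rep(c(3, -2, 5), each = nrow(m$nodes)), ncol = 3)
  expect_equal(cavity_volume(m, u), cavity_volume(m), tolerance = 1e-12)
})

test_that("cavity volume gradient matches finite differences", {
  m <- build_lv_mesh()
  g <- myolv:::cavity_volume_grad(m)
  h <- 1e-6
  set.seed(3)
  for (i in sample(nrow(m$nodes), 5)) {
    for (d in 1:3) {
      up <- matrix(0, nrow(m$nodes), 3); up[i, d] <- h
      fd <- (cavity_volume(m, up) - cavity_volume(m)) / h
      expect_equal(g[i, d], fd, tolerance = 1e-4)
    }
  }
})

test_that("VTK export writes a readable unstructured grid", {
  m <- build_lv_mesh()
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, cell_data = list(layer = as.numeric(factor(m$layer))))
  lines <- readLines(f)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(m$nodes)), lines)))
  expect_true(any(grepl("CELL_DATA 144", lines)))
  unlink(f)
})
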