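test_that("CL shear angle matches closed-form evaluations", {
  expect_equal(cl_shear_angle(0, 0, 0), 0)
  expect_equal(cl_shear_angle(0, 0, 0.1), asin(0.2) * 180 / pi)
  expect_equal(cl_shear_angle(0, 0, 0.1), 11.537, tolerance = 1e-4)
  expect_equal(cl_shear_angle(-0.1, -0.05, 0.05),
               asin(0.1 / sqrt(0.8 * 0.9)) * 180 / pi)
  expect_equal(cl_shear_angle(-0.1, -0.05, 0.05), 6.768, tolerance = 1e-3)
  expect_error(cl_shear_angle(0, 0, 0.6), "arcsin")
  expect_error(cl_shear_angle(-0.6, 0, 0.1), "positive")
})

test_that("CL shear angle is odd and increasing in the shear strain", {
  ecl <- seq(-0.2, 0.2, by = 0.01)
  a <- cl_shear_angle(-0.05, 0.02, ecl)
  expect_equal(a, -rev(a), tolerance = 1e-12)
  expect_true(all(diff(a) > 0))
})

test_that("regional averaging reproduces a brute-force loop", {
  set.seed(11)
  m <- build_lv_mesh()
  ne <- nrow(m$elem)
  st <- data.frame(E_cc = rnorm(ne, -0.1, 0.02), E_rr = rnorm(ne, 0.2, 0.05),
                   E_ll = rnorm(ne, -0.05, 0.02), E_cr = rnorm(ne, 0, 0.01),
                   E_cl = rnorm(ne, 0.03, 0.01), E_rl = rnorm(ne, 0, 0.01))
  out <- regional_average(st, m, layer = "mid", slice = "mid")
  expect_s3_class(out, "regional_strain")
  expect_setequal(unique(out$segment),
                  c("anterior", "lateral", "posterior", "septal"))
  for (seg in unique(out$segment)) {
    keep <- m$layer == "mid" & m$slice == "mid" & m$segment == seg
    brute <- mean(st$E_cc[keep])
    expect_equal(out$mean[out$segment == seg & out$component == "E_cc"],
                 brute)
    expect_equal(out$se[out$segment == seg & out$component == "E_cc"],
                 sd(st$E_cc[keep]) / sqrt(sum(keep)))
  }
  # invariant to element ordering
  perm <- sample(ne)
  lab <- data.frame(layer = m$layer[perm], segment = m$segment[perm],
                    slice = m$slice[perm])
  out2 <- regional_average(st[perm, ], lab, layer = "mid", slice = "mid")
  expect_equal(out2[order(out2$segment, out2$component), "mean"],
               out[order(out$segment, out$component), "mean"])
})

test_that("uniform fields average to themselves with zero spread", {
  m <- build_lv_mesh()
  ne <- nrow(m$elem)
  st <- data.frame(E_cc = rep(-0.1, ne), E_rr = 0, E_ll = 0,
                   E_cr = 0, E_cl = 0, E_rl = 0)
  out <- regional_average(st, m)
  ecc <- out[out$component == "E_cc", ]
  expect_true(all(ecc$mean == -0.1))
  expect_true(all(ecc$se == 0))
})

test_that("element strain tracking recovers prescribed deformations", {
  m <- build_lv_mesh()
  u0 <- matrix(0, nrow(m$nodes), 3)
  E0 <- element_strain_tracking(m, u0, u0)
  expect_true(all(abs(as.matrix(E0)) < 1e-12))
  # uniform 10% circumferential (in-plane) shortening
  lam <- 0.9
  u1 <- cbind(m$nodes[, 1] * (lam - 1), m$nodes[, 2] * (lam - 1), 0)
  E1 <- element_strain_tracking(m, u0, u1)
  expect_equal(E1$E_cc, rep((lam^2 - 1) / 2, nrow(E1)), tolerance = 1e-10)
  expect_equal(E1$E_cc[1], -0.095, tolerance = 1e-12)
})
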