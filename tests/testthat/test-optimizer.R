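test_that("objective matches hand-computed strain and pressure errors", {
  strains <- data.frame(E_cc = 0.1, E_rr = 0.2, E_ll = -0.1,
                        E_cr = 0.01, E_cl = 0.02, E_rl = 0)
  pressures <- c(1, 2, 3, 4, 5, 6)
  tg <- list(strains = strains, pressures = pressures)
  expect_equal(objective_phi(tg, tg)$phi, 0)
  # one pressure point off by 10%
  pred <- list(strains = strains, pressures = replace(pressures, 3, 3 * 1.1))
  expect_equal(objective_phi(pred, tg)$phi, 0.01)
  # one strain point off by 0.05 in every tensor slot (9 slots)
  s2 <- strains
  s2[1, ] <- s2[1, ] + 0.05
  pred2 <- list(strains = s2, pressures = pressures)
  expect_equal(objective_phi(pred2, tg)$phi, 9 * 0.0025)
  expect_error(objective_phi(list(strains = rbind(strains, strains),
                                  pressures = pressures), tg),
               "misaligned")
})

test_that("target container enforces the pressure and point-count contracts", {
  strains <- as.data.frame(matrix(0, 300, 6))
  names(strains) <- c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl")
  expect_s3_class(objective_targets(strains, rep(1, 6)), "objective_targets")
  expect_error(objective_targets(strains, rep(1, 5)), "6 pressure")
  expect_error(objective_targets(strains[1:10, ], rep(1, 6)), "250")
})

quad_bowl <- function(par) sum((par - c(a = 0.3, b = -1))^2)
bounds2 <- data.frame(name = c("a", "b"), lower = c(-2, -3),
                      upper = c(2, 3), stringsAsFactors = FALSE)

test_that("simulated annealing locates a quadratic minimum and is reproducible", {
  lower <- setNames(bounds2$lower, bounds2$name)
  upper <- setNames(bounds2$upper, bounds2$name)
  ctl <- list(n_temps = 30, moves = 30)
  sa1 <- simulated_annealing(quad_bowl, lower, upper, seed = 5, control = ctl)
  sa2 <- simulated_annealing(quad_bowl, lower, upper, seed = 5, control = ctl)
  expect_identical(sa1$par, sa2$par)          # determinism contract
  expect_lt(abs(sa1$par["a"] - 0.3) / 4, 0.01)
  expect_lt(abs(sa1$par["b"] + 1) / 6, 0.01)
  expect_true(all(sa1$par >= lower & sa1$par <= upper))
  # degenerate flat landscape: any feasible point, no error
  flat <- simulated_annealing(function(p) 1, lower, upper, seed = 1)
  expect_equal(flat$value, 1)
})

test_that("response surface converges on an exact quadratic in few iterations", {
  lower <- setNames(bounds2$lower, bounds2$name)
  upper <- setNames(bounds2$upper, bounds2$name)
  region <- list(lower = lower, upper = upper)
  rs <- sequential_response_surface(quad_bowl, region, lower, upper,
                                    seed = 2, control = list(n_iter = 2))
  expect_lt(abs(rs$par["a"] - 0.3) / 4, 1e-6)
  expect_lt(abs(rs$par["b"] + 1) / 6, 1e-6)
  # region size shrinks monotonically
  sizes <- vapply(rs$history, `[[`, numeric(1), "size")
  expect_true(all(diff(sizes) < 0) || length(sizes) == 1)
})

test_that("hybrid beats annealing alone on a curved valley", {
  rosen <- function(p) (1 - p["a"])^2 + 5 * (p["b"] - p["a"]^2)^2
  lower <- c(a = -2, b = -1); upper <- c(a = 2, b = 3)
  sa <- simulated_annealing(rosen, lower, upper, seed = 3)
  rs <- sequential_response_surface(rosen, sa$region, lower, upper,
                                    seed = 4)
  expect_lte(rs$value, sa$value / 10)
  fit <- fit_contraction(rosen, bounds = data.frame(
    name = c("a", "b"), lower = lower, upper = upper), seed = 3)
  expect_true(all(coef(fit) >= lower & coef(fit) <= upper))
  expect_lte(fit$value, min(sa$value, rs$value) + 1e-12)
})
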