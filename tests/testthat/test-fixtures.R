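test_that("flowrate waveform balances filling and ejection", {
  d <- make_flowrate(period = 0.17, edv = 0.5, ef = 0.6)
  # stroke volume carried by the ejection lobe
  ej <- d$phases[d$phases$phase == "ejection", ]
  q_int <- stats::integrate(d$q, ej$start, ej$end,
                            subdivisions = 2000, rel.tol = 1e-10)
  expect_equal(q_int$value, -0.3, tolerance = 1e-8)
  whole <- stats::integrate(d$q, 0, d$period, subdivisions = 2000,
                            rel.tol = 1e-12, abs.tol = 1e-12)
  expect_lt(abs(whole$value), 1e-10)
  # identically zero during both isovolumic windows
  for (ph in c("ivc", "ivr")) {
    w <- d$phases[d$phases$phase == ph, ]
    tt <- seq(w$start, w$end - 1e-9, length.out = 50)
    expect_true(all(d$q(tt) == 0))
  }
  expect_error(make_flowrate(fill_frac = 0.7, eject_frac = 0.3), "phase")
})

test_that("calcium transient respects its bounds and timing", {
  ca <- make_calcium(period = 0.17, peak = 1000, baseline = 100)
  f <- ca_at(ca)
  tt <- seq(0, 0.17, by = 1e-4)
  v <- f(tt)
  expect_gte(min(v), 100 - 1e-9)
  expect_lte(max(v), 1000 + 1e-9)
  expect_equal(f(ca$onset + ca$t_peak), 1000)
  expect_equal(min(v), 100, tolerance = 1e-2)
  # flat when peak equals baseline
  flat <- ca_at(make_calcium(peak = 200, baseline = 200))
  expect_true(all(flat(tt) == 200))
  # time-to-peak grows with the rise time constant
  t_pk <- function(tr) make_calcium(tau_rise = tr, tau_decay = 0.05)$t_peak
  trs <- c(0.005, 0.01, 0.02, 0.03)
  expect_true(all(diff(vapply(trs, t_pk, numeric(1))) > 0))
  # periodicity
  expect_equal(f(0.05), f(0.05 + 0.17), tolerance = 1e-12)
})

test_that("trace CSV round-trips bit-identically with metadata", {
  df <- data.frame(t = seq(0, 1, by = 0.1), y = rnorm(11))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(df, f, meta = list(seed = 42, units = "s,kPa"))
  back <- read_trace_csv(f)
  expect_identical(back$t, df$t)
  expect_identical(back$y, df$y)
  expect_equal(attr(back, "meta")$seed, "42")
  unlink(f)
})

test_that("calcium CSV writer and reader agree", {
  ca <- make_calcium(period = 0.2, peak = 900, baseline = 120)
  f <- tempfile(fileext = ".csv")
  write_calcium_csv(ca, f, dt = 5e-4)
  rd <- read_calcium_csv(f)
  expect_equal(rd$period, 0.2)
  tt <- seq(0, 0.2, by = 1e-3)
  expect_equal(rd$fun(tt), ca_at(ca)(tt), tolerance = 1e-3)
  unlink(f)
})

test_that("YAML configuration instantiates all parameter blocks", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 7",
    "active:",
    "  a_on: 0.025",
    "  k_minus: 10",
    "passive:",
    "  C: 0.3",
    "mesh:",
    "  n_circ: 8",
    "drive:",
    "  period: 0.2",
    "  ef: 0.5",
    "calcium:",
    "  period: 0.2",
    "  peak: 900"), f)
  cfg <- read_config(f)
  expect_equal(cfg$active$a_on, 0.025)
  expect_equal(cfg$active$k_minus, 10)
  expect_equal(cfg$passive$C, 0.3)
  expect_equal(cfg$drive$period, 0.2)
  expect_equal(cfg$calcium$peak, 900)
  expect_equal(cfg$seed, 7)
  expect_s3_class(cfg$mesh, "lv_mesh")
  unlink(f)
})
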