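# shared fixtures for the test suite; everything is generated in code
case1 <- optimized_cases(1)

# a small, fast parameter set with mild rates for oracle comparisons
mild_params <- function(...) {
  active_params(a_on = 0.02, a_off = 150, k_plus = 20, k_minus = 5,
                Ck_pos = 300, Ck_neg = 100, kd_pos = 150, kd_neg = 100,
                kdb_pos = 5, kdb_neg = 8, ...)
}

# dense fixed-step forward-Euler reference for the coupled N/A system
# at fixed length and constant calcium (independent of the RK4 path)
euler_reference <- function(p, ca, hsl, t_end, h = 2e-7, save_every = 500) {
  k1 <- attachment_rate(p$bins, p)
  km1 <- detachment_rate(p$bins, p)
  Nov <- overlap_fraction(hsl, p)
  n <- round(t_end / h)
  N <- 0
  A <- numeric(21)
  out_t <- numeric(0); out_T <- numeric(0); out_N <- numeric(0)
  for (i in seq_len(n)) {
    Nb <- sum(A)
    D <- max(N - Nb, 0)
    A <- A + h * (k1 * D - km1 * A)
    A[A < 0] <- 0
    Nb <- sum(A)
    sink <- switch(p$coop_form,
                   inactive = p$k_minus * (Nov - N),
                   active = p$k_minus * N,
                   unbound = p$k_minus * (N - Nb))
    N <- N + h * (p$a_on * ca * (Nov - N) - p$a_off * (N - Nb) +
                    p$k_plus * Nb - sink)
    N <- min(max(N, Nb), max(Nov, Nb))
    if (i %% save_every == 0) {
      out_t <- c(out_t, i * h)
      out_T <- c(out_T, p$rho * p$k_cb * sum(A * (p$bins + p$x_ps) * 1e-9))
      out_N <- c(out_N, N)
    }
  }
  list(t = out_t, T = out_T, N = out_N, A = A)
}
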