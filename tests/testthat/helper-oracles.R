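# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Oseen tensor and MFPT rates are written
# from their textbook definitions, and the rejection sampler checks the
# closed-form inverse-CDF sampler.

# Oseen tensor in mobility units of mu0 (a = 1 reduced units):
# (1/(8 pi eta r)) (I + rr) = mu0 * (3a/(4r)) (I + rr)
oseen_reduced <- function(d) {
  r <- sqrt(sum(d^2))
  e <- d / r
  (3 / (4 * r)) * (diag(3) + outer(e, e))
}

# Smoluchowski mean-first-passage-time escape rate over the force-tilted
# cusp-harmonic barrier: U(x) = E (x/x_b)^2 - F x / kBT (dimensionless),
# reflecting at -Inf, absorbing at the cusp x_b; double quadrature with
# the inner Gaussian integral in closed form.
mfpt_rate_oracle <- function(F_pn, E, x_b, D, temperature = 298) {
  kbt <- kbt_pn_nm(temperature)
  phi <- F_pn / kbt
  sg <- x_b / sqrt(2 * E)          # Gaussian width of the well
  m <- phi * sg^2                  # tilted well minimum
  u <- function(x) E * (x / x_b)^2 - phi * x
  inner <- function(x) {
    exp(m^2 / (2 * sg^2)) * sqrt(2 * pi) * sg * pnorm((x - m) / sg)
  }
  val <- integrate(function(x) exp(u(x)) * inner(x), m, x_b,
                   rel.tol = 1e-10)$value
  D / val
}

# oracle rupture-force density built from the MFPT rate:
# P(F) = (k(F)/LR) exp(-(1/LR) int_0^F k)
oracle_bsk_pdf <- function(F_grid, LR, E, x_b, D, temperature = 298) {
  k <- vapply(F_grid, mfpt_rate_oracle, numeric(1), E = E, x_b = x_b,
              D = D, temperature = temperature)
  H <- c(0, cumsum((head(k, -1) + tail(k, -1)) / 2 * diff(F_grid)))
  (k / LR) * exp(-H / LR)
}

# rejection sampler from the Evans-Ritchie density (oracle for the
# closed-form inverse-CDF sampler)
er_rejection_sample <- function(n, r, koff, x_beta, temperature = 298) {
  kbt <- kbt_pn_nm(temperature)
  mode <- max(evans_ritchie_mode(r, koff, x_beta, temperature), 1)
  fmax <- evans_ritchie_pdf(mode, r, koff, x_beta, temperature) * 1.05
  hi <- mode + 15 * kbt / x_beta
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, hi)
    y <- runif(2 * n, 0, fmax)
    out <- c(out, x[y <= evans_ritchie_pdf(x, r, koff, x_beta,
                                           temperature)])
  }
  out[seq_len(n)]
}

# exact per-velocity Gaussian summaries of a BSK model (quadrature mean
# and sd), the deterministic fixture for fit recovery
bsk_exact_summaries <- function(params, LRs) {
  mu <- bsk_mean_force(LRs, params)
  m2 <- vapply(LRs, function(lr) {
    integrate(function(x) x^2 * bsk_force_pdf(x, lr, params), 0,
              params$F_c, rel.tol = 1e-8)$value +
      params$F_c^2 * bsk_survival_at_fc(lr, params)
  }, numeric(1))
  data.frame(LR = LRs, mu = mu, sigma = sqrt(m2 - mu^2), n = 1000)
}

# small BD configs used by several tests
bd_test_chain <- function(...) chain_config(...)
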