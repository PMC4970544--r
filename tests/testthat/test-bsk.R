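# BSK rapid-force-spectroscopy model: density, moments, ML fit, band

test_that("BSK density is normalised (with the critical-force point mass) and non-negative", {
  p <- bsk_params(25, 0.8, 1e6)
  for (LR in c(1e3, 1e4, 1e6)) {
    mass <- integrate(function(x) bsk_force_pdf(x, LR, p), 0, p$F_c,
                      rel.tol = 1e-9)$value + bsk_survival_at_fc(LR, p)
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  Fg <- seq(-10, p$F_c * 1.2, length.out = 200)
  d <- bsk_force_pdf(Fg, 1e4, p)
  expect_true(all(d >= 0))
  expect_true(all(d[Fg >= p$F_c] == 0))
  expect_true(all(d[Fg < 0] == 0))
})

test_that("mean rupture force is non-decreasing in loading rate over 1e3..1e11 pN/s", {
  p <- bsk_params(30, 0.4, 1e8)
  mf <- bsk_mean_force(10^seq(3, 11, by = 0.5), p)
  expect_true(all(diff(mf) > -1e-8))
})

test_that("at low loading rate and high barrier the BSK mean approaches the Evans-Ritchie mean", {
  p <- bsk_params(25, 0.5, 1e7)
  for (LR in c(100, 1000)) {
    er_mean <- integrate(function(F) F * evans_ritchie_pdf(F, LR, p$k0,
                                                           p$x_b),
                         0, Inf, rel.tol = 1e-9)$value
    expect_equal(bsk_mean_force(LR, p), er_mean, tolerance = 0.15)
  }
})

test_that("closed-form density agrees with the MFPT-based oracle within 10% sup-norm", {
  for (E in c(15, 20, 25)) {
    p <- bsk_params(E, 0.5, 1e7)
    for (LR in c(1e3, 1e5)) {
      Fg <- seq(0, 0.8 * p$F_c, length.out = 300)
      d_pkg <- bsk_force_pdf(Fg, LR, p)
      d_or <- oracle_bsk_pdf(Fg, LR, E, 0.5, 1e7)
      expect_lt(max(abs(d_pkg - d_or)) / max(d_or), 0.10)
    }
  }
})

test_that("sampling, quantiles and hazard are mutually consistent", {
  p <- bsk_params(20, 0.5, 1e7)
  set.seed(1)
  x <- bsk_sample(5000, 1e4, p)
  expect_equal(mean(x), bsk_mean_force(1e4, p), tolerance = 0.02)
  qs <- bsk_quantile(c(0.25, 0.5, 0.75), 1e4, p)
  expect_equal(mean(x <= qs[2]), 0.5, tolerance = 0.03)
  expect_true(all(diff(qs) > 0))
})

test_that("BSK ML fit recovers generating parameters from AFM summaries + MD forces", {
  truth <- bsk_params(30, 0.4, 1e8)
  afm <- bsk_exact_summaries(truth, afm_velocities() * 10)
  md <- data.frame(force = bsk_quantile(c(.1, .3, .5, .7, .9), 8.3e10,
                                        truth),
                   LR = 8.3e10)
  fit <- fit_bsk(afm, md, seed = 1)
  expect_equal(fit$params$E, 30, tolerance = 0.15)
  expect_equal(fit$params$x_b, 0.4, tolerance = 0.15)
  expect_lt(max(fit$params$D / 1e8, 1e8 / fit$params$D), 3)
  expect_equal(fit$params$k0,
               kramers_k0(fit$params$E, fit$params$x_b, fit$params$D))
})

test_that("fit preconditions and the largest-MD-force exclusion rule", {
  truth <- bsk_params(25, 0.5, 1e7)
  afm <- bsk_exact_summaries(truth, c(500, 2000, 8000))
  expect_error(fit_bsk(afm[1:2, ]), "3 distinct")

  truth2 <- bsk_params(30, 0.4, 1e8)
  afm2 <- bsk_exact_summaries(truth2, c(500, 2000, 8000, 30000))
  # three typical MD-regime ruptures plus one extreme event of the kind
  # the bridged construct forbids
  md <- data.frame(force = bsk_quantile(c(.2, .5, .8, .995), 8.3e10,
                                        truth2),
                   LR = 8.3e10)
  f_all <- fit_bsk(afm2, md, seed = 2)
  f_excl <- fit_bsk(afm2, md, exclude_max_md = TRUE, seed = 2)
  # dropping the outlier changes the fitted barrier
  expect_false(isTRUE(all.equal(f_all$params$E, f_excl$params$E,
                                tolerance = 1e-5)))
  expect_equal(nrow(f_excl$md), 3L)
})

test_that("the bootstrap band covers the generating mean-force curve", {
  truth <- bsk_params(30, 0.4, 1e8)
  LRs <- afm_velocities() * 10
  set.seed(21)
  nv <- 400
  afm <- data.frame(LR = LRs, mu = NA_real_, sigma = NA_real_, n = nv)
  for (i in seq_along(LRs)) {
    s <- bsk_sample(nv, LRs[i], truth)
    afm$mu[i] <- mean(s); afm$sigma[i] <- sd(s)
  }
  md <- data.frame(force = bsk_sample(6, 8.3e10, truth), LR = 8.3e10)
  fit <- fit_bsk(afm, md, seed = 2)
  band <- bsk_confidence_band(fit, n_boot = 80, n_eff = nv, seed = 5)
  truth_curve <- bsk_mean_force(band$LR, truth)
  expect_gte(mean(truth_curve >= band$lo & truth_curve <= band$hi), 0.90)
})
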