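# mobility tensor, drift, noise, stepping, profiles, lifetimes

test_that("mobility limits: Stokes diagonal, far-field Oseen, wall drag", {
  cfg <- chain_config()
  eng_f <- engine_config(hydrodynamics = "free")
  mu0 <- attr(mobility_matrix(chain_state(rbind(c(0, 0, 3000),
                                                c(1e5, 0, 3000))),
                              cfg, eng_f), "mu0")
  # single bead block in free space is mu0 I
  st1 <- chain_state(rbind(c(0, 0, 3000), c(1e5, 0, 3000)))
  M <- mobility_matrix(st1, cfg, eng_f)
  expect_equal(M[1:3, 1:3], mu0 * diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pair block at 100 a matches the Oseen tensor within 1%
  d <- c(100 * cfg$a, 0, 0)
  st2 <- chain_state(rbind(c(0, 0, 3000), c(0, 0, 3000) + d))
  M2 <- mobility_matrix(st2, cfg, eng_f)
  expect_equal(M2[1:3, 4:6] / mu0, oseen_reduced(d / cfg$a),
               tolerance = 0.01, ignore_attr = TRUE)
  # wall drag: self mu_zz strictly decreases approaching the wall
  eng_w <- engine_config(hydrodynamics = "wall")
  zs <- seq(1, 20, by = 0.25) * cfg$a
  mzz <- vapply(zs, function(z) {
    st <- chain_state(rbind(c(0, 0, z), c(5000, 0, z)))
    mobility_matrix(st, cfg, eng_w)[3, 3]
  }, numeric(1))
  expect_true(all(diff(mzz) > 0))
  expect_true(all(mzz > 0 & mzz < mu0))
  expect_error(mobility_matrix(chain_state(rbind(c(0, 0, -1),
                                                 c(100, 0, 50))),
                               cfg, eng_w), "z <= 0")
})

test_that("mobility is symmetric positive-semidefinite on random grafted coils", {
  cfg <- chain_config()
  eng <- engine_config(hydrodynamics = "wall")
  for (seed in 1:10) {
    st <- chain_init(cfg, "coil", seed = seed)
    M <- mobility_matrix(st, cfg, eng)
    expect_equal(M, t(M), tolerance = 1e-12, ignore_attr = TRUE)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev) / max(ev), -1e-10)
  }
})

test_that("point-image wall correction restores no-slip at the boundary", {
  # velocity induced at a near-wall point by a distant point force ~ 0
  cfg <- chain_config()
  eng <- engine_config(hydrodynamics = "wall")
  mu0 <- stokes_mobility(cfg$a, eng$viscosity)
  for (zf in c(0.02, 0.005) * cfg$a) {
    st <- chain_state(rbind(c(0, 0, zf), c(40 * cfg$a, 10 * cfg$a,
                                           8 * cfg$a)))
    pair <- mobility_matrix(st, cfg, eng)[1:3, 4:6]
    oseen_scale <- mu0 * 3 * cfg$a / (4 * sqrt(sum((st$positions[1, ] -
                                                st$positions[2, ])^2) / cfg$a^2))
    expect_lt(max(abs(pair)) / oseen_scale, 0.02)
  }
})

test_that("drift correction: zero off-wall modes, analytic = finite difference, positive near wall", {
  cfg <- chain_config()
  st <- chain_init(cfg, "coil", seed = 2)
  expect_equal(drift_correction(st, cfg, engine_config(hydrodynamics = "free")),
               rep(0, cfg$N))
  expect_equal(drift_correction(st, cfg, engine_config(hydrodynamics = "none")),
               rep(0, cfg$N))
  eng <- engine_config(hydrodynamics = "wall")
  v <- drift_correction(st, cfg, eng)
  expect_true(all(v > 0))
  # FD of the self mu_zz
  h <- 1e-3
  for (i in c(2, 5, 10)) {
    z <- st$positions[i, 3]
    muz <- function(zz) {
      s <- chain_state(rbind(c(0, 0, zz), c(1e6, 0, zz)))
      mobility_matrix(s, cfg, eng)[3, 3]
    }
    fd <- (muz(z + h) - muz(z - h)) / (2 * h) * kbt_pn_nm(cfg$temperature)
    expect_equal(v[i], fd, tolerance = 1e-5)
  }
})

test_that("random displacements satisfy fluctuation-dissipation", {
  # diagonal Stokes case first: covariance 2 kBT dt mu0 I within 3%
  cfg1 <- chain_config()
  mu0 <- stokes_mobility(cfg1$a, 0.89e-3)
  Mdiag <- mu0 * diag(3)
  set.seed(80)
  dt0 <- 55e-9
  Xd <- t(replicate(1e5, random_displacement(Mdiag, dt0)))
  Cd <- 2 * kbt_pn_nm(298) * dt0 * Mdiag
  expect_lt(max(abs(cov(Xd) - Cd)) / Cd[1, 1], 0.03)

  cfg <- chain_config(N = 5)
  eng <- engine_config(hydrodynamics = "wall")
  st <- chain_init(cfg, "coil", seed = 7)
  M <- mobility_matrix(st, cfg, eng)
  dt <- eng$dt
  expect_equal(random_displacement(M, 0), rep(0, 15))
  set.seed(8)
  n <- 3e4
  X <- t(replicate(n, random_displacement(M, dt, cfg$temperature)))
  Cexp <- 2 * kbt_pn_nm(cfg$temperature) * dt * M
  scale <- sqrt(outer(diag(Cexp), diag(Cexp)))
  expect_lt(max(abs(cov(X) - Cexp) / scale), 0.05)
})

test_that("stepping honours its exact special cases", {
  a <- 30
  cfg <- chain_config(N = 2)
  # two beads at the pair-potential minimum, free space, no noise: frozen
  st <- chain_state(rbind(c(0, 0, 900), c(2 * a, 0, 900)),
                    grafted = FALSE)
  eng0 <- engine_config(hydrodynamics = "free", wall = FALSE,
                        noise = FALSE, grafted = FALSE)
  expect_equal(bd_step(st, cfg, eng0)$positions, st$positions,
               tolerance = 1e-12)
  # pure shear advection with diagonal mobility: dx = shear * z * dt
  z0 <- 900
  engS <- engine_config(shear_rate = 1e4, hydrodynamics = "none",
                        wall = FALSE, noise = FALSE, grafted = FALSE)
  out <- bd_step(st, cfg, engS)$positions
  expect_equal(out[, 1] - st$positions[, 1],
               rep(1e4 * z0 * engS$dt, 2), tolerance = 1e-10)
  expect_equal(out[, 2:3], st$positions[, 2:3], tolerance = 1e-12)
})

test_that("the grafted bead never moves and runs are seed-deterministic", {
  cfg <- chain_config(N = 8)
  eng <- engine_config(shear_rate = 5453, n_steps = 2000, n_equil = 500,
                       seed = 4)
  r1 <- bd_run(cfg, eng)
  r2 <- bd_run(cfg, eng)
  expect_identical(r1$blocks, r2$blocks)
  expect_equal(r1$final_state$positions[1, ], c(0, 0, cfg$graft_height))
})

test_that("noise-free relaxation from a stretched line converges to the rest bond length", {
  a <- 30
  cfg <- chain_config(N = 5, epsilon = 1e-9)
  st <- chain_state(cbind(seq(0, 4) * 3 * a, 0, 1000), grafted = FALSE)
  eng <- engine_config(hydrodynamics = "free", wall = FALSE,
                       noise = FALSE, drift = FALSE, grafted = FALSE,
                       n_steps = 4000, n_equil = 0, seed = 1)
  run <- bd_run(cfg, eng, init = st)
  expect_equal(unname(run$blocks[nrow(run$blocks), ]), rep(2 * a, 4),
               tolerance = 1e-4)
})

test_that("a free bead diffuses with the Stokes-Einstein coefficient", {
  cfg <- chain_config()
  eng <- engine_config(hydrodynamics = "free", wall = FALSE,
                       noise = TRUE, grafted = FALSE)
  p <- vwforce:::.reduced_par(cfg, eng)
  p$eps <- 0; p$kappa <- 0
  set.seed(9)
  pos <- matrix(c(0, 0, 5), 1, 3)
  n <- 3e4
  tr <- matrix(NA_real_, n, 3)
  for (s in seq_len(n)) {
    pos <- vwforce:::cpp_bd_step(pos, p)
    tr[s, ] <- pos
  }
  D_hat <- mean(apply(diff(tr), 2, var)) / (2 * p$dt) # reduced units
  D_phys <- D_hat * cfg$a^2 / p$tau
  D0 <- stokes_mobility(cfg$a, eng$viscosity) * kbt_pn_nm(cfg$temperature)
  expect_equal(D_phys, D0, tolerance = 0.05)
})

test_that("tensile profile converts mean bond lengths with the printed spring constant", {
  cfg <- chain_config(N = 20, a = 30, kappa = 203)   # kappa in kBT/nm^2
  r <- rep(2 * 30 + 1, 19)                           # 1 nm extension
  prof <- tensile_profile(r, cfg)
  expect_equal(prof$tensile_force,
               rep(203 * kbt_pn_nm(cfg$temperature), 19))
  expect_equal(prof$tensile_force[1], 834.8, tolerance = 0.002)
  expect_equal(prof$contour_length, 1140)            # 1.14 um
  prof0 <- tensile_profile(rep(60, 19), cfg)
  expect_equal(prof0$tensile_force, rep(0, 19))
})

test_that("lifetime under shear follows the Bell-Evans law and clamps compression", {
  cfg <- chain_config()
  mk <- function(f0) {
    r <- rep(2 * cfg$a, cfg$N - 1)
    kap_pn <- cfg$kappa * kbt_pn_nm(cfg$temperature)
    r[1] <- 2 * cfg$a + f0 / kap_pn
    tensile_profile(r, cfg)
  }
  expect_equal(lifetime_under_shear(mk(0), tau0 = 100, x_beta = 0.3), 100)
  kbt <- kbt_pn_nm(298)
  expect_equal(lifetime_under_shear(mk(kbt / 0.3), 100, 0.3),
               100 / exp(1), tolerance = 1e-9)
  expect_warning(lt <- lifetime_under_shear(mk(-5), 100, 0.3),
                 "compression")
  expect_equal(lt, 100)
})
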