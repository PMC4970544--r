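# bead-spring + LJ chain energy, analytic forces, wall potential

two_bead_state <- function(r, a = 30) {
  chain_state(rbind(c(0, 0, 100), c(r, 0, 100)), grafted = FALSE)
}

test_that("chain energy hits its closed-form anchors", {
  cfg <- chain_config(N = 2)
  a <- cfg$a
  # LJ minimum at r = 2a with the spring at rest: U = -epsilon
  expect_equal(chain_energy(two_bead_state(2 * a), cfg, wall = FALSE),
               -cfg$epsilon)
  # LJ term vanishes where (2a/r)^6 = 2
  r0 <- 2 * a / 2^(1 / 6)
  u <- chain_energy(two_bead_state(r0), cfg, wall = FALSE)
  expect_equal(u, cfg$kappa * a^2 / 2 * (r0 / a - 2)^2, tolerance = 1e-10)
  # three collinear beads at spacing 2a: LJ sum = (-2 + 0.5^12 - 2*0.5^6) eps
  cfg3 <- chain_config(N = 3)
  st3 <- chain_state(rbind(c(0, 0, 100), c(2 * a, 0, 100),
                           c(4 * a, 0, 100)), grafted = FALSE)
  expect_equal(chain_energy(st3, cfg3, wall = FALSE),
               cfg3$epsilon * (-2 + 0.5^12 - 2 * 0.5^6), tolerance = 1e-12)
  # coincident beads error
  st_bad <- chain_state(rbind(c(0, 0, 100), c(0, 0, 100)), grafted = FALSE)
  expect_error(chain_energy(st_bad, cfg, wall = FALSE), "oincident")
})

test_that("analytic forces equal the central finite difference of the energy", {
  cfg <- chain_config(N = 6)
  h <- 1e-4
  set.seed(31)
  worst <- 0
  for (rep in 1:100) {
    # height 2a keeps bead 1 off the wall-potential cutoff, where the
    # force is continuous but not differentiable
    st <- chain_init(cfg, "coil", grafted = FALSE, height = 2,
                     seed = rep)
    Fa <- chain_forces(st, cfg, wall = TRUE)
    num <- matrix(0, cfg$N, 3)
    for (i in seq_len(cfg$N)) for (k in 1:3) {
      pp <- st$positions; pp[i, k] <- pp[i, k] + h
      pm <- st$positions; pm[i, k] <- pm[i, k] - h
      num[i, k] <- -(chain_energy(chain_state(pp), cfg) -
                       chain_energy(chain_state(pm), cfg)) / (2 * h)
    }
    worst <- max(worst, max(abs(num - Fa)) / max(abs(Fa)))
  }
  expect_lt(worst, 1e-6)
})

test_that("pair forces vanish at the minimum and conserve momentum", {
  cfg <- chain_config(N = 2)
  F <- chain_forces(two_bead_state(2 * cfg$a), cfg, wall = FALSE)
  expect_equal(max(abs(F)), 0, tolerance = 1e-12)
  cfgN <- chain_config(N = 8)
  st <- chain_init(cfgN, "coil", grafted = FALSE, seed = 5)
  Fs <- chain_forces(st, cfgN, wall = FALSE)
  expect_equal(colSums(Fs), c(0, 0, 0), tolerance = 1e-12)
})

test_that("energy is invariant under x-y translation", {
  cfg <- chain_config(N = 5)
  st <- chain_init(cfg, "coil", grafted = FALSE, seed = 6)
  shifted <- chain_state(sweep(st$positions, 2, c(123, -45, 0), "+"))
  expect_equal(chain_energy(st, cfg), chain_energy(shifted, cfg),
               tolerance = 1e-12)
})

test_that("wall potential: zero at cutoff, printed bracket at sigma_R/2, divergent and monotone near wall", {
  cfg <- chain_config()
  expect_equal(wall_energy(cfg$sigma_R, cfg), 0)
  expect_equal(wall_energy(cfg$sigma_R * 1.5, cfg), 0)
  # bracket at z = sigma_R/2: 0.4*2^10 - 2^4 + 0.6 = 394.2 x prefactor
  expect_equal(wall_energy(cfg$sigma_R / 2, cfg), cfg$wall_amp * 394.2)
  z <- seq(cfg$sigma_R / 50, cfg$sigma_R, length.out = 400)
  u <- wall_energy(z, cfg)
  expect_true(all(diff(u) < 0))
  expect_gt(u[1], 1e6)
  expect_error(wall_energy(0, cfg), "z > 0")
  expect_error(wall_energy(-1, cfg), "z > 0")
})

test_that("cohesion at 2 kBT collapses an untethered chain relative to the phantom chain", {
  rg_of <- function(eps, seed) {
    cfgc <- chain_config(epsilon = eps)
    engc <- engine_config(hydrodynamics = "free", wall = FALSE,
                          grafted = FALSE, n_steps = 25000,
                          n_equil = 20000, seed = seed)
    mean(bd_run(cfgc, engc,
                init = chain_init(cfgc, "coil", grafted = FALSE,
                                  seed = seed))$rg)
  }
  rg_coh <- mean(vapply(1:2, function(s) rg_of(2, s), numeric(1)))
  rg_phan <- mean(vapply(1:2, function(s) rg_of(1e-9, s), numeric(1)))
  expect_lt(rg_coh, 0.8 * rg_phan)
})
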