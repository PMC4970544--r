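# Brownian-dynamics propagation with hydrodynamic interactions near a
# no-slip wall: Rotne-Prager-Yamakawa pair mobilities plus Blake-image
# wall corrections, Ermak-McCammon drift term, correlated noise from a
# matrix square root, linear shear advection scaled by the normalised
# self-mobility, block-averaged bond statistics and tensile profiles.

#' Engine configuration for a BD run
#'
#' @param shear_rate shear rate (velocity gradient), 1/s.
#' @param dt time step, s (default 55 ns; about 5e-4 bead diffusion
#'   times for the default chain).
#' @param n_steps production steps.
#' @param n_equil equilibration steps, not recorded (default 1e5).
#' @param block_size steps per block average (default 100).
#' @param viscosity solvent dynamic viscosity, Pa s (default 0.89 mPa s).
#' @param seed integer seed; all randomness of the run flows from it.
#' @param hydrodynamics `"wall"` (Rotne-Prager + Blake images, the model
#'   default), `"free"` (plain Rotne-Prager-Yamakawa) or `"none"`
#'   (diagonal Stokes mobility).
#' @param wall include the repulsive wall potential and reflecting
#'   boundary (default TRUE).
#' @param noise include the fluctuation-dissipation random displacement
#'   (FALSE gives deterministic overdamped relaxation).
#' @param drift include the Ermak-McCammon correction
#'   `kBT d(mu_zz)/dz` for the spatial dependence of the random velocity
#'   (wall mode only; identically zero otherwise).
#' @param grafted fix bead 1 (default TRUE).
#' @param literal_shear advect with the bare `shear_rate * z` instead of
#'   the self-mobility-scaled form (sensitivity check; default FALSE).
#' @return list of class `"engine_config"`.
#' @export
engine_config <- function(shear_rate = 0, dt = 55e-9, n_steps = 1e5,
                          n_equil = 1e5, block_size = 100,
                          viscosity = 0.89e-3, seed = NULL,
                          hydrodynamics = c("wall", "free", "none"),
                          wall = TRUE, noise = TRUE, drift = TRUE,
                          grafted = TRUE, literal_shear = FALSE) {
  hydrodynamics <- match.arg(hydrodynamics)
  stopifnot(shear_rate >= 0, dt > 0, n_steps >= 1, n_equil >= 0,
            block_size >= 1, viscosity > 0)
  structure(list(shear_rate = shear_rate, dt = dt,
                 n_steps = as.integer(n_steps),
                 n_equil = as.integer(n_equil),
                 block_size = as.integer(block_size),
                 viscosity = viscosity, seed = seed,
                 hydrodynamics = hydrodynamics, wall = wall,
                 noise = noise, drift = drift, grafted = grafted,
                 literal_shear = literal_shear),
            class = "engine_config")
}

.hydro_code <- function(h) match(h, c("none", "free", "wall")) - 1L

# reduced engine+chain parameter list for the C++ core
.reduced_par <- function(cfg, eng) {
  mu0 <- stokes_mobility(cfg$a, eng$viscosity)
  tau <- bead_time_s(cfg$a, eng$viscosity, cfg$temperature)
  ch <- .reduced_chain(cfg, eng$wall)
  list(eps = ch$eps, kappa = ch$kappa, sigR = ch$sigR,
       wall_amp = ch$wall_amp, wall = eng$wall,
       shear = eng$shear_rate * tau, dt = eng$dt / tau,
       noise = eng$noise, drift = eng$drift, grafted = eng$grafted,
       literal_shear = eng$literal_shear,
       hydro = .hydro_code(eng$hydrodynamics), mu0 = mu0, tau = tau)
}

#' Mobility matrix of the chain
#'
#' 3N x 3N symmetric positive-semidefinite mobility. Modes: wall-corrected
#' (Rotne-Prager-Yamakawa pair mobilities plus point-Blake image
#' corrections and Pade-resummed wall-corrected self-mobilities),
#' free-space (plain RPY) or none (Stokes diagonal).
#'
#' @param state a [chain_state] (positions in nm).
#' @param cfg a [chain_config].
#' @param eng an [engine_config] (supplies viscosity and mode).
#' @return 3N x 3N matrix in nm/(pN s), with attributes `mu0` (Stokes
#'   mobility, same units) and `mode`.
#' @export
mobility_matrix <- function(state, cfg, eng) {
  stopifnot(inherits(state, "chain_state"))
  mu0 <- stokes_mobility(cfg$a, eng$viscosity)
  M <- cpp_mobility(state$positions / cfg$a,
                    .hydro_code(eng$hydrodynamics)) * mu0
  attr(M, "mu0") <- mu0
  attr(M, "mode") <- eng$hydrodynamics
  M
}

#' Ermak-McCammon drift correction
#'
#' The spatial dependence of the wall-corrected self-mobility makes the
#' random velocity state-dependent; the compensating deterministic drift
#' is `v_corr(z) = kBT d(mu_zz self)/dz`, directed away from the wall.
#' Identically zero in free-space/none modes, where the self-mobility is
#' constant.
#'
#' @inheritParams mobility_matrix
#' @return per-bead z-velocities, nm/s.
#' @export
drift_correction <- function(state, cfg, eng) {
  mu0 <- stokes_mobility(cfg$a, eng$viscosity)
  kbt <- kbt_pn_nm(cfg$temperature)
  as.numeric(cpp_drift(state$positions / cfg$a,
                       .hydro_code(eng$hydrodynamics))) *
    mu0 * kbt / cfg$a
}

#' Correlated random displacement satisfying fluctuation-dissipation
#'
#' Zero-mean Gaussian with covariance `2 kBT dt mu`, realised through a
#' Cholesky factor of the mobility (with an eigenvalue-clipping fallback
#' for semidefinite matrices).
#'
#' @param mu mobility matrix, nm/(pN s) (from [mobility_matrix]).
#' @param dt time step, s (0 gives a zero vector).
#' @param temperature kelvin.
#' @return displacement vector of length 3N, nm.
#' @export
random_displacement <- function(mu, dt, temperature = 298) {
  stopifnot(is.matrix(mu), nrow(mu) == ncol(mu), dt >= 0)
  if (dt == 0) return(numeric(nrow(mu)))
  L <- cpp_sqrt_mobility(mu)
  sqrt(2 * kbt_pn_nm(temperature) * dt) *
    as.numeric(L %*% rnorm(nrow(mu)))
}

#' One BD step
#'
#' Applies, in order: shear advection `v_shear(z) = shear_rate * z` scaled
#' by the normalised self-mobility xx-component, hydrodynamically coupled
#' deterministic forces `sum_j mu_ij F_j`, the drift correction, and the
#' random displacement; the grafted bead is not moved and beads crossing
#' the wall are reflected.
#'
#' @inheritParams mobility_matrix
#' @return the updated [chain_state].
#' @export
bd_step <- function(state, cfg, eng) {
  p <- .reduced_par(cfg, eng)
  out <- cpp_bd_step(state$positions / cfg$a, p) * cfg$a
  chain_state(out, grafted = state$grafted)
}

#' Run a BD simulation and collect the tensile-force profile
#'
#' Equilibrates for `n_equil` steps (nothing recorded), then runs
#' `n_steps` production steps recording block means (over `block_size`
#' steps) of all bond lengths, the chain extension in x and the radius of
#' gyration. Final mean bond lengths are means of block means; standard
#' errors come from aggregating blocks into ~30 superblocks, which
#' absorbs residual autocorrelation between adjacent blocks.
#'
#' @param cfg a [chain_config].
#' @param eng an [engine_config].
#' @param init optional initial [chain_state] (default: seeded compact
#'   coil via [chain_init]).
#' @return object of class `"bd_run"`: `profile` (a [tensile_profile]),
#'   `mean_bond_length`, `se_bond_length` (nm), `blocks` (block x bond
#'   matrix, nm), `extension`, `rg` (block series, nm), `final_state`,
#'   plus the configs.
#' @export
bd_run <- function(cfg, eng, init = NULL) {
  stopifnot(inherits(cfg, "chain_config"), inherits(eng, "engine_config"))
  if (!is.null(eng$seed)) set.seed(eng$seed)
  if (is.null(init)) init <- chain_init(cfg, "coil", grafted = eng$grafted)
  p <- .reduced_par(cfg, eng)
  res <- cpp_bd_run(init$positions / cfg$a, p, eng$n_equil, eng$n_steps,
                    eng$block_size)
  blocks <- res$blocks * cfg$a            # nm
  mean_bond <- colMeans(blocks)
  se_bond <- superblock_se(blocks)
  prof <- tensile_profile(mean_bond, cfg, se = se_bond,
                          shear_rate = eng$shear_rate)
  structure(list(profile = prof, mean_bond_length = mean_bond,
                 se_bond_length = se_bond, blocks = blocks,
                 extension = as.numeric(res$extension) * cfg$a,
                 rg = as.numeric(res$rg) * cfg$a,
                 final_state = chain_state(res$final * cfg$a,
                                           grafted = eng$grafted),
                 chain = cfg, engine = eng),
            class = "bd_run")
}

#' @export
print.bd_run <- function(x, ...) {
  cat(sprintf("BD run: shear %g 1/s, %d production steps (%d blocks)\n",
              x$engine$shear_rate, x$engine$n_steps, nrow(x$blocks)))
  cat(sprintf("  grafted-end tension f0 = %.3g +/- %.2g pN\n",
              x$profile$tensile_force[1], x$profile$se[1]))
  invisible(x)
}

# standard error of column means from ~15 superblocks; the coarse
# superblocks absorb slow conformational autocorrelation that
# 100-step blocks do not resolve
superblock_se <- function(blocks, n_super = 15) {
  nb <- nrow(blocks)
  if (nb < 4) return(rep(NA_real_, ncol(blocks)))
  n_super <- max(2, min(n_super, nb %/% 2))
  grp <- cut(seq_len(nb), n_super, labels = FALSE)
  sb <- apply(blocks, 2, function(col) tapply(col, grp, mean))
  apply(sb, 2, sd) / sqrt(n_super)
}

#' Tensile-force profile from mean bond lengths
#'
#' \deqn{f_i = \kappa (\langle r_{i,i+1}\rangle - 2a)} converted to pN
#' (`kappa` in kBT/nm^2 times kBT in pN nm).
#'
#' @param mean_bond_lengths N-1 mean bond lengths, nm.
#' @param cfg a [chain_config] (supplies `kappa`, `a`, `temperature`).
#' @param se optional standard errors of the mean bond lengths, nm.
#' @param shear_rate recorded for bookkeeping, 1/s.
#' @return object of class `"tensile_profile"`: `mean_bond_length`,
#'   `tensile_force` (pN), `se` (pN), `shear_rate`, `contour_length`
#'   (nm, `(N-1) 2a`).
#' @export
tensile_profile <- function(mean_bond_lengths, cfg, se = NULL,
                            shear_rate = NA_real_) {
  stopifnot(inherits(cfg, "chain_config"),
            length(mean_bond_lengths) == cfg$N - 1)
  kap_pn <- cfg$kappa * kbt_pn_nm(cfg$temperature)   # pN/nm
  f <- kap_pn * (mean_bond_lengths - 2 * cfg$a)
  structure(list(mean_bond_length = mean_bond_lengths,
                 tensile_force = f,
                 se = if (is.null(se)) rep(NA_real_, length(f))
                      else kap_pn * se,
                 shear_rate = shear_rate,
                 contour_length = (cfg$N - 1) * 2 * cfg$a),
            class = "tensile_profile")
}

#' @export
print.tensile_profile <- function(x, ...) {
  cat(sprintf("tensile profile: %d bonds, contour %g nm, shear %g 1/s\n",
              length(x$tensile_force), x$contour_length, x$shear_rate))
  cat(sprintf("  f0 (grafted end) = %.3g pN, f_last = %.3g pN\n",
              x$tensile_force[1], tail(x$tensile_force, 1)))
  invisible(x)
}

#' Complex lifetime under shear from the grafted-end tension
#'
#' Plugs the mean tensile force of the grafted-end bond into the
#' Bell-Evans lifetime law ([bell_evans_lifetime]). Negative mean
#' tensions (compression) are clamped to zero with a warning, since
#' compression does not accelerate rupture in this regime.
#'
#' @param profile a [tensile_profile].
#' @param tau0 zero-force lifetime, s (`1/koff` from a Bell-Evans fit).
#' @param x_beta barrier width, nm.
#' @param temperature kelvin.
#' @return estimated lifetime, s.
#' @export
lifetime_under_shear <- function(profile, tau0, x_beta,
                                 temperature = 298) {
  stopifnot(inherits(profile, "tensile_profile"))
  f0 <- profile$tensile_force[1]
  if (is.na(f0)) stop("profile has no grafted-end tension", call. = FALSE)
  if (f0 < 0) {
    warning("grafted-end bond is under compression; clamping force to 0",
            call. = FALSE)
    f0 <- 0
  }
  bell_evans_lifetime(f0, tau0, x_beta, temperature)
}
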