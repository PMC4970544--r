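# Coarse-grained VWF force field: each bead is one protomer (radius of
# gyration a = 30 nm); beads cohere through a 12-6 Lennard-Jones potential
# and the backbone is held by harmonic springs of rest length 2a; a
# truncated repulsive 10-4 potential keeps beads off the grafting wall.

#' Bead-spring chain configuration
#'
#' @param N number of beads (>= 2). Default 20: 19 bonds x 60 nm gives the
#'   1.14 um contour length of the simulated multimer.
#' @param a bead (protomer) radius, nm.
#' @param epsilon LJ cohesion strength, kBT units. The default 2 kBT
#'   collapses an untethered chain, mimicking circulating VWF.
#' @param kappa backbone spring constant, kBT/nm^2. Default `203 / a^2`
#'   (i.e. 203 kBT per squared bead radius), the bead-spring convention;
#'   see the methods vignette for why the per-`a^2` reading is the stable,
#'   dimensionally consistent one.
#' @param sigma_R wall repulsion range, nm.
#' @param temperature kelvin.
#' @param wall_amp wall-potential amplitude, kBT. The default is the
#'   dimensionless prefactor `2 pi sigma_R / a`; it is exposed because the
#'   amplitude only needs to be large enough to keep beads off the wall.
#' @param graft_height height of the fixed grafted bead, nm (default `a`,
#'   keeping the wall-corrected mobility well defined; the grafted bead
#'   never moves, so this only affects hydrodynamic coupling).
#' @return list of class `"chain_config"`.
#' @export
chain_config <- function(N = 20, a = 30, epsilon = 2, kappa = 203 / a^2,
                         sigma_R = 45, temperature = 298,
                         wall_amp = 2 * pi * sigma_R / a,
                         graft_height = a) {
  stopifnot(N >= 2)
  stop_if_not_positive(a = a, epsilon = epsilon, kappa = kappa,
                       sigma_R = sigma_R, temperature = temperature,
                       wall_amp = wall_amp, graft_height = graft_height)
  structure(list(N = as.integer(N), a = a, epsilon = epsilon,
                 kappa = kappa, sigma_R = sigma_R,
                 temperature = temperature, wall_amp = wall_amp,
                 graft_height = graft_height),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("bead-spring chain: N = %d, a = %g nm, eps = %g kBT,\n",
              x$N, x$a, x$epsilon))
  cat(sprintf("  kappa = %.4g kBT/nm^2 (%.4g kBT/a^2), sigma_R = %g nm, T = %g K\n",
              x$kappa, x$kappa * x$a^2, x$sigma_R, x$temperature))
  cat(sprintf("  contour length (N-1) x 2a = %g nm\n", (x$N - 1) * 2 * x$a))
  invisible(x)
}

#' Chain state: bead positions
#'
#' @param positions N x 3 matrix of bead positions, nm; the wall is at
#'   z = 0 and all mobile beads must have z > 0 when a wall is present.
#' @param grafted is bead 1 fixed at its position (default TRUE)?
#' @return object of class `"chain_state"`.
#' @export
chain_state <- function(positions, grafted = TRUE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 2)
  structure(list(positions = positions, grafted = grafted),
            class = "chain_state")
}

#' Initial chain configurations
#'
#' `"coil"` grows a compact random walk of bond length 2a above the wall
#' (overlap-avoiding, z kept in a band above the graft height), suitable
#' for equilibrating the collapsed globule; `"line"` lays the chain
#' straight along x at a fixed height.
#'
#' @param cfg a [chain_config].
#' @param mode `"coil"` or `"line"`.
#' @param grafted fix bead 1 (default TRUE; bead 1 sits at
#'   `(0, 0, graft_height)`).
#' @param height line height or coil band centre in units of `a`
#'   (default 1.5).
#' @param seed optional integer seed.
#' @return a [chain_state].
#' @export
chain_init <- function(cfg, mode = c("coil", "line"), grafted = TRUE,
                       height = 1.5, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  a <- cfg$a; N <- cfg$N
  pos <- matrix(0, N, 3)
  pos[1, ] <- c(0, 0, if (grafted) cfg$graft_height else height * a)
  if (mode == "line") {
    for (i in 2:N) pos[i, ] <- pos[1, ] + c((i - 1) * 2 * a, 0, 0)
    if (grafted) pos[2:N, 3] <- height * a
  } else {
    zlo <- 1.4 * a; zhi <- 4 * a
    for (restart in 1:50) {
      ok <- TRUE
      for (i in 2:N) {
        placed <- FALSE
        for (try in 1:300) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- pos[i - 1, ] + 2 * a * u
          if (cand[3] < zlo) cand[3] <- zlo + (zlo - cand[3])
          if (cand[3] > zhi) cand[3] <- zhi - (cand[3] - zhi)
          d <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                               matrix(cand, i - 1, 3, byrow = TRUE))^2))
          # hard floor on separations: deep LJ overlaps at the start
          # would destabilise the first integration steps
          if (all(d > 1.9 * a) && abs(d[i - 1] - 2 * a) < 0.15 * a) {
            placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }  # boxed in: regrow the coil
        pos[i, ] <- cand
      }
      if (ok) break
      if (restart == 50) stop("could not grow an overlap-free initial ",
                              "coil", call. = FALSE)
    }
  }
  chain_state(pos, grafted = grafted)
}

# reduced-unit parameters shared by energy/force wrappers
.reduced_chain <- function(cfg, wall = TRUE) {
  list(eps = cfg$epsilon, kappa = cfg$kappa * cfg$a^2,
       sigR = cfg$sigma_R / cfg$a, wall_amp = cfg$wall_amp, wall = wall)
}

#' Potential energy of the chain
#'
#' \deqn{U = \varepsilon \sum_{i<j} [(2a/r_{ij})^{12} - 2 (2a/r_{ij})^6]
#'   + \frac{\kappa}{2} \sum_i (r_{i,i+1} - 2a)^2}
#' plus, when `wall = TRUE`, the repulsive truncated 10-4 wall potential
#' ([wall_energy]) for every bead.
#'
#' @param state a [chain_state].
#' @param cfg a [chain_config].
#' @param wall include the wall term (default TRUE).
#' @return energy in kBT.
#' @export
chain_energy <- function(state, cfg, wall = TRUE) {
  stopifnot(inherits(state, "chain_state"), inherits(cfg, "chain_config"))
  p <- .reduced_chain(cfg, wall)
  cpp_chain_energy(state$positions / cfg$a, p$eps, p$kappa, p$wall,
                   p$sigR, p$wall_amp)
}

#' Analytic forces on all beads
#'
#' Exact gradient of [chain_energy] (LJ + springs + wall). Newton's third
#' law holds pairwise for the LJ/spring parts; the wall force acts along
#' z only.
#'
#' @inheritParams chain_energy
#' @return N x 3 matrix of forces in kBT/nm.
#' @export
chain_forces <- function(state, cfg, wall = TRUE) {
  stopifnot(inherits(state, "chain_state"), inherits(cfg, "chain_config"))
  p <- .reduced_chain(cfg, wall)
  cpp_chain_forces(state$positions / cfg$a, p$eps, p$kappa, p$wall,
                   p$sigR, p$wall_amp) / cfg$a
}

#' Repulsive wall potential
#'
#' Truncated, shifted 10-4 wall:
#' \deqn{U(z) = A\left[\tfrac{2}{5}(\sigma_R/z)^{10} - (\sigma_R/z)^4 +
#'   \tfrac{3}{5}\right] \quad (0 < z < \sigma_R), \qquad 0
#'   \;(z \ge \sigma_R),}
#' with amplitude `A = wall_amp` in kBT (default `2 pi sigma_R / a`). The
#' bracket vanishes at the cutoff, so the potential and force are
#' continuous there, and diverges at the wall. The repulsive branch is
#' necessarily the near-wall one; the printed piecewise conditions of the
#' source model are transposed relative to this (see vignette).
#'
#' @param z heights above the wall, nm (> 0).
#' @param cfg a [chain_config].
#' @return energies, kBT.
#' @export
wall_energy <- function(z, cfg) {
  stopifnot(inherits(cfg, "chain_config"))
  if (any(z <= 0)) stop("wall_energy requires z > 0", call. = FALSE)
  s <- cfg$sigma_R / z
  ifelse(z >= cfg$sigma_R, 0,
         cfg$wall_amp * (0.4 * s^10 - s^4 + 0.6))
}
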