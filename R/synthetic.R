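# Seeded generators for synthetic SMFS inputs: rupture-event datasets from
# known single-barrier kinetics, retraction traces with stretching and
# rupture, and bimodal force mixtures for first-peak fitting.

#' The nine pulling velocities of the SMFS protocol
#'
#' @return velocities in nm/s: 50, 100, 200, 400, 600, 800, 1200, 2000,
#'   3000.
#' @export
afm_velocities <- function() c(50, 100, 200, 400, 600, 800, 1200, 2000, 3000)

#' Generate rupture events from known Bell-Evans kinetics
#'
#' For each velocity, per-event effective spring constants are drawn from
#' a Gaussian truncated at a small positive floor, the loading rate is
#' `r = keff * v`, and rupture forces are sampled from the Evans-Ritchie
#' density by its closed-form inverse CDF.
#'
#' @param koff ground-truth off-rate, 1/s.
#' @param x_beta ground-truth barrier width, nm.
#' @param velocities pulling velocities, nm/s (default: the nine-velocity
#'   protocol of [afm_velocities]).
#' @param keff_mean,keff_sd Gaussian mean/sd of the per-event effective
#'   spring constant, pN/nm.
#' @param n_per_velocity events per velocity.
#' @param temperature kelvin.
#' @param keff_floor truncation floor for keff, pN/nm.
#' @param seed integer seed (reproducible given seed).
#' @return a [rupture_events] data frame with `n_per_velocity *
#'   length(velocities)` rows.
#' @export
gen_rupture_dataset <- function(koff, x_beta,
                                velocities = afm_velocities(),
                                keff_mean = 10, keff_sd = 2,
                                n_per_velocity = 1000, temperature = 298,
                                keff_floor = 0.1, seed = NULL) {
  stop_if_not_positive(koff = koff, x_beta = x_beta, keff_mean = keff_mean,
                       temperature = temperature)
  stopifnot(keff_sd >= 0, n_per_velocity >= 1, all(velocities > 0))
  if (!is.null(seed)) set.seed(seed)
  tab <- do.call(rbind, lapply(velocities, function(v) {
    keff <- pmax(rnorm(n_per_velocity, keff_mean, keff_sd), keff_floor)
    data.frame(keff = keff, velocity = v, r = keff * v)
  }))
  # inverse-CDF draw with each event's own loading rate
  bx <- x_beta / kbt_pn_nm(temperature)
  u <- runif(nrow(tab))
  F <- log1p(-log1p(-u) * tab$r * bx / koff) / bx
  rupture_events(force = F, keff = tab$keff, velocity = tab$velocity)
}

#' Parameters for synthetic force-distance-cycle generation
#'
#' @param velocity retraction velocity, nm/s.
#' @param cantilever_k cantilever spring constant, pN/nm.
#' @param linker_keff linker stiffness, pN/nm; the slope at rupture is the
#'   series combination [effective_spring]`(cantilever_k, linker_keff)`.
#' @param koff,x_beta,temperature ground-truth Bell-Evans kinetics from
#'   which rupture forces are drawn.
#' @param noise_sd baseline force noise, pN.
#' @param specific_fraction probability that a cycle shows a specific
#'   unbinding event (stretching segment + discontinuous jump).
#' @param nonspecific_fraction probability of a short-range nonspecific
#'   adhesion signature near contact (smooth, no jump).
#' @param n_cycles number of cycles.
#' @param d_max retraction length, nm.
#' @param points_per_nm sampling density along distance (default 1/nm).
#' @param seed integer seed.
#' @return validated parameter list of class `"synthetic_fdc_params"`.
#' @export
synthetic_fdc_params <- function(velocity = 400, cantilever_k = 30,
                                 linker_keff = 15, koff = 0.01,
                                 x_beta = 0.3, temperature = 298,
                                 noise_sd = 5, specific_fraction = 0.4,
                                 nonspecific_fraction = 0.1,
                                 n_cycles = 100, d_max = 300,
                                 points_per_nm = 1, seed = NULL) {
  stop_if_not_positive(velocity = velocity, cantilever_k = cantilever_k,
                       linker_keff = linker_keff, koff = koff,
                       x_beta = x_beta, temperature = temperature,
                       d_max = d_max, points_per_nm = points_per_nm)
  stopifnot(noise_sd >= 0, n_cycles >= 1,
            specific_fraction >= 0, nonspecific_fraction >= 0,
            specific_fraction + nonspecific_fraction <= 1)
  structure(list(velocity = velocity, cantilever_k = cantilever_k,
                 linker_keff = linker_keff, koff = koff, x_beta = x_beta,
                 temperature = temperature, noise_sd = noise_sd,
                 specific_fraction = specific_fraction,
                 nonspecific_fraction = nonspecific_fraction,
                 n_cycles = as.integer(n_cycles), d_max = d_max,
                 points_per_nm = points_per_nm, seed = seed),
            class = "synthetic_fdc_params")
}

#' Construct a force-distance retraction trace
#'
#' @param distance tip-sample distances, nm, monotone increasing.
#' @param force forces, pN (negative = attractive/downward deflection).
#' @param velocity retraction velocity, nm/s.
#' @param cantilever_k cantilever spring constant, pN/nm.
#' @param ground_truth optional list of generator metadata.
#' @return object of class `"fdc_trace"`.
#' @export
fdc_trace <- function(distance, force, velocity, cantilever_k,
                      ground_truth = NULL) {
  stopifnot(length(distance) == length(force), length(distance) >= 2,
            velocity > 0, cantilever_k > 0)
  if (is.unsorted(distance, strictly = TRUE)) {
    stop("`distance` must be strictly increasing along the retraction",
         call. = FALSE)
  }
  structure(list(distance = distance, force = force, velocity = velocity,
                 cantilever_k = cantilever_k, ground_truth = ground_truth),
            class = "fdc_trace")
}

#' @export
print.fdc_trace <- function(x, ...) {
  cat(sprintf("FDC retraction trace: %d points, %g-%g nm, v = %g nm/s\n",
              length(x$distance), min(x$distance), max(x$distance),
              x$velocity))
  if (!is.null(x$ground_truth) && isTRUE(x$ground_truth$has_event)) {
    cat(sprintf("  ground truth: F = %.3g pN at d = %g nm (keff %.3g)\n",
                x$ground_truth$force, x$ground_truth$d_rupture,
                x$ground_truth$keff))
  }
  invisible(x)
}

#' Generate synthetic force-distance retraction traces
#'
#' Each cycle is a zero-mean noisy baseline. With probability
#' `specific_fraction` a parabolic stretching segment (the elastic linker
#' signature) ends in a discontinuous jump back to baseline; the jump
#' magnitude is drawn from the ground-truth Evans-Ritchie model at the
#' cycle's loading rate and the local slope at rupture equals the series
#' stiffness of cantilever and linker. With probability
#' `nonspecific_fraction` a smooth short-range adhesion near contact is
#' added instead (no jump). Rupture appears as a negative excursion
#' returning to baseline, the conventional AFM retract sign; magnitudes
#' are reported positive downstream.
#'
#' @param params a [synthetic_fdc_params] list.
#' @return list of [fdc_trace] objects; each carries `ground_truth`
#'   metadata (`type`, and for specific events `force`, `keff`,
#'   `d_rupture`).
#' @export
gen_fdc_traces <- function(params) {
  stopifnot(inherits(params, "synthetic_fdc_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  d <- seq(0, p$d_max, by = 1 / p$points_per_nm)
  keff_true <- effective_spring(p$cantilever_k, p$linker_keff)
  r <- keff_true * p$velocity
  types <- sample(c("specific", "nonspecific", "none"), p$n_cycles,
                  replace = TRUE,
                  prob = c(p$specific_fraction, p$nonspecific_fraction,
                           1 - p$specific_fraction - p$nonspecific_fraction))
  lapply(seq_len(p$n_cycles), function(i) {
    f <- rnorm(length(d), 0, p$noise_sd)
    gt <- list(type = types[i], has_event = FALSE)
    if (types[i] == "specific") {
      F <- evans_ritchie_quantile(runif(1), r = r, koff = p$koff,
                                  x_beta = p$x_beta,
                                  temperature = p$temperature)
      Ls <- 2 * F / keff_true               # stretch length, nm
      # rupture snapped to the sampling grid
      d_lo <- max(Ls + 5, 40); d_hi <- max(d_lo + 1, p$d_max - 50)
      d_rup <- d[findInterval(runif(1, d_lo, d_hi), d)]
      d0 <- d_rup - Ls
      cc <- keff_true^2 / (2 * F)           # parabola curvature
      seg <- d > d0 & d <= d_rup
      f[seg] <- f[seg] - cc / 2 * (d[seg] - d0)^2
      gt <- list(type = "specific", has_event = TRUE, force = F,
                 keff = keff_true, d_rupture = d_rup, d_onset = d0)
    } else if (types[i] == "nonspecific") {
      A <- runif(1, 30, 80); lam <- 8
      f <- f - A * exp(-d / lam)
      gt <- list(type = "nonspecific", has_event = FALSE, amplitude = A)
    }
    fdc_trace(d, f, p$velocity, p$cantilever_k, ground_truth = gt)
  })
}

#' Sample forces from a two-component Gaussian mixture
#'
#' Fixture for first-peak extraction: `w1` of the mass sits in the
#' lower-force component.
#'
#' @param mu1,sd1 lower component mean/sd, pN (`mu1 < mu2`).
#' @param mu2,sd2 upper component mean/sd, pN.
#' @param w1 weight of the lower component, in (0, 1) (or exactly 1 for a
#'   unimodal sample).
#' @param n sample size (0 gives an empty vector).
#' @param seed integer seed.
#' @return numeric vector of forces, pN.
#' @export
gen_bimodal_forces <- function(mu1, sd1, mu2, sd2, w1, n, seed = NULL) {
  stopifnot(mu1 < mu2, w1 > 0, w1 <= 1, sd1 > 0, sd2 > 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  comp <- runif(n) < w1
  ifelse(comp, rnorm(n, mu1, sd1), rnorm(n, mu2, sd2))
}
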