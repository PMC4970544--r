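# Single-energy-barrier (Evans-Ritchie / Bell-Evans) rupture-force model
# under constant loading rate, and its maximum-likelihood fit.

#' Evans-Ritchie rupture-force density
#'
#' Probability density of the unbinding force for a single sharp energy
#' barrier whose off-rate grows exponentially with force (Bell), loaded at
#' a constant rate `r`:
#' \deqn{p(F | r) = (k_{off}/r)\, e^{x_\beta F / k_BT}
#'   \exp\!\left[-\frac{k_{off} k_BT}{r x_\beta}
#'   \left(e^{x_\beta F / k_BT} - 1\right)\right]}
#'
#' @param F rupture force, pN (vectorised).
#' @param r loading rate, pN/s.
#' @param koff zero-force off-rate, 1/s.
#' @param x_beta barrier width along the pulling coordinate, nm.
#' @param temperature kelvin.
#' @return density values, 1/pN.
#' @seealso [evans_ritchie_cdf], [evans_ritchie_quantile], [fit_bell_evans]
#' @export
evans_ritchie_pdf <- function(F, r, koff, x_beta, temperature = 298) {
  stop_if_not_positive(r = r, koff = koff, x_beta = x_beta,
                       temperature = temperature)
  bx <- x_beta / kbt_pn_nm(temperature)       # 1/pN
  out <- (koff / r) * exp(bx * F - (koff / (r * bx)) * expm1(bx * F))
  out[F < 0] <- 0
  out
}

#' Evans-Ritchie rupture-force distribution function
#'
#' @inheritParams evans_ritchie_pdf
#' @return P(rupture force <= F).
#' @export
evans_ritchie_cdf <- function(F, r, koff, x_beta, temperature = 298) {
  stop_if_not_positive(r = r, koff = koff, x_beta = x_beta,
                       temperature = temperature)
  bx <- x_beta / kbt_pn_nm(temperature)
  out <- -expm1(-(koff / (r * bx)) * expm1(bx * F))
  out[F < 0] <- 0
  out
}

#' Evans-Ritchie quantile function (closed-form inverse CDF)
#'
#' @param p probabilities in (0, 1) (vectorised).
#' @inheritParams evans_ritchie_pdf
#' @return forces, pN.
#' @export
evans_ritchie_quantile <- function(p, r, koff, x_beta, temperature = 298) {
  stop_if_not_positive(r = r, koff = koff, x_beta = x_beta,
                       temperature = temperature)
  stopifnot(all(p >= 0 & p < 1))
  bx <- x_beta / kbt_pn_nm(temperature)
  log1p(-log1p(-p) * r * bx / koff) / bx
}

#' Most probable rupture force
#'
#' Closed-form mode of the Evans-Ritchie density,
#' \eqn{F^* = (k_BT/x_\beta)\ln(x_\beta r / (k_{off} k_BT))}, valid when
#' the log-argument exceeds 1 (otherwise the density peaks at 0).
#'
#' @inheritParams evans_ritchie_pdf
#' @return modal force, pN (0 when the distribution peaks at zero force).
#' @export
evans_ritchie_mode <- function(r, koff, x_beta, temperature = 298) {
  kbt <- kbt_pn_nm(temperature)
  pmax(0, (kbt / x_beta) * log(x_beta * r / (koff * kbt)))
}

#' Bell-Evans bond lifetime under constant force
#'
#' \deqn{\tau(F) = \tau_0 \exp(-x_\beta F / k_BT)}
#' With \eqn{\tau_0 = 1/k_{off}} from a Bell-Evans fit and `F` the mean
#' grafted-end tension from a shear-flow BD run, this estimates the A1/A2
#' complex lifetime under physiological shear.
#'
#' @param F force, pN (vectorised).
#' @param tau0 zero-force lifetime, s.
#' @param x_beta barrier width, nm.
#' @param temperature kelvin.
#' @return lifetime, s.
#' @export
bell_evans_lifetime <- function(F, tau0, x_beta, temperature = 298) {
  stop_if_not_positive(tau0 = tau0, x_beta = x_beta,
                       temperature = temperature)
  tau0 * exp(-x_beta * F / kbt_pn_nm(temperature))
}

#' Construct a table of rupture events
#'
#' The atom of all kinetic fits: per-event unbinding force, effective
#' spring constant (slope at rupture) and pulling velocity; the loading
#' rate is derived as `r = keff * velocity`.
#'
#' @param force unbinding forces, pN (> 0).
#' @param keff effective spring constants at rupture, pN/nm (> 0).
#' @param velocity pulling velocities, nm/s (> 0); recycled.
#' @return a `data.frame` of class `"rupture_events"` with columns
#'   `force`, `keff`, `velocity`, `loading_rate`.
#' @export
rupture_events <- function(force, keff, velocity) {
  n <- length(force)
  velocity <- rep_len(velocity, n)
  keff <- rep_len(keff, n)
  if (any(!is.finite(force)) || any(force <= 0)) {
    stop("all rupture forces must be positive and finite", call. = FALSE)
  }
  if (any(keff <= 0) || any(velocity <= 0)) {
    stop("`keff` and `velocity` must be positive", call. = FALSE)
  }
  out <- data.frame(force = force, keff = keff, velocity = velocity,
                    loading_rate = keff * velocity)
  class(out) <- c("rupture_events", "data.frame")
  out
}

# negative log-likelihood of events under (log koff, log x_beta)
.be_nll <- function(lp, F, r, kbt) {
  koff <- exp(lp[1]); xb <- exp(lp[2])
  bx <- xb / kbt
  ll <- log(koff / r) + bx * F - (koff / (r * bx)) * expm1(bx * F)
  if (!all(is.finite(ll))) return(1e12)
  -sum(ll)
}

#' Maximum-likelihood Bell-Evans fit of a loading-rate dependence
#'
#' Fits the Evans-Ritchie single-barrier model to individual rupture
#' events, each with its own loading rate `r = keff * velocity`, by
#' maximising the summed log density over `(koff, x_beta)` in log-parameter
#' space. Standard errors come from the observed information matrix.
#'
#' @param events a [rupture_events] data frame (columns `force`,
#'   `loading_rate`; extra columns ignored).
#' @param temperature kelvin.
#' @param start optional list with elements `koff`, `x_beta` overriding the
#'   internal multi-start heuristics.
#' @return an object of class `"bell_evans_fit"`: a list with `koff`,
#'   `x_beta` (nm), their standard errors, `temperature`, `log_likelihood`,
#'   `n_events`, and the optimizer record.
#' @export
fit_bell_evans <- function(events, temperature = 298, start = NULL) {
  stopifnot(is.data.frame(events),
            all(c("force", "loading_rate") %in% names(events)))
  F <- events$force; r <- events$loading_rate
  if (any(F <= 0) || any(r <= 0)) {
    stop("events must have positive forces and loading rates", call. = FALSE)
  }
  if (length(unique(signif(r, 10))) < 2L) {
    stop("at least 2 distinct loading rates are required to identify ",
         "(koff, x_beta)", call. = FALSE)
  }
  if (sd(F) == 0) {
    stop("degenerate data: all rupture forces are identical", call. = FALSE)
  }
  kbt <- kbt_pn_nm(temperature)

  starts <- if (!is.null(start)) {
    list(log(c(start$koff, start$x_beta)))
  } else {
    # mode-based heuristic: F* = (kbt/xb) log(xb r / (koff kbt))
    lapply(c(0.1, 0.3, 1.0, 3.0), function(xb0) {
      k0 <- (xb0 / kbt) * median(r) * exp(-xb0 * mean(F) / kbt)
      log(c(max(k0, 1e-8), xb0))
    })
  }
  fits <- lapply(starts, function(p0) {
    optim(p0, .be_nll, F = F, r = r, kbt = kbt, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  polish <- optim(best$par, .be_nll, F = F, r = r, kbt = kbt,
                  method = "BFGS", control = list(maxit = 500,
                                                  reltol = 1e-12))
  if (polish$value <= best$value) best <- polish
  if (!is.finite(best$value) || best$value >= 1e12) {
    stop("Bell-Evans fit did not converge: ",
         "optimizer value ", best$value, call. = FALSE)
  }
  H <- optimHess(best$par, .be_nll, F = F, r = r, kbt = kbt)
  se_log <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA, NA))
  koff <- exp(best$par[1]); xb <- exp(best$par[2])
  structure(list(koff = koff, x_beta = xb,
                 se_koff = koff * se_log[1], se_x_beta = xb * se_log[2],
                 temperature = temperature,
                 log_likelihood = -best$value,
                 n_events = length(F), optim = best),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat("Bell-Evans single-barrier maximum-likelihood fit\n")
  cat(sprintf("  events: %d   T = %g K\n", x$n_events, x$temperature))
  cat(sprintf("  koff   = %.4g 1/s  (se %.3g)\n", x$koff, x$se_koff))
  cat(sprintf("  x_beta = %.4g nm   (se %.3g)\n", x$x_beta, x$se_x_beta))
  cat(sprintf("  tau0 = 1/koff = %.4g s   logLik = %.4g\n",
              1 / x$koff, x$log_likelihood))
  invisible(x)
}
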