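# Rupture-event extraction from force-distance cycles and per-velocity
# force statistics: event detection with a polynomial stretch fit,
# binding probability, first-peak Gaussian fit, mu +/- sigma selection.

#' Detect rupture events in a retraction trace
#'
#' Estimates the baseline (median) and noise level (MAD) from the final
#' far-from-surface fifth of the trace, locates discontinuous upward force
#' jumps exceeding `snr_threshold` times the noise, and for each jump fits
#' a low-order polynomial to the preceding stretching segment. The rupture
#' force is the gap between baseline and the fitted force at the jump
#' onset; the effective spring constant `keff` is the magnitude of the
#' fitted slope there.
#'
#' @param trace an [fdc_trace].
#' @param snr_threshold jump detection threshold in noise-sd units
#'   (default 4).
#' @param fit_window maximum length of the stretch segment used for the
#'   polynomial fit, nm (default 10).
#' @param poly_order polynomial order of the stretch fit (default 2, the
#'   parabolic linker signature).
#' @param min_jump absolute floor of the jump threshold, pN (guards the
#'   noiseless limit; default 1e-6).
#' @return data frame with one row per event (sorted by distance):
#'   `force` (pN, positive), `keff` (pN/nm), `distance` (nm). Zero rows
#'   when no event is found.
#' @export
detect_rupture <- function(trace, snr_threshold = 4, fit_window = 10,
                           poly_order = 2, min_jump = 1e-6) {
  stopifnot(inherits(trace, "fdc_trace"), snr_threshold > 0)
  d <- trace$distance; f <- trace$force; n <- length(d)
  if (diff(range(d)) <= fit_window) {
    stop("trace shorter than `fit_window`", call. = FALSE)
  }
  tail_idx <- seq.int(ceiling(0.8 * n), n)
  baseline <- median(f[tail_idx])
  noise <- mad(f[tail_idx])
  # the detection statistic is a first difference, whose noise sd is
  # sqrt(2) * noise; thresholding it at snr_threshold sigma keeps the
  # false-positive rate per trace at the percent level
  thr <- max(snr_threshold * noise * sqrt(2), min_jump)

  jumps <- which(diff(f) > thr)
  if (length(jumps) == 0) {
    return(data.frame(force = numeric(0), keff = numeric(0),
                      distance = numeric(0)))
  }
  # consecutive indices belong to one rupture; onset = last pre-jump sample
  grp <- cumsum(c(1, diff(jumps) > 1))
  onsets <- vapply(split(jumps, grp), min, numeric(1))

  out <- lapply(onsets, function(k) {
    # jumps too close to contact leave no stretch segment to fit
    if (k < poly_order + 2) return(NULL)
    # stretch segment: walk back to the last near-baseline sample
    lo_win <- suppressWarnings(max(1, max(which(d <= d[k] - fit_window))))
    near_base <- which(f[seq_len(k)] >= baseline - max(2 * noise, 1e-9))
    lo <- if (length(near_base)) max(near_base) + 1L else lo_win
    lo <- max(lo, lo_win)
    lo <- min(lo, max(1, k - poly_order - 1))   # keep >= order + 2 points
    idx <- lo:k
    if (length(idx) < 3) return(NULL)
    x <- d[idx] - d[k]
    fit <- stats::lm(f[idx] ~ poly(x, degree = min(poly_order,
                                                   length(idx) - 2),
                                   raw = TRUE))
    co <- coef(fit)
    f_at <- co[1]                         # value at jump onset (x = 0)
    slope <- if (length(co) >= 2) co[2] else 0
    force <- baseline - f_at
    data.frame(force = force, keff = abs(slope), distance = d[k])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(force = numeric(0), keff = numeric(0),
                      distance = numeric(0)))
  }
  out <- out[out$force > thr, , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binding probability over a set of cycles
#'
#' BP = fraction of force-distance cycles showing at least one unbinding
#' event; its collapse under free-ligand blocking demonstrates the
#' specificity of the probed interaction.
#'
#' @param events_per_trace list with one element per cycle: the event
#'   table from [detect_rupture] (or anything whose row/element count is
#'   the event count).
#' @return list of class `"binding_stats"`: `n_total`, `n_with_event`,
#'   `bp`.
#' @export
binding_probability <- function(events_per_trace) {
  if (!is.list(events_per_trace) || length(events_per_trace) == 0) {
    stop("`events_per_trace` must be a non-empty list", call. = FALSE)
  }
  n_ev <- vapply(events_per_trace, function(e) {
    if (is.data.frame(e)) nrow(e) else length(e)
  }, numeric(1))
  out <- list(n_total = length(n_ev), n_with_event = sum(n_ev > 0),
              bp = mean(n_ev > 0))
  class(out) <- "binding_stats"
  out
}

#' @export
print.binding_stats <- function(x, ...) {
  cat(sprintf("binding probability: %d / %d cycles with events (BP = %.3f)\n",
              x$n_with_event, x$n_total, x$bp))
  invisible(x)
}

#' Gaussian fit to the first (lowest-force) peak of a force distribution
#'
#' Builds a histogram density, finds the lowest-force local maximum (the
#' peak that in most cases corresponds to the fingerprint of the specific
#' wild-type rupture), and fits a Gaussian around it by nonlinear least
#' squares restricted to bins below the following antimode, so a second,
#' higher-force population does not bias the fit.
#'
#' @param forces rupture forces, pN.
#' @param n_bins histogram bin count (default: Freedman-Diaconis).
#' @param min_n minimum number of forces (default 50).
#' @return list of class `"peak_fit"`: `mu`, `sigma` (pN), the selection
#'   `interval` `mu +/- sigma`, and the fitted bin table.
#' @export
fit_first_peak <- function(forces, n_bins = NULL, min_n = 50) {
  forces <- forces[is.finite(forces)]
  if (length(forces) < min_n) {
    stop(sprintf("need at least %d forces (got %d)", min_n,
                 length(forces)), call. = FALSE)
  }
  if (sd(forces) == 0) {
    stop("zero-width force distribution: all forces identical",
         call. = FALSE)
  }
  breaks <- if (is.null(n_bins)) "FD" else n_bins
  h <- graphics::hist(forces, breaks = breaks, plot = FALSE)
  cnt <- as.numeric(stats::runmed(h$counts, 3))
  mids <- h$mids
  nb <- length(cnt)
  if (nb < 5) stop("too few histogram bins to locate a peak", call. = FALSE)
  is_max <- vapply(seq_len(nb), function(i) {
    l <- if (i > 1) cnt[i - 1] else -Inf
    r <- if (i < nb) cnt[i + 1] else -Inf
    cnt[i] >= l && cnt[i] >= r && cnt[i] > 0
  }, logical(1))
  # ignore noise bumps below 10% of the global maximum
  is_max <- is_max & cnt >= 0.1 * max(cnt)
  if (!any(is_max)) {
    stop("no local maximum found in the force histogram; distribution ",
         "may be too flat or too sparse", call. = FALSE)
  }
  pk <- which(is_max)[1]
  # antimode: first local minimum after the peak (caps the fit window)
  after <- if (pk < nb) pk + which(diff(cnt[pk:nb]) > 0)[1] - 1 else nb
  if (is.na(after)) after <- nb
  # initial sigma from the half-maximum width
  half <- cnt[pk] / 2
  lo_h <- which(cnt[seq_len(pk)] <= half)
  hi_h <- which(cnt[pk:nb] <= half)
  w_lo <- if (length(lo_h)) mids[pk] - mids[max(lo_h)] else NA
  w_hi <- if (length(hi_h)) mids[pk + min(hi_h) - 1] - mids[pk] else NA
  fwhm <- 2 * mean(c(w_lo, w_hi), na.rm = TRUE)
  if (!is.finite(fwhm) || fwhm <= 0) fwhm <- 2 * diff(mids[1:2])
  s0 <- fwhm / 2.355
  m0 <- mids[pk]
  sel <- which(mids >= m0 - 2.5 * s0 & mids <= m0 + 2.5 * s0)
  sel <- sel[sel <= after]
  if (length(sel) < 4) sel <- max(1, pk - 3):min(nb, pk + 3)
  df <- data.frame(x = mids[sel], y = cnt[sel])
  fit <- tryCatch(
    nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
        start = list(A = cnt[pk], mu = m0, s = s0),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
        algorithm = "port",
        lower = c(A = 0, mu = min(df$x) - s0, s = 1e-6)),
    error = function(e) {
      stop("Gaussian peak fit failed: ", conditionMessage(e),
           call. = FALSE)
    })
  co <- coef(fit)
  mu <- unname(co["mu"]); sigma <- abs(unname(co["s"]))
  structure(list(mu = mu, sigma = sigma,
                 interval = c(mu - sigma, mu + sigma),
                 bins = data.frame(mid = mids, count = cnt)),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("first-peak Gaussian: mu = %.3g pN, sigma = %.3g pN ",
              x$mu, x$sigma))
  cat(sprintf("(selection interval [%.3g, %.3g])\n",
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' Select forces inside the first-peak mu +/- sigma interval
#'
#' Returns the subset with `mu - sigma <= F <= mu + sigma` (closed
#' interval: boundary forces are kept). Idempotent on its own output.
#'
#' @param forces rupture forces, pN.
#' @param peak a [fit_first_peak] result (or any list with `mu`, `sigma`).
#' @return the retained forces.
#' @export
select_mu_sigma <- function(forces, peak) {
  stopifnot(is.numeric(forces), !is.null(peak$mu), peak$sigma > 0)
  forces[forces >= peak$mu - peak$sigma & forces <= peak$mu + peak$sigma]
}

#' Extract per-cycle events and assemble a rupture-event table
#'
#' Runs [detect_rupture] over a list of traces and keeps one event per
#' cycle for kinetics (by convention the last, i.e. farthest, rupture).
#'
#' @param traces list of [fdc_trace] objects.
#' @param which_event `"last"` (default, the standard SMFS convention) or
#'   `"all"`.
#' @param ... passed to [detect_rupture].
#' @return list with `events` (a [rupture_events] data frame),
#'   `binding_stats` ([binding_probability]) and `events_per_trace`.
#' @export
analyze_traces <- function(traces, which_event = c("last", "all"), ...) {
  which_event <- match.arg(which_event)
  stopifnot(length(traces) > 0)
  per_trace <- lapply(traces, detect_rupture, ...)
  bs <- binding_probability(per_trace)
  rows <- mapply(function(ev, tr) {
    if (nrow(ev) == 0) return(NULL)
    if (which_event == "last") ev <- ev[nrow(ev), , drop = FALSE]
    ev$velocity <- tr$velocity
    ev
  }, per_trace, traces, SIMPLIFY = FALSE)
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  events <- if (is.null(rows) || nrow(rows) == 0) {
    rupture_events(numeric(0), numeric(0), numeric(0))
  } else {
    ok <- rows$keff > 0
    rupture_events(rows$force[ok], rows$keff[ok], rows$velocity[ok])
  }
  list(events = events, binding_stats = bs, events_per_trace = per_trace)
}
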