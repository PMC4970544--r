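# Physical constants and unit helpers. Internal force/energy bookkeeping is
# pN and pN nm; BD propagation uses reduced units (length a, energy kBT,
# mobility mu0) with conversion at the I/O boundary only.

# Boltzmann constant, pN nm / K (CODATA: 1.380649e-23 J/K)
.kB_pN_nm <- 1.380649e-2

#' Thermal energy in piconewton-nanometres
#'
#' @param temperature temperature in kelvin.
#' @return kB*T in pN nm (4.1143 pN nm at 298 K).
#' @examples
#' kbt_pn_nm(298)
#' @export
kbt_pn_nm <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_pN_nm * temperature
}

# Stokes mobility of a sphere, nm / (pN s): 1 / (6 pi eta a) with eta in
# Pa s and a in nm.  1 Pa s = 1 N s/m^2 = 1e-6 pN s / nm^2.
stokes_mobility <- function(radius_nm, viscosity_Pa_s) {
  1 / (6 * pi * (viscosity_Pa_s * 1e-6) * radius_nm)
}

# Bead diffusion time a^2 / (mu0 kBT) in seconds; the natural BD time unit.
bead_time_s <- function(radius_nm, viscosity_Pa_s, temperature = 298) {
  radius_nm^2 / (stokes_mobility(radius_nm, viscosity_Pa_s) *
                   kbt_pn_nm(temperature))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
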