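#' Physical constants of the RRM frequency-to-light mapping
#'
#' One record holding every constant the frequency/wavelength conversions
#' depend on, so none is scattered as a literal:
#' \describe{
#'   \item{K}{empirical coefficient of the linear relation
#'     \eqn{\lambda = K / f_{rrm}} between activating-light wavelength (nm)
#'     and RRM frequency; default 201 nm.}
#'   \item{charge_velocity}{estimated velocity of charge transfer along the
#'     macromolecular backbone, m/s; default 7.87e5.}
#'   \item{residue_spacing}{distance between adjacent amino acids, m; default
#'     3.8e-10 (3.8 Angstrom).}
#'   \item{light_speed}{m/s.}
#' }
#'
#' Note the two routes to a physical scale are not mutually consistent: K =
#' 201 nm versus the velocity-based estimate
#' \eqn{\lambda = c\,d/(v f) \approx 145/f} nm differ by ~39%. Both are
#' exposed; neither is "corrected".
#'
#' @param K wavelength-scale coefficient, nm.
#' @param charge_velocity m/s.
#' @param residue_spacing m.
#' @param light_speed m/s.
#' @return An object of class \code{rrm_constants}.
#' @export
rrm_constants <- function(K = 201, charge_velocity = 7.87e5,
                          residue_spacing = 3.8e-10, light_speed = 2.998e8) {
  vals <- c(K = K, charge_velocity = charge_velocity,
            residue_spacing = residue_spacing, light_speed = light_speed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_validation("all physical constants must be finite and strictly positive")
  structure(as.list(vals), class = "rrm_constants")
}

#' @export
print.rrm_constants <- function(x, ...) {
  cat(sprintf("<rrm_constants> K = %g nm, v = %g m/s, d = %g m, c = %g m/s\n",
              x$K, x$charge_velocity, x$residue_spacing, x$light_speed))
  invisible(x)
}

#' Round half-up to the nearest integer
#'
#' The rounding convention used for catalog wavelength comparison (base R's
#' \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Map an RRM frequency to an electromagnetic wavelength
#'
#' \eqn{\lambda = K / f_{rrm}} with \eqn{\lambda} in nm. With
#' \code{rounded = TRUE} the result is rounded half-up to integer nm, the form
#' used for comparison against the printed catalog wavelengths.
#'
#' @param f RRM frequency (cycles/residue), > 0. Values above the Nyquist
#'   limit 0.5 are accepted with a warning (outside the RRM band).
#' @param constants an [rrm_constants()] record.
#' @param rounded round half-up to integer nm.
#' @return Wavelength(s) in nm.
#' @examples
#' rrm_to_wavelength(0.2363, rounded = TRUE)  # 851
#' @export
rrm_to_wavelength <- function(f, constants = rrm_constants(), rounded = FALSE) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop_domain("RRM frequency must be finite and > 0")
  if (any(f > 0.5))
    warning("frequency above the Nyquist limit 0.5: outside the RRM band")
  lambda <- constants$K / f
  if (rounded) round_half_up(lambda) else lambda
}

#' Map a wavelength to an RRM frequency
#'
#' Algebraic inverse of [rrm_to_wavelength()]: \eqn{f = K / \lambda}.
#' Wavelengths below K map to frequencies above the RRM band (0, 0.5]; these
#' are returned with a warning, not rejected.
#'
#' @param lambda_nm wavelength in nm, > 0.
#' @param constants an [rrm_constants()] record.
#' @return RRM frequency (cycles/residue).
#' @export
wavelength_to_rrm <- function(lambda_nm, constants = rrm_constants()) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop_domain("wavelength must be finite and > 0")
  f <- constants$K / lambda_nm
  if (any(f > 0.5))
    warning("mapped frequency above the Nyquist limit 0.5: outside the RRM band")
  f
}

#' Map an RRM frequency to a physical frequency in Hz
#'
#' Uses the charge-transfer route: a charge travelling at
#' \code{charge_velocity} past residues spaced \code{residue_spacing} apart
#' oscillates at \eqn{f \cdot v / d} Hz. Over the RRM band this spans roughly
#' 1e13–1e15 Hz (infra-red through ultra-violet).
#'
#' @param f RRM frequency in (0, 0.5].
#' @param constants an [rrm_constants()] record.
#' @return Frequency in Hz.
#' @export
rrm_to_physical_frequency <- function(f, constants = rrm_constants()) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 0.5))
    stop_domain("RRM frequency must lie in (0, 0.5]")
  f * constants$charge_velocity / constants$residue_spacing
}

#' Estimate the coefficient K from frequency/wavelength pairs
#'
#' Least-squares estimate of K in \eqn{\lambda = K / f}: the slope of
#' \eqn{\lambda} regressed on \eqn{1/f} through the origin,
#' \eqn{\hat K = \sum x_i y_i / \sum x_i^2} with \eqn{x = 1/f}.
#'
#' @param frequencies RRM frequencies, all > 0.
#' @param wavelengths_nm corresponding wavelengths in nm, all > 0.
#' @return Estimated K in nm.
#' @examples
#' f <- c(0.1, 0.2, 0.4)
#' fit_K(f, 100 / f)  # exactly 100
#' @export
fit_K <- function(frequencies, wavelengths_nm) {
  if (length(frequencies) != length(wavelengths_nm))
    stop_validation("frequencies and wavelengths must have equal length")
  ok <- is.finite(frequencies) & is.finite(wavelengths_nm)
  if (!all(ok)) stop_validation("non-finite pairs supplied")
  if (length(frequencies) < 2)
    stop_validation("need at least 2 (frequency, wavelength) pairs")
  if (any(frequencies <= 0) || any(wavelengths_nm <= 0))
    stop_validation("all pairs must be strictly positive")
  x <- 1 / frequencies
  sum(x * wavelengths_nm) / sum(x * x)
}
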