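#' Amplitude/phase spectrum of a numerical series
#'
#' Computes the discrete Fourier spectrum of an encoded sequence on the RRM
#' frequency grid. The series mean is removed, the series is zero-padded to
#' \code{n_points}, and the transform is evaluated at frequencies
#' \code{k/n_points} for \code{k = 0 .. n_points/2} (cycles per residue; the
#' Nyquist limit for unit residue spacing is 0.5). Because the mean is removed
#' before padding, the amplitude at frequency 0 is exactly 0.
#'
#' Zero-padding brings sequences of unequal length onto a common grid without
#' distorting phases; \code{n_points} defaults to 512 and must be at least the
#' series length. No sub-bin interpolation is performed: frequencies are
#' reported at grid resolution only.
#'
#' @param series an \code{rrm_series} (length >= 4), see [encode_sequence()].
#' @param n_points transform size (even, >= series length).
#' @return An object of class \code{rrm_spectrum}: list with
#'   \code{frequencies}, \code{amplitudes}, \code{phases} (radians in
#'   \code{(-pi, pi]}), \code{n_points}, \code{source_id}.
#' @export
amplitude_spectrum <- function(series, n_points = 512) {
  X <- series_fft(series, n_points)
  k <- 0:(n_points / 2)
  amps <- Mod(X)
  amps[1] <- 0  # mean removal makes the DC bin identically zero
  structure(list(frequencies = k / n_points,
                 amplitudes = amps,
                 phases = Arg(X),
                 n_points = n_points,
                 source_id = series$source_id),
            class = "rrm_spectrum")
}

# Complex half-grid transform (bins 0..n_points/2) of the mean-removed,
# zero-padded series; shared by amplitude_spectrum and phase_difference.
series_fft <- function(series, n_points) {
  stopifnot(inherits(series, "rrm_series"))
  n <- series$length
  if (n < 4) stop_validation(sprintf("series length %d < 4", n))
  if (n_points < n)
    stop_validation(sprintf("n_points (%d) < series length (%d)", n_points, n))
  if (n_points %% 2 != 0) stop_validation("n_points must be even")
  x <- c(series$values - mean(series$values), rep(0, n_points - n))
  stats::fft(x)[1:(n_points / 2 + 1)]
}

#' @export
print.rrm_spectrum <- function(x, ...) {
  cat(sprintf("<rrm_spectrum> '%s', %d-point grid over [0, 0.5]\n",
              x$source_id, length(x$frequencies)))
  invisible(x)
}

#' Multiplicative cross-spectrum of a sequence group
#'
#' The RRM consensus spectrum of a functional group: the pointwise product of
#' the member amplitude spectra. Only a periodicity present in every member
#' survives the product, so the prominent common peak is the group's
#' characteristic frequency. All members must share the same grid (compute
#' each with the same \code{n_points}).
#'
#' Member spectra are not normalized before multiplication by default;
#' \code{normalize = TRUE} divides each member by its maximum amplitude first,
#' as a sensitivity check.
#'
#' @param spectra list of at least two \code{rrm_spectrum} objects.
#' @param normalize divide each member by its max amplitude first.
#' @return An object of class \code{rrm_consensus}: list with
#'   \code{frequencies}, \code{amplitudes}, \code{member_count},
#'   \code{member_ids}, \code{n_points}.
#' @export
cross_spectrum <- function(spectra, normalize = FALSE) {
  if (!is.list(spectra) || length(spectra) < 2)
    stop_validation("cross_spectrum needs at least 2 spectra")
  if (!all(vapply(spectra, inherits, logical(1), "rrm_spectrum")))
    stop_validation("all members must be rrm_spectrum objects")
  np <- vapply(spectra, function(s) s$n_points, numeric(1))
  if (length(unique(np)) != 1L)
    stop_validation(sprintf("mismatched grids: n_points = %s",
                            paste(unique(np), collapse = ", ")))
  amps <- lapply(spectra, function(s) {
    if (normalize && max(s$amplitudes) > 0) s$amplitudes / max(s$amplitudes)
    else s$amplitudes
  })
  structure(list(frequencies = spectra[[1]]$frequencies,
                 amplitudes = Reduce(`*`, amps),
                 member_count = length(spectra),
                 member_ids = vapply(spectra, function(s) s$source_id, character(1)),
                 n_points = np[1]),
            class = "rrm_consensus")
}

#' @export
print.rrm_consensus <- function(x, ...) {
  cat(sprintf("<rrm_consensus> %d members (%s)\n", x$member_count,
              paste(utils::head(x$member_ids, 5), collapse = ", ")))
  invisible(x)
}

# Grid index of `frequency` on a spectrum/consensus grid; errors if off-grid.
grid_index <- function(obj, frequency) {
  i <- which(abs(obj$frequencies - frequency) < 1e-9)
  if (length(i) != 1L)
    stop_validation(sprintf("frequency %.6g is not on the %d-point grid",
                            frequency, obj$n_points))
  i
}

#' Signal-to-noise ratio of a consensus frequency
#'
#' The RRM peak-significance heuristic: the consensus amplitude at
#' \code{frequency} divided by the mean consensus amplitude over the whole
#' grid (peak bin included, zero-frequency bin excluded).
#'
#' @param consensus an \code{rrm_consensus}.
#' @param frequency a frequency on the consensus grid.
#' @return Dimensionless ratio >= 0.
#' @export
signal_to_noise <- function(consensus, frequency) {
  stopifnot(inherits(consensus, "rrm_consensus"))
  i <- grid_index(consensus, frequency)
  amps <- consensus$amplitudes[-1]  # drop degenerate zero-frequency bin
  m <- mean(amps)
  if (m == 0) stop_validation("all-zero consensus: signal-to-noise undefined")
  consensus$amplitudes[i] / m
}

#' Call the consensus peak of a group
#'
#' Returns the grid frequency of maximal consensus amplitude together with its
#' signal-to-noise ratio, provided S/N >= \code{min_snr}; otherwise returns
#' \code{NULL} (no significant common frequency — not an error). Ties are
#' broken toward the lower frequency; the zero-frequency bin is never
#' callable.
#'
#' @param consensus an \code{rrm_consensus}.
#' @param min_snr significance threshold (default 20, the conventional RRM
#'   cutoff).
#' @return An \code{rrm_peak} (list with \code{frequency}, \code{amplitude},
#'   \code{snr}) or \code{NULL}.
#' @export
find_consensus_peak <- function(consensus, min_snr = 20) {
  stopifnot(inherits(consensus, "rrm_consensus"))
  amps <- consensus$amplitudes
  amps[1] <- -Inf  # zero-frequency bin excluded
  i <- which.max(amps)  # which.max returns the first (lowest-frequency) tie
  f <- consensus$frequencies[i]
  snr <- signal_to_noise(consensus, f)
  if (snr < min_snr) return(NULL)
  structure(list(frequency = f, amplitude = consensus$amplitudes[i], snr = snr),
            class = "rrm_peak")
}

#' @export
print.rrm_peak <- function(x, ...) {
  cat(sprintf("<rrm_peak> f = %.6g cycles/residue, amplitude %.4g, S/N %.1f\n",
              x$frequency, x$amplitude, x$snr))
  invisible(x)
}

#' Phase difference between two series at a frequency
#'
#' Absolute principal-value difference of the two Fourier phases at
#' \code{frequency}, in \code{[0, pi]}. The RRM proposes that interacting
#' partners share a characteristic frequency with opposite phase (difference
#' of pi); [is_opposite_phase()] tests that predicate with a tolerance.
#'
#' The phase is undefined where a spectrum has (numerically) zero amplitude:
#' if either amplitude at \code{frequency} is below \code{1e-12} of that
#' spectrum's maximum, an error is raised.
#'
#' @param a,b \code{rrm_series} objects.
#' @param frequency grid frequency.
#' @param n_points transform size used for both series.
#' @return Radians in \code{[0, pi]}.
#' @export
phase_difference <- function(a, b, frequency, n_points = 512) {
  Xa <- series_fft(a, n_points)
  Xb <- series_fft(b, n_points)
  i <- which(abs((0:(n_points / 2)) / n_points - frequency) < 1e-9)
  if (length(i) != 1L)
    stop_validation(sprintf("frequency %.6g is not on the %d-point grid",
                            frequency, n_points))
  for (s in list(a = Xa, b = Xb)) {
    if (Mod(s[i]) < 1e-12 * max(Mod(s)))
      stop_validation(sprintf(
        "amplitude at frequency %.6g is ~0: phase undefined", frequency))
  }
  # principal-value difference via the cross term: exact pi for b = -a
  # (Arg(-|X|^2) = atan2(+/-0, negative) = +/-pi) and exact 0 for b = a
  abs(Arg(Xa[i] * Conj(Xb[i])))
}

#' Test the opposite-phase predicate
#'
#' @inheritParams phase_difference
#' @param tol tolerance around pi (default \code{pi/4}).
#' @return \code{TRUE} if the phase difference is within \code{tol} of pi.
#' @export
is_opposite_phase <- function(a, b, frequency, n_points = 512, tol = pi / 4) {
  abs(phase_difference(a, b, frequency, n_points) - pi) <= tol
}

#' Write a spectrum or consensus to CSV
#'
#' Columns \code{frequency,amplitude} and, for single-sequence spectra,
#' \code{phase}.
#'
#' @param x an \code{rrm_spectrum} or \code{rrm_consensus}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  df <- data.frame(frequency = x$frequencies, amplitude = x$amplitudes)
  if (!is.null(x$phases)) df$phase <- x$phases
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
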