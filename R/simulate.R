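#' Synthesize a sequence group with a known characteristic frequency
#'
#' Generates \code{n} numerical series, each an embedded cosine at the target
#' frequency plus independent Gaussian noise:
#' \code{a * cos(2*pi*f0*j + phi_i) + eps_j}, \code{eps_j ~ N(0, s^2)},
#' \code{j = 0 .. length_i - 1}. This is the controlled stand-in for a
#' functional group sharing a periodicity: the cross-spectrum of the group
#' should recover \code{f0}. Generation is a pure function of its arguments —
#' the seed is applied locally (no global RNG state is consumed or left
#' behind), so the same call always reproduces the same fixture.
#'
#' @param f0 target frequency in the open band (0, 0.5).
#' @param n number of members, >= 2.
#' @param lengths member lengths (recycled to \code{n}), each >= 8.
#' @param amplitude embedded cosine amplitude.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param phases per-member phase vector (radians), or \code{"random"} for
#'   i.i.d. uniform on \code{(-pi, pi]}.
#' @param seed integer RNG seed (mandatory-with-default: 42).
#' @return An object of class \code{rrm_fixture}: list with \code{series}
#'   (list of \code{rrm_series}), \code{true_frequency}, \code{amplitude},
#'   \code{noise_sd}, \code{phases}, \code{lengths}, \code{seed}.
#' @examples
#' fx <- synth_group(0.25, seed = 42)
#' sp <- lapply(fx$series, amplitude_spectrum, n_points = 128)
#' find_consensus_peak(cross_spectrum(sp))
#' @export
synth_group <- function(f0, n = 5, lengths = 128, amplitude = 1,
                        noise_sd = 0.5, phases = "random", seed = 42) {
  if (!is.finite(f0) || f0 <= 0 || f0 >= 0.5)
    stop_domain(sprintf("f0 = %g outside the open band (0, 0.5)", f0))
  if (n < 2) stop_validation("need n >= 2 members")
  lengths <- rep_len(lengths, n)
  if (any(lengths < 8)) stop_validation("member lengths must be >= 8")
  withr::with_seed(seed, {
    phi <- if (identical(phases, "random")) stats::runif(n, -pi, pi)
           else rep_len(phases, n)
    series <- lapply(seq_len(n), function(i) {
      j <- seq_len(lengths[i]) - 1
      v <- amplitude * cos(2 * pi * f0 * j + phi[i]) +
        stats::rnorm(lengths[i], 0, noise_sd)
      new_rrm_series(v, source_id = sprintf("synth_%02d", i))
    })
  })
  structure(list(series = series, true_frequency = f0, amplitude = amplitude,
                 noise_sd = noise_sd, phases = phi, lengths = lengths,
                 seed = seed), class = "rrm_fixture")
}

#' @export
print.rrm_fixture <- function(x, ...) {
  cat(sprintf("<rrm_fixture> %d members, f0 = %g, a = %g, sd = %g, seed = %d\n",
              length(x$series), x$true_frequency, x$amplitude, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Synthesize an interacting pair in phase opposition
#'
#' Two series sharing the embedded frequency \code{f0}, the second
#' phase-shifted by pi relative to the first — the simulated analogue of an
#' interacting protein/target pair, which the RRM proposes share a
#' characteristic frequency at opposite phase.
#'
#' @inheritParams synth_group
#' @param length common series length, >= 8.
#' @return List of two \code{rrm_series}.
#' @export
synth_opposite_pair <- function(f0, length = 128, amplitude = 1,
                                noise_sd = 0.5, seed = 42) {
  fx <- synth_group(f0, n = 2, lengths = length, amplitude = amplitude,
                    noise_sd = noise_sd, phases = c(0, pi), seed = seed)
  fx$series
}

#' Quantize a numerical series back to a residue sequence
#'
#' Maps each value to the residue whose scale value is nearest, ties broken
#' toward the alphabetically first residue. Lets synthetic fixtures round-trip
#' through FASTA and the encoder: \code{encode_sequence(quantize_to_sequence(x,
#' sc), sc)} approximates \code{x} (exactly, when \code{x} already consists of
#' scale values).
#'
#' @param series an \code{rrm_series}.
#' @param scale an \code{rrm_scale}.
#' @return Residue string.
#' @export
quantize_to_sequence <- function(series, scale) {
  stopifnot(inherits(series, "rrm_series"), inherits(scale, "rrm_scale"))
  res <- names(scale$values)  # already sorted alphabetically by constructor
  vals <- unname(scale$values)
  idx <- vapply(series$values,
                function(v) which.min(abs(vals - v)),  # first = alphabetical
                integer(1))
  paste(res[idx], collapse = "")
}

#' Write a fixture to FASTA with a ground-truth manifest
#'
#' Quantizes every member of a fixture to residue sequences under
#' \code{scale}, writes them as a multi-record FASTA, and writes a JSON
#' manifest of the generation parameters (true frequency, amplitude, noise,
#' seed) alongside.
#'
#' @param fixture an \code{rrm_fixture}, see [synth_group()].
#' @param scale an \code{rrm_scale}.
#' @param fasta_path output FASTA path; the manifest goes to the same path
#'   with extension \code{.json}.
#' @return \code{fasta_path}, invisibly.
#' @export
write_fixture_fasta <- function(fixture, scale, fasta_path) {
  stopifnot(inherits(fixture, "rrm_fixture"))
  seqs <- vapply(fixture$series, quantize_to_sequence, character(1),
                 scale = scale)
  names(seqs) <- vapply(fixture$series, function(s) s$source_id, character(1))
  write_fasta(seqs, fasta_path)
  manifest <- list(true_frequency = fixture$true_frequency,
                   amplitude = fixture$amplitude, noise_sd = fixture$noise_sd,
                   phases = fixture$phases, lengths = fixture$lengths,
                   seed = fixture$seed, scale = scale$name)
  jsonlite::write_json(manifest, sub("\\.[^.]*$", ".json", fasta_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}
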