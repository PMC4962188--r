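# Independent brute-force oracles, written before and kept independent of the
# implementation they check.

# O(N^2) direct discrete Fourier sum: X_k = sum_j x_j exp(-2*pi*i*k*j/n).
dft_direct <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(complex(real = x, imaginary = 0) *
          exp(complex(imaginary = -2 * pi * k * (0:(n - 1)) / n)))
  }, complex(1))
}

# Oracle version of the module's spectrum: mean-remove, zero-pad, direct sum,
# keep bins 0..n_points/2.
spectrum_oracle <- function(values, n_points) {
  x <- c(values - mean(values), rep(0, n_points - length(values)))
  X <- dft_direct(x)[1:(n_points / 2 + 1)]
  amps <- Mod(X)
  amps[1] <- 0
  list(frequencies = (0:(n_points / 2)) / n_points, amplitudes = amps,
       phases = Arg(X))
}

# Circular distance between phase vectors (angles equal mod 2*pi, so -pi and
# +pi are the same phase).
phase_dist <- function(p, q) abs(atan2(sin(p - q), cos(p - q)))

# Tiny deterministic protein-like fixture sequences.
random_series <- function(n, seed) {
  withr::with_seed(seed, new_rrm_series(stats::runif(n), source_id = "rand"))
}
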