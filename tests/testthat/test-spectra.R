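test_that("amplitude_spectrum matches the brute-force DFT oracle", {
  for (case in list(c(n = 8, seed = 1), c(n = 17, seed = 2),
                    c(n = 32, seed = 3), c(n = 61, seed = 4),
                    c(n = 64, seed = 5))) {
    s <- random_series(case[["n"]], case[["seed"]])
    np <- 64
    sp <- amplitude_spectrum(s, n_points = np)
    or <- spectrum_oracle(s$values, np)
    expect_equal(sp$frequencies, or$frequencies)
    expect_equal(sp$amplitudes, or$amplitudes, tolerance = 1e-9)
    # compare phases only where amplitude is non-negligible
    big <- or$amplitudes > 1e-9 * max(or$amplitudes)
    expect_lt(max(phase_dist(sp$phases[big], or$phases[big])), 1e-9)
  }
})

test_that("spectrum grid, DC bin and degenerate inputs behave as specified", {
  const <- new_rrm_series(rep(3.7, 16))
  sp <- amplitude_spectrum(const, 32)
  expect_equal(sp$amplitudes, rep(0, 17))  # mean removal annihilates constants
  expect_equal(max(sp$frequencies), 0.5)
  expect_equal(sp$amplitudes[1], 0)
  expect_error(amplitude_spectrum(new_rrm_series(1:3)),
               class = "rrm_validation_error")
  expect_error(amplitude_spectrum(new_rrm_series(1:32), n_points = 16),
               class = "rrm_validation_error")
})

test_that("a pure on-grid cosine concentrates in a single bin", {
  N <- 64; k <- 9
  v <- cos(2 * pi * (k / N) * (0:(N - 1)))
  sp <- amplitude_spectrum(new_rrm_series(v), n_points = N)
  nz <- which(sp$amplitudes > 1e-8)
  expect_equal(sp$frequencies[nz], k / N)
})

test_that("Parseval's identity holds on the padded mean-removed series", {
  for (seed in 1:5) {
    s <- random_series(40, seed)
    np <- 64
    x <- c(s$values - mean(s$values), rep(0, np - 40))
    X <- dft_direct(x)
    expect_equal(sum(Mod(X)^2), np * sum(x^2), tolerance = 1e-9)
    # the returned half-grid is consistent with the full-transform energy
    sp <- amplitude_spectrum(s, np)
    full <- c(sp$amplitudes, rev(sp$amplitudes[2:(np / 2)]))
    expect_equal(sum(full^2), np * sum(x^2), tolerance = 1e-9)
  }
})

test_that("cross_spectrum is the pointwise product of member amplitudes", {
  s <- random_series(32, 11)
  sp <- amplitude_spectrum(s, 64)
  cons <- cross_spectrum(list(sp, sp, sp))
  expect_s3_class(cons, "rrm_consensus")
  expect_equal(cons$amplitudes, sp$amplitudes^3)
  expect_equal(cons$member_count, 3L)
  # absorbing element: a zero spectrum zeroes the consensus
  zero <- amplitude_spectrum(new_rrm_series(rep(1, 16)), 64)
  expect_equal(cross_spectrum(list(sp, zero))$amplitudes, rep(0, 33))
  # contract errors
  expect_error(cross_spectrum(list(sp)), class = "rrm_validation_error")
  expect_error(cross_spectrum(list(sp, amplitude_spectrum(s, 128))),
               class = "rrm_validation_error")
})

test_that("consensus of a seeded cosine group peaks at the embedded frequency", {
  fx <- synth_group(0.25, n = 5, lengths = 128, noise_sd = 0.5, seed = 42)
  cons <- cross_spectrum(lapply(fx$series, amplitude_spectrum, n_points = 512))
  pk <- find_consensus_peak(cons, min_snr = 1)
  expect_lte(abs(pk$frequency - 0.25), 1 / 512)
  # the called peak has the top S/N over all bins
  snrs <- vapply(cons$frequencies[-1], signal_to_noise, numeric(1),
                 consensus = cons)
  expect_equal(max(snrs), pk$snr)
})

test_that("signal_to_noise matches its closed form on constructed spectra", {
  s <- random_series(32, 21)
  cons <- cross_spectrum(list(amplitude_spectrum(s, 64),
                              amplitude_spectrum(s, 64)))
  M <- length(cons$frequencies) - 1  # non-zero-frequency bins
  # single nonzero bin among M bins -> S/N = M
  one <- cons
  one$amplitudes <- c(0, 5, rep(0, M - 1))
  expect_equal(signal_to_noise(one, one$frequencies[2]), M)
  # flat consensus -> S/N = 1 everywhere
  flat <- cons
  flat$amplitudes <- c(0, rep(2, M))
  for (f in flat$frequencies[c(2, 10, M + 1)])
    expect_equal(signal_to_noise(flat, f), 1)
  # direct recomputation on a real consensus
  f <- cons$frequencies[7]
  expect_equal(signal_to_noise(cons, f),
               cons$amplitudes[7] / mean(cons$amplitudes[-1]))
  # all-zero consensus is undefined
  zero <- cons; zero$amplitudes[] <- 0
  expect_error(signal_to_noise(zero, zero$frequencies[2]),
               class = "rrm_validation_error")
  expect_error(signal_to_noise(cons, 0.1234567),
               class = "rrm_validation_error")
})

test_that("find_consensus_peak applies threshold, tie-break and never calls DC", {
  s <- random_series(32, 22)
  cons <- cross_spectrum(list(amplitude_spectrum(s, 100),
                              amplitude_spectrum(s, 100)))
  M <- length(cons$frequencies) - 1
  one <- cons
  one$amplitudes <- c(0, rep(0, M)); one$amplitudes[11] <- 4  # f = 0.10
  expect_equal(find_consensus_peak(one, min_snr = 1)$frequency, 0.10)
  # flat consensus has S/N 1 < 2 -> no call, NULL not error
  flat <- cons; flat$amplitudes <- c(0, rep(1, M))
  expect_null(find_consensus_peak(flat, min_snr = 2))
  # equal maxima at 0.10 and 0.30 -> lower frequency reported
  two <- cons
  two$amplitudes <- c(0, rep(0.01, M))
  two$amplitudes[c(11, 31)] <- 7  # 0.10 and 0.30 on the 100-point grid
  expect_equal(find_consensus_peak(two, min_snr = 1)$frequency, 0.10)
  # huge DC value must never be called
  dc <- cons; dc$amplitudes <- c(1e9, rep(1, M)); dc$amplitudes[21] <- 3
  expect_equal(find_consensus_peak(dc, min_snr = 0)$frequency,
               dc$frequencies[21])
})

test_that("adding a member weak at f demotes f below that member's maximum", {
  # member spectra constructed directly on a shared 20-bin grid
  mk <- function(amps) {
    structure(list(frequencies = (0:20) / 40, amplitudes = c(0, amps),
                   phases = rep(0, 21), n_points = 40, source_id = "c"),
              class = "rrm_spectrum")
  }
  base <- mk(rep(1, 20))
  weak_at_5 <- rep(0.01, 20); weak_at_5[10] <- 2  # maximal at bin 10
  cons <- cross_spectrum(list(base, base, mk(weak_at_5)))
  r <- rank(-cons$amplitudes[-1])
  expect_lt(r[10], r[5])  # bin 10 now outranks bin 5
  expect_equal(find_consensus_peak(cons, min_snr = 0)$frequency,
               cons$frequencies[11])
})

test_that("phase_difference has the stated identities", {
  s <- random_series(32, 31)
  neg <- new_rrm_series(-s$values, source_id = "neg")
  sp <- amplitude_spectrum(s, 64)
  f <- sp$frequencies[which.max(sp$amplitudes)]
  expect_equal(phase_difference(s, neg, f, 64), pi)
  expect_equal(phase_difference(s, s, f, 64), 0)
  # constructed half-period shift of an on-grid cosine
  N <- 64; f0 <- 8 / N; j <- 0:(N - 1)
  a <- new_rrm_series(cos(2 * pi * f0 * j))
  b <- new_rrm_series(cos(2 * pi * f0 * j + pi))
  expect_equal(phase_difference(a, b, f0, N), pi)
  expect_true(is_opposite_phase(a, b, f0, N))
  expect_false(is_opposite_phase(a, a, f0, N))
  # phase undefined where amplitude ~ 0 (pure cosine away from its bin)
  expect_error(phase_difference(a, b, 20 / N, N),
               class = "rrm_validation_error")
})

test_that("per-member normalization changes scale but not the called peak", {
  fx <- synth_group(0.2, n = 4, lengths = c(64, 96, 128, 100), seed = 9)
  sp <- lapply(fx$series, amplitude_spectrum, n_points = 256)
  raw <- find_consensus_peak(cross_spectrum(sp), min_snr = 0)
  nrm <- find_consensus_peak(cross_spectrum(sp, normalize = TRUE), min_snr = 0)
  expect_equal(raw$frequency, nrm$frequency)
})

test_that("spectrum CSV writer emits the documented columns", {
  s <- random_series(16, 41)
  sp <- amplitude_spectrum(s, 32)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, tmp)
  df <- read.csv(tmp)
  expect_identical(names(df), c("frequency", "amplitude", "phase"))
  expect_equal(df$amplitude, sp$amplitudes)
  cons <- cross_spectrum(list(sp, sp))
  write_spectrum_csv(cons, tmp)
  expect_identical(names(read.csv(tmp)), c("frequency", "amplitude"))
})
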