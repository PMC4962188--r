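test_that("blackbody spectra peak where Wien's law says they should", {
  grid <- seq(100, 3000, by = 1)
  sun <- blackbody_spectrum(5778, grid)
  expect_equal(max(sun$intensities), 1)
  expect_true(all(sun$intensities >= 0))
  expect_lte(abs(grid[which.max(sun$intensities)] - 2.898e6 / 5778), 2)
  warm <- blackbody_spectrum(2700, grid)
  expect_lte(abs(grid[which.max(warm$intensities)] - 2.898e6 / 2700), 2)
  expect_error(blackbody_spectrum(-10), class = "rrm_validation_error")
})

test_that("line spectra place maxima at their stated centers", {
  grid <- seq(300, 800, by = 1)
  one <- line_spectrum(data.frame(center_nm = 450, width_nm = 10, height = 1),
                       grid)
  expect_equal(grid[which.max(one$intensities)], 450)
  expect_equal(max(one$intensities), 1)
  two <- line_spectrum(data.frame(center_nm = c(430, 620),
                                  width_nm = c(8, 8), height = c(1, 0.8)),
                       grid)
  i <- two$intensities
  locmax <- grid[which(diff(sign(diff(i))) == -2) + 1]
  expect_true(all(c(430, 620) %in% locmax))
  expect_warning(zero <- line_spectrum(data.frame()[0, ], grid), "all-zero")
  expect_equal(zero$intensities, rep(0, length(grid)))
  expect_error(line_spectrum(data.frame(center_nm = 1, width_nm = 0,
                                        height = 1), grid),
               class = "rrm_validation_error")
})

test_that("light spectrum constructor and CSV reader enforce invariants", {
  expect_error(new_light_spectrum(c(2, 1), c(0, 0)),
               class = "rrm_validation_error")
  expect_error(new_light_spectrum(c(1, 2), c(-1, 0)),
               class = "rrm_validation_error")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = c(500, 400, 600),
                       intensity = c(1, 0.5, 0.2)), tmp, row.names = FALSE)
  sp <- read_light_spectrum(tmp)
  expect_equal(sp$wavelengths_nm, c(400, 500, 600))  # sorted on read
  expect_error(read_light_spectrum("no/file.csv"), class = "rrm_io_error")
})

test_that("coverage distinguishes covered, uncovered, out-of-range, unevaluable", {
  cat68 <- load_catalog()
  # single 851 nm line: Chymotrypsins covered, Proto-oncogenes (3722) not
  src <- line_spectrum(data.frame(center_nm = 851, width_nm = 5, height = 1),
                       grid = seq(300, 2600, by = 1))
  rep1 <- coverage_report(src, cat68, threshold = 0.1, half_band_nm = 10)
  rec <- rep1$records
  expect_true(rec$covered[rec$functional_group == "Chymotrypsins"])
  expect_false(rec$covered[rec$functional_group == "Proto-oncogenes"])
  expect_equal(rec$status[rec$functional_group == "Proto-oncogenes"],
               "out_of_range")  # 3722 nm is beyond the 2600 nm grid
  expect_equal(rec$status[rec$functional_group == "Hemoglobin"], "unevaluable")
  expect_true(all(rep1$summary$fraction_covered >= 0 &
                    rep1$summary$fraction_covered <= 1))
  # degenerate zero source covers nothing
  zero <- suppressWarnings(line_spectrum(data.frame()[0, ]))
  expect_warning(rep0 <- coverage_report(zero, cat68), "covered")
  expect_false(any(rep0$records$covered))
})

test_that("coverage is monotone in threshold and under added intensity", {
  cat68 <- load_catalog()
  src <- light_preset("cfl_fixture")
  lo <- coverage_report(src, cat68, threshold = 0.02)
  hi <- coverage_report(src, cat68, threshold = 0.5)
  expect_true(all(hi$records$covered <= lo$records$covered))
  # adding a peak (below the existing max, so the max is unchanged) only adds
  more <- src
  more$intensities <- pmin(
    src$intensities +
      0.5 * exp(-(src$wavelengths_nm - 700)^2 / (2 * 25)), 1)
  more <- new_light_spectrum(more$wavelengths_nm, more$intensities, "more")
  cov2 <- coverage_report(more, cat68, threshold = 0.02)
  expect_true(all(coverage_report(src, cat68, threshold = 0.02)$records$covered
                  <= cov2$records$covered))
})

test_that("a sun-like blackbody covers strictly more than a single visible line", {
  cat68 <- load_catalog()
  grid <- seq(100, 10000, by = 5)
  sun <- blackbody_spectrum(5778, grid)
  line <- line_spectrum(data.frame(center_nm = 550, width_nm = 10, height = 1),
                        grid)
  csun <- coverage_report(sun, cat68, threshold = 0.01)
  clin <- coverage_report(line, cat68, threshold = 0.01)
  expect_true(all(clin$records$covered <= csun$records$covered))
  expect_gt(sum(csun$records$covered), sum(clin$records$covered))
})

test_that("water_window_filter partitions by published wavelength", {
  cat68 <- load_catalog()
  part <- water_window_filter(cat68, c(380, 750))
  blue <- cat68[!is.na(cat68$super_family) & cat68$super_family == "Blue", ]
  expect_true(all(blue$functional_group %in% part$inside$functional_group))
  tr <- cat68[!is.na(cat68$super_family) &
                cat68$super_family == "Tumor regulation", ]
  expect_true(all(tr$functional_group %in% part$outside$functional_group))
  expect_equal(nrow(part$unevaluable), 2)
  expect_equal(nrow(part$inside) + nrow(part$outside) + nrow(part$unevaluable),
               nrow(cat68))
  # vacuous window keeps every evaluable record
  all_in <- water_window_filter(cat68, c(0, 1e9))
  expect_equal(nrow(all_in$inside), 66)
  expect_error(water_window_filter(cat68, c(700, 300)),
               class = "rrm_validation_error")
})
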