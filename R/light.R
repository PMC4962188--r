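#' Light-source spectral power distributions
#'
#' A \code{light_spectrum} is a relative spectral power distribution: an
#' ascending wavelength grid (nm) with non-negative relative intensities.
#' Sources can be synthesized ([blackbody_spectrum()], [line_spectrum()]),
#' taken from a named preset ([light_preset()]), or read from a two-column CSV
#' ([read_light_spectrum()]).
#'
#' @param wavelengths_nm ascending numeric grid (>= 2 points).
#' @param intensities non-negative relative intensities, same length.
#' @param label source name.
#' @return An object of class \code{light_spectrum}.
#' @export
new_light_spectrum <- function(wavelengths_nm, intensities, label = "source") {
  if (length(wavelengths_nm) < 2 || length(intensities) != length(wavelengths_nm))
    stop_validation("need >= 2 grid points and matching intensity length")
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stop_validation("wavelength grid must be strictly ascending")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop_validation("intensities must be finite and non-negative")
  structure(list(wavelengths_nm = wavelengths_nm, intensities = intensities,
                 label = label), class = "light_spectrum")
}

#' @export
print.light_spectrum <- function(x, ...) {
  cat(sprintf("<light_spectrum> '%s': %d points over %g-%g nm, max %g\n",
              x$label, length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), max(x$intensities)))
  invisible(x)
}

#' Blackbody (Planck) spectrum
#'
#' Planck spectral radiance per unit wavelength at temperature
#' \code{temperature_K}, evaluated on \code{grid} and normalized to maximum 1.
#' By Wien's displacement law the peak sits near \code{2.898e6/T} nm (501 nm
#' for a sun-like 5778 K source).
#'
#' @param temperature_K blackbody temperature, K, > 0.
#' @param grid ascending wavelength grid in nm.
#' @param label source name.
#' @return A \code{light_spectrum}.
#' @export
blackbody_spectrum <- function(temperature_K, grid = seq(200, 3000, by = 2),
                               label = sprintf("blackbody_%gK", temperature_K)) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop_validation("temperature must be > 0")
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23
  lam <- grid * 1e-9
  B <- 1 / (lam^5 * expm1(h * c0 / (lam * kB * temperature_K)))
  new_light_spectrum(grid, B / max(B), label)
}

#' Sum-of-Gaussians line spectrum
#'
#' Synthesizes a peaked source (LED- or fluorescent-like) as a sum of Gaussian
#' bumps \code{height * exp(-(lambda - center)^2 / (2 width^2))}, normalized
#' to maximum 1. \code{width} is the Gaussian standard deviation in nm. An
#' empty peak list yields an all-zero spectrum (allowed, with a warning).
#'
#' @param peaks data frame (or matrix) with columns \code{center_nm},
#'   \code{width_nm}, \code{height}; widths and heights > 0.
#' @param grid ascending wavelength grid in nm.
#' @param label source name.
#' @return A \code{light_spectrum}.
#' @export
line_spectrum <- function(peaks, grid = seq(300, 800, by = 1),
                          label = "line_spectrum") {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    warning("empty peak list: returning an all-zero spectrum")
    return(new_light_spectrum(grid, rep(0, length(grid)), label))
  }
  if (!all(c("center_nm", "width_nm", "height") %in% names(peaks)))
    stop_validation("peaks needs columns center_nm, width_nm, height")
  if (any(peaks$width_nm <= 0) || any(peaks$height <= 0))
    stop_validation("peak widths and heights must be > 0")
  I <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks)))
    I <- I + peaks$height[i] *
      exp(-(grid - peaks$center_nm[i])^2 / (2 * peaks$width_nm[i]^2))
  new_light_spectrum(grid, I / max(I), label)
}

#' Named light-source presets
#'
#' Synthetic stand-ins for common sources (measured lamp curves are not
#' bundled):
#' \describe{
#'   \item{sunlike}{5778 K blackbody on 100-10000 nm.}
#'   \item{incandescent}{2700 K blackbody on 100-10000 nm.}
#'   \item{led_fixture}{synthetic white LED: narrow blue pump at 450 nm plus a
#'     broad phosphor band at 550 nm.}
#'   \item{cfl_fixture}{synthetic compact fluorescent: narrow mercury/phosphor
#'     lines at 405, 436, 488, 546 and 611 nm.}
#' }
#' All presets are normalized to maximum 1 and clearly synthetic: they emulate
#' the qualitative shape (continuous versus peaked) of real sources, not any
#' measured lamp.
#'
#' @param name one of \code{"sunlike"}, \code{"incandescent"},
#'   \code{"led_fixture"}, \code{"cfl_fixture"}.
#' @return A \code{light_spectrum}.
#' @export
light_preset <- function(name) {
  wide <- seq(100, 10000, by = 5)
  switch(name,
    sunlike = blackbody_spectrum(5778, wide, "sunlike (synthetic 5778 K blackbody)"),
    incandescent = blackbody_spectrum(2700, wide, "incandescent (synthetic 2700 K blackbody)"),
    led_fixture = line_spectrum(
      data.frame(center_nm = c(450, 550), width_nm = c(10, 50),
                 height = c(1, 0.7)),
      label = "led_fixture (synthetic)"),
    cfl_fixture = line_spectrum(
      data.frame(center_nm = c(405, 436, 488, 546, 611),
                 width_nm = c(5, 5, 5, 5, 5),
                 height = c(0.3, 0.6, 0.2, 1, 0.9)),
      label = "cfl_fixture (synthetic)"),
    stop_not_found(sprintf(
      "unknown preset '%s'; valid: sunlike, incandescent, led_fixture, cfl_fixture",
      name))
  )
}

#' Read a light spectrum from CSV
#'
#' Expects header \code{wavelength_nm,intensity}.
#'
#' @param path CSV file path.
#' @param label source name (defaults to the file name).
#' @return A \code{light_spectrum}.
#' @export
read_light_spectrum <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_io(sprintf("spectrum file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop_validation("spectrum CSV must have header 'wavelength_nm,intensity'")
  o <- order(df$wavelength_nm)
  new_light_spectrum(df$wavelength_nm[o], df$intensity[o], label)
}

# Max source intensity within [lo, hi] nm, linearly interpolating band
# endpoints that fall between grid points. NA if the band misses the grid.
band_max_intensity <- function(source, lo, hi) {
  w <- source$wavelengths_nm
  if (hi < w[1] || lo > w[length(w)]) return(NA_real_)
  inside <- source$intensities[w >= lo & w <= hi]
  ends <- stats::approx(w, source$intensities,
                        xout = pmin(pmax(c(lo, hi), w[1]), w[length(w)]))$y
  max(c(inside, ends))
}

#' Coverage of the catalog by a light source
#'
#' For each catalog record, asks whether the source emits appreciably at the
#' record's characteristic wavelength: the record is \emph{covered} iff the
#' source's maximum intensity within \code{[lambda - half_band_nm, lambda +
#' half_band_nm]} is at least \code{threshold} times the source's maximum.
#' Records whose band lies wholly outside the source grid are reported as out
#' of range (not covered); the two rows with verbatim "K" wavelengths are
#' unevaluable. A degenerate all-zero source covers nothing (with a warning).
#'
#' Coverage is monotone in both arguments: lowering \code{threshold}, or
#' adding intensity pointwise, never un-covers a record.
#'
#' @param source a \code{light_spectrum}.
#' @param catalog an \code{rrm_catalog}, see [load_catalog()].
#' @param threshold fraction of the source maximum, in (0, 1).
#' @param half_band_nm half-width of the wavelength band, nm, > 0.
#' @return An object of class \code{rrm_coverage}: list with \code{records}
#'   (per-record data frame: wavelength, status, covered flag,
#'   \code{relative_intensity_at_band}), \code{summary} (per-super-family
#'   fraction of member groups covered), \code{source_label}, and the
#'   parameters used.
#' @export
coverage_report <- function(source, catalog = load_catalog(),
                            threshold = 0.05, half_band_nm = 10) {
  stopifnot(inherits(source, "light_spectrum"))
  if (threshold <= 0 || threshold >= 1)
    stop_validation("threshold must lie in (0, 1)")
  if (half_band_nm <= 0) stop_validation("half_band_nm must be > 0")
  src_max <- max(source$intensities)
  if (src_max == 0)
    warning("degenerate source (max intensity 0): nothing is covered")
  n <- nrow(catalog)
  rel <- rep(NA_real_, n)
  status <- rep("unevaluable", n)
  for (i in seq_len(n)) {
    lam <- catalog$wavelength_nm[i]
    if (is.na(lam)) next  # verbatim "K" rows
    bm <- band_max_intensity(source, lam - half_band_nm, lam + half_band_nm)
    if (is.na(bm)) {
      status[i] <- "out_of_range"
    } else if (src_max > 0 && bm >= threshold * src_max) {
      status[i] <- "covered"
      rel[i] <- bm / src_max
    } else {
      status[i] <- "uncovered"
      rel[i] <- if (src_max > 0) bm / src_max else 0
    }
  }
  records <- data.frame(
    rrm_frequency = catalog$rrm_frequency,
    wavelength_nm = catalog$wavelength_nm,
    functional_group = catalog$functional_group,
    super_family = catalog$super_family,
    status = status,
    covered = status == "covered",
    relative_intensity_at_band = rel,
    stringsAsFactors = FALSE)
  ev <- records[records$status != "unevaluable" & !is.na(records$super_family), ]
  summary <- do.call(rbind, lapply(split(ev, ev$super_family), function(g)
    data.frame(super_family = g$super_family[1], n_groups = nrow(g),
               fraction_covered = mean(g$covered))))
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary,
                 source_label = source$label,
                 threshold = threshold, half_band_nm = half_band_nm),
            class = "rrm_coverage")
}

#' @export
print.rrm_coverage <- function(x, ...) {
  cat(sprintf("<rrm_coverage> source '%s', threshold %g, half-band %g nm\n",
              x$source_label, x$threshold, x$half_band_nm))
  tab <- table(x$records$status)
  cat("  records:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  super-family coverage:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("    %-26s %d/%d covered\n", x$summary$super_family[i],
                round(x$summary$fraction_covered[i] * x$summary$n_groups[i]),
                x$summary$n_groups[i]))
  invisible(x)
}

#' Partition the catalog by a wavelength window
#'
#' Splits catalog records by whether their characteristic wavelength lies in
#' \code{[window[1], window[2]]} — e.g. the water transparency window
#' (conventionally taken here as the visible band, 380-750 nm), inside which
#' macromolecular electromagnetic signalling would propagate through the
#' cellular water medium without loss.
#'
#' @param catalog an \code{rrm_catalog}.
#' @param window \code{c(min_nm, max_nm)} with min < max.
#' @return List with elements \code{inside}, \code{outside},
#'   \code{unevaluable} (the "K" rows), each a subset of the catalog.
#' @export
water_window_filter <- function(catalog = load_catalog(), window = c(380, 750)) {
  if (length(window) != 2 || !(window[1] < window[2]))
    stop_validation("window must be c(min, max) with min < max")
  lam <- catalog$wavelength_nm
  list(inside = catalog[!is.na(lam) & lam >= window[1] & lam <= window[2], ],
       outside = catalog[!is.na(lam) & (lam < window[1] | lam > window[2]), ],
       unevaluable = catalog[is.na(lam), ])
}
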