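# Curated catalog of characteristic RRM frequencies for biological functional
# groups, bundled as a plain-text CSV with an integrity checksum. Two rows
# print their wavelength with a "K" suffix ("100 K", "20 K") inconsistent with
# lambda = K/f; they are kept verbatim with a missing numeric wavelength and
# excluded from all numeric paths.

CATALOG_MD5 <- "dd16b48feea41c33f46a543f95744a8b"

SUPER_FAMILIES <- c("Tumor regulation", "Viral-bacterial infection", "Growth",
                    "Enzymes", "Structural proteins", "Blue")

catalog_path <- function() {
  system.file("extdata", "table1_catalog.csv", package = "rrmtools",
              mustWork = TRUE)
}

#' Load the characteristic-frequency catalog
#'
#' Returns the curated table of characteristic RRM frequencies for protein and
#' DNA functional groups: one row per functional group with its RRM frequency,
#' the published wavelength in nm, and (where the group belongs to one) its
#' functional super family — Tumor regulation, Viral-bacterial infection,
#' Growth, Enzymes, Structural proteins, or Blue (blue-light
#' absorption/emission proteins).
#'
#' Two anomalous rows (frequencies 0.002 and 0.0234) publish their wavelength
#' as \code{"100 K"} and \code{"20 K"}, inconsistent with the relation
#' \eqn{\lambda = K/f}; they are stored verbatim in
#' \code{wavelength_verbatim} with \code{NA} in \code{wavelength_nm} and are
#' excluded from numeric analyses. In addition, the loader computes
#' \code{eq1_nm = round_half_up(K/frequency)} and flags each numeric row with
#' \code{eq1_consistent}; three published wavelengths (at frequencies 0.0446,
#' 0.289 and 0.297) differ by 1 nm from the relation and carry
#' \code{eq1_consistent = FALSE}.
#'
#' @param check_integrity verify the bundled file's MD5 checksum.
#' @param constants an [rrm_constants()] record used for the consistency
#'   columns.
#' @return A data frame of class \code{rrm_catalog}, rows sorted by frequency
#'   ascending, with columns \code{rrm_frequency}, \code{wavelength_nm},
#'   \code{wavelength_verbatim}, \code{functional_group}, \code{super_family},
#'   \code{eq1_nm}, \code{eq1_consistent}.
#' @export
load_catalog <- function(check_integrity = TRUE, constants = rrm_constants()) {
  path <- catalog_path()
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, CATALOG_MD5))
      stop_validation(sprintf(
        "bundled catalog failed integrity check (md5 %s, expected %s)",
        md5, CATALOG_MD5))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rrm_frequency = "numeric",
                                       wavelength_nm = "numeric",
                                       wavelength_verbatim = "character",
                                       functional_group = "character",
                                       super_family = "character"))
  df$super_family[df$super_family == ""] <- NA_character_
  df$wavelength_verbatim[df$wavelength_verbatim == ""] <- NA_character_
  if (is.unsorted(df$rrm_frequency))
    stop_validation("catalog rows are not sorted by frequency")
  if (any(df$rrm_frequency <= 0 | df$rrm_frequency > 0.5))
    stop_validation("catalog frequency outside (0, 0.5]")
  df$eq1_nm <- round_half_up(constants$K / df$rrm_frequency)
  df$eq1_consistent <- !is.na(df$wavelength_nm) & df$eq1_nm == df$wavelength_nm
  class(df) <- c("rrm_catalog", "data.frame")
  df
}

#' Classify a frequency against the catalog
#'
#' Nearest-match lookup: all catalog records whose characteristic frequency
#' lies within \code{tolerance} of \code{f}, nearest first (ties broken by
#' ascending frequency). The default tolerance, 0.004, is about half the
#' typical gap between adjacent catalog frequencies.
#'
#' @param f RRM frequency in (0, 0.5].
#' @param tolerance non-negative frequency delta (default 0.004).
#' @param catalog an \code{rrm_catalog}, see [load_catalog()].
#' @return Subset of the catalog (possibly zero rows), nearest first.
#' @examples
#' classify_frequency(0.300)
#' @export
classify_frequency <- function(f, tolerance = 0.004, catalog = load_catalog()) {
  if (!is.finite(f) || f <= 0 || f > 0.5)
    stop_domain(sprintf("frequency %g outside the RRM band (0, 0.5]", f))
  if (tolerance < 0) stop_validation("tolerance must be >= 0")
  d <- abs(catalog$rrm_frequency - f)
  hit <- d <= tolerance + 1e-12
  out <- catalog[hit, , drop = FALSE]
  out[order(d[hit], out$rrm_frequency), , drop = FALSE]
}

#' Frequency band of a functional super family
#'
#' Minimum and maximum characteristic frequency over the catalog records of a
#' super family.
#'
#' Note: for \code{"Tumor regulation"} the catalog's colored block starts at
#' 0.027 (Protein A-VHIII) while the accompanying text gives the band as
#' 0.031–0.054; the catalog is the primary artifact, so the band returned is
#' \code{c(0.027, 0.054)} and the discrepancy is attached as the \code{"note"}
#' attribute rather than silently resolved.
#'
#' @param name one of the known super-family labels (see the error message for
#'   the list).
#' @param catalog an \code{rrm_catalog}.
#' @return Named numeric vector \code{c(f_min = ..., f_max = ...)}; for Tumor
#'   regulation, with a \code{"note"} attribute documenting the band-edge
#'   discrepancy.
#' @export
superfamily_band <- function(name, catalog = load_catalog()) {
  if (!name %in% SUPER_FAMILIES)
    stop_not_found(sprintf("unknown super family '%s'; valid names: %s",
                           name, paste(SUPER_FAMILIES, collapse = ", ")))
  f <- catalog$rrm_frequency[!is.na(catalog$super_family) &
                               catalog$super_family == name]
  band <- c(f_min = min(f), f_max = max(f))
  if (name == "Tumor regulation")
    attr(band, "note") <- paste(
      "catalog block starts at 0.027 (Protein A-VHIII) whereas the narrative",
      "band is stated as 0.031-0.054; the catalog coloring is followed")
  band
}

#' Histogram of functional groups by frequency bin
#'
#' Counts catalog rows in half-open bins \code{[k*w, (k+1)*w)} across the RRM
#' band \code{[0, 0.5]}, the binning used to visualize the clustering of
#' biological functions. Bins with zero count are included. When two rows
#' share a frequency (0.0820, 0.4922) each row is counted.
#'
#' @param catalog an \code{rrm_catalog} (or any data frame with an
#'   \code{rrm_frequency} column).
#' @param bin_width bin width, > 0 (default 0.01).
#' @return Data frame with columns \code{bin_start}, \code{count}; counts sum
#'   to \code{nrow(catalog)}.
#' @export
frequency_histogram <- function(catalog = load_catalog(), bin_width = 0.01) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop_validation("bin_width must be > 0")
  n_bins <- ceiling(0.5 / bin_width - 1e-9)
  starts <- (seq_len(n_bins) - 1) * bin_width
  idx <- findInterval(catalog$rrm_frequency, c(starts, n_bins * bin_width + 1e-9))
  count <- tabulate(idx, nbins = length(starts))
  data.frame(bin_start = starts, count = count)
}
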