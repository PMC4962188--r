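#' Run configuration
#'
#' Collects every tunable parameter of the analysis pipeline in one validated
#' record. Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... named overrides of the defaults: \code{scale} ("eiip_protein"),
#'   \code{n_points} (512), \code{min_snr} (20), \code{classify_tolerance}
#'   (0.004), \code{K} (201), \code{charge_velocity} (7.87e5),
#'   \code{residue_spacing} (3.8e-10), \code{coverage_threshold} (0.05),
#'   \code{half_band_nm} (10), \code{water_window} (c(380, 750)),
#'   \code{out_dir} ("."), \code{log_level} ("info"), \code{seed} (42).
#' @return An object of class \code{rrm_config} (named list).
#' @export
rrm_config <- function(...) {
  defaults <- list(
    scale = "eiip_protein", n_points = 512, min_snr = 20,
    classify_tolerance = 0.004, K = 201, charge_velocity = 7.87e5,
    residue_spacing = 3.8e-10, coverage_threshold = 0.05, half_band_nm = 10,
    water_window = c(380, 750), out_dir = ".", log_level = "info", seed = 42)
  override <- list(...)
  if (length(override) && (is.null(names(override)) || any(names(override) == "")))
    stop_validation("all config overrides must be named")
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, override)
  if (cfg$n_points < 8 || cfg$n_points %% 2 != 0)
    stop_validation("n_points must be an even integer >= 8")
  if (cfg$min_snr < 0) stop_validation("min_snr must be >= 0")
  if (cfg$classify_tolerance < 0) stop_validation("classify_tolerance must be >= 0")
  if (cfg$coverage_threshold <= 0 || cfg$coverage_threshold >= 1)
    stop_validation("coverage_threshold must lie in (0, 1)")
  rrm_constants(cfg$K, cfg$charge_velocity, cfg$residue_spacing)  # validates
  if (length(cfg$water_window) != 2 || cfg$water_window[1] >= cfg$water_window[2])
    stop_validation("water_window must be c(min, max) with min < max")
  if (!cfg$log_level %in% c("quiet", "info", "debug"))
    stop_validation("log_level must be quiet, info or debug")
  structure(cfg, class = "rrm_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose keys are [rrm_config()] parameters.
#' @return An \code{rrm_config}.
#' @export
read_rrm_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rrm_config, as.list(vals))
}

#' @export
print.rrm_config <- function(x, ...) {
  cat("<rrm_config>\n")
  for (k in names(unclass(x)))
    cat(sprintf("  %-19s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

config_constants <- function(config) {
  rrm_constants(config$K, config$charge_velocity, config$residue_spacing)
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]])
    message(sprintf(fmt, ...))
}

#' End-to-end group analysis of a FASTA file
#'
#' The full RRM pipeline on one functional group: read the multi-record FASTA,
#' encode every sequence under the configured potential scale, compute
#' individual amplitude spectra on a common grid, form the multiplicative
#' consensus spectrum, call the consensus peak against the configured
#' signal-to-noise threshold, map the called frequency to a wavelength via
#' \eqn{\lambda = K/f}, and classify it against the characteristic-frequency
#' catalog.
#'
#' When \code{config$out_dir} is non-\code{NULL} the following files are
#' written there: \code{spectrum_<id>.csv} per sequence,
#' \code{consensus.csv}, \code{peak.json} (the peak call, or an explicit
#' no-peak record), and \code{classification.csv}. The constants record is
#' logged on every run, since results are meaningless without it.
#'
#' @param fasta path to a FASTA file with >= 2 records.
#' @param config an [rrm_config()].
#' @return An invisible list with \code{series}, \code{spectra},
#'   \code{consensus}, \code{peak} (\code{rrm_peak} or \code{NULL}),
#'   \code{wavelength_nm} (or \code{NA}), \code{classification} (catalog
#'   subset), \code{constants}, \code{config}.
#' @export
run_group_analysis <- function(fasta, config = rrm_config()) {
  stopifnot(inherits(config, "rrm_config"))
  seqs <- read_fasta(fasta)
  if (length(seqs) < 2)
    stop_validation(sprintf("group analysis needs >= 2 FASTA records, got %d",
                            length(seqs)))
  constants <- config_constants(config)
  log_msg(config, "info", "constants: K = %g nm, v = %g m/s, d = %g m",
          constants$K, constants$charge_velocity, constants$residue_spacing)
  scale <- load_scale(config$scale)
  series <- Map(function(s, id) encode_sequence(s, scale, source_id = id),
                seqs, names(seqs))
  spectra <- lapply(series, amplitude_spectrum, n_points = config$n_points)
  consensus <- cross_spectrum(unname(spectra))
  peak <- find_consensus_peak(consensus, min_snr = config$min_snr)
  lambda <- if (is.null(peak)) NA_real_
            else rrm_to_wavelength(peak$frequency, constants)
  classification <- if (is.null(peak)) NULL
                    else classify_frequency(peak$frequency,
                                            config$classify_tolerance)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in spectra)
      write_spectrum_csv(sp, file.path(config$out_dir,
                                       sprintf("spectrum_%s.csv", sp$source_id)))
    write_spectrum_csv(consensus, file.path(config$out_dir, "consensus.csv"))
    peak_rec <- if (is.null(peak)) {
      list(peak_found = FALSE,
           reason = sprintf("no consensus peak with S/N >= %g", config$min_snr))
    } else {
      list(peak_found = TRUE, frequency = peak$frequency,
           amplitude = peak$amplitude, snr = peak$snr, wavelength_nm = lambda)
    }
    jsonlite::write_json(peak_rec, file.path(config$out_dir, "peak.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(classification))
      utils::write.csv(classification,
                       file.path(config$out_dir, "classification.csv"),
                       row.names = FALSE)
    log_msg(config, "info", "results written to %s", config$out_dir)
  }
  if (is.null(peak))
    log_msg(config, "info", "no consensus peak with S/N >= %g", config$min_snr)
  else
    log_msg(config, "info", "peak at f = %.6g (S/N %.1f) -> %.0f nm",
            peak$frequency, peak$snr, lambda)
  invisible(list(series = series, spectra = spectra, consensus = consensus,
                 peak = peak, wavelength_nm = lambda,
                 classification = classification, constants = constants,
                 config = config))
}
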