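#' Residue electron-potential scales
#'
#' The Resonant Recognition Model (RRM) renders a sequence numerical by
#' replacing each residue with a physical parameter for the energy of its
#' delocalized electrons, conventionally the electron-ion interaction
#' potential (EIIP). Two scales are bundled with the package:
#' \code{"eiip_protein"} (20 amino acids) and \code{"eiip_dna"} (4
#' nucleotides), both carrying their literature citation. Any other scale can
#' be supplied as a two-column CSV with header \code{residue,value}.
#'
#' A scale is valid only if every canonical residue of its alphabet has a
#' finite, non-negative value; \code{load_scale()} enforces this and names the
#' missing residues on failure.
#'
#' @param identifier name of a bundled scale (\code{"eiip_protein"},
#'   \code{"eiip_dna"}) or path to a readable CSV file.
#' @return An object of class \code{rrm_scale}: a list with elements
#'   \code{name}, \code{alphabet} (\code{"protein"} or \code{"dna"}),
#'   \code{values} (named numeric vector) and \code{source} (citation string).
#' @examples
#' sc <- load_scale("eiip_protein")
#' sc$values[["W"]]
#' @export
load_scale <- function(identifier) {
  bundled <- c("eiip_protein", "eiip_dna")
  if (identifier %in% bundled) {
    path <- system.file("extdata", "scales", paste0(identifier, ".csv"),
                        package = "rrmtools", mustWork = TRUE)
  } else if (file.exists(identifier)) {
    path <- identifier
  } else {
    stop_not_found(sprintf(
      "unknown scale '%s': not a bundled scale (%s) and not a readable file",
      identifier, paste(bundled, collapse = ", ")))
  }
  lines <- readLines(path)
  src <- sub("^#\\s?", "", grep("^#", lines, value = TRUE))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab)))
    stop_validation(sprintf("scale file '%s' must have header 'residue,value'", path))
  vals <- stats::setNames(as.numeric(tab$value), toupper(trimws(tab$residue)))
  alphabet <- if (setequal(names(vals), DNA_ALPHABET)) "dna" else "protein"
  new_rrm_scale(
    name = if (identifier %in% bundled) identifier else basename(path),
    alphabet = alphabet, values = vals,
    source = if (length(src)) paste(src, collapse = " ") else paste("user file:", path)
  )
}

PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_ALPHABET <- c("A", "C", "G", "T")

canonical_alphabet <- function(alphabet) {
  switch(alphabet, protein = PROTEIN_ALPHABET, dna = DNA_ALPHABET,
         stop_validation(sprintf("unknown alphabet '%s'", alphabet)))
}

#' Construct a residue scale
#'
#' Low-level constructor validating the \code{rrm_scale} invariants: complete
#' coverage of the canonical alphabet with finite, non-negative values.
#'
#' @param name scale label.
#' @param alphabet \code{"protein"} or \code{"dna"}.
#' @param values named numeric vector, residue letter to potential.
#' @param source citation string.
#' @return An \code{rrm_scale} object.
#' @export
new_rrm_scale <- function(name, alphabet, values, source = "") {
  canon <- canonical_alphabet(alphabet)
  missing <- setdiff(canon, names(values))
  if (length(missing))
    stop_validation(sprintf("scale '%s' is missing canonical residue(s): %s",
                            name, paste(missing, collapse = ", ")))
  if (any(!is.finite(values)))
    stop_validation(sprintf("scale '%s' has non-finite values", name))
  if (any(values < 0))
    stop_validation(sprintf("scale '%s' has negative values", name))
  structure(list(name = name, alphabet = alphabet,
                 values = values[order(names(values))], source = source),
            class = "rrm_scale")
}

#' @export
print.rrm_scale <- function(x, ...) {
  cat(sprintf("<rrm_scale> %s (%s, %d residues)\n", x$name, x$alphabet,
              length(x$values)))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Encode a sequence as a numerical potential series
#'
#' Maps each residue of \code{sequence} to its value under \code{scale},
#' producing the energy-of-delocalized-electrons series that all RRM spectral
#' analysis operates on. Input is case-insensitive; in DNA mode \code{U} is
#' read as \code{T} so RNA sequences encode directly.
#'
#' Residues absent from the scale (ambiguity codes such as \code{X}, \code{B},
#' \code{Z}, or \code{N} for DNA) are handled by \code{policy}:
#' \code{"strict"} (default) raises an error naming the first offending
#' position, \code{"skip"} drops them, \code{"zero"} substitutes 0. Strict is
#' the default because silent substitution changes the spectrum.
#'
#' @param sequence non-empty residue string (or character vector of single
#'   letters).
#' @param scale an \code{rrm_scale}, see [load_scale()].
#' @param policy one of \code{"strict"}, \code{"skip"}, \code{"zero"}.
#' @param source_id label recorded on the resulting series.
#' @return An object of class \code{rrm_series}: list with \code{values},
#'   \code{length}, \code{source_id}.
#' @examples
#' sc <- load_scale("eiip_protein")
#' encode_sequence("MKV", sc)
#' @export
encode_sequence <- function(sequence, scale,
                            policy = c("strict", "skip", "zero"),
                            source_id = "seq") {
  policy <- match.arg(policy)
  stopifnot(inherits(scale, "rrm_scale"))
  if (length(sequence) == 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (!length(sequence)) stop_validation("sequence is empty")
  letters <- toupper(sequence)
  if (scale$alphabet == "dna") letters[letters == "U"] <- "T"
  known <- letters %in% names(scale$values)
  if (!all(known)) {
    if (policy == "strict") {
      i <- which(!known)[1]
      stop_validation(sprintf(
        "residue '%s' at position %d is not in scale '%s' (policy = strict)",
        letters[i], i, scale$name))
    } else if (policy == "skip") {
      letters <- letters[known]
      if (!length(letters))
        stop_validation("all residues dropped under policy = skip")
      known <- rep(TRUE, length(letters))
    }
  }
  vals <- numeric(length(letters))
  vals[known] <- unname(scale$values[letters[known]])
  new_rrm_series(vals, source_id = source_id)
}

#' Construct a numerical series
#'
#' @param values finite numeric vector, one potential per residue.
#' @param source_id label of the originating sequence.
#' @return An \code{rrm_series} object.
#' @export
new_rrm_series <- function(values, source_id = "series") {
  values <- as.numeric(values)
  if (!length(values)) stop_validation("series must be non-empty")
  if (any(!is.finite(values))) stop_validation("series has non-finite values")
  structure(list(values = values, length = length(values),
                 source_id = source_id), class = "rrm_series")
}

#' @export
print.rrm_series <- function(x, ...) {
  cat(sprintf("<rrm_series> '%s', length %d\n", x$source_id, x$length))
  invisible(x)
}

#' @export
length.rrm_series <- function(x) x$length

#' Read a multi-record FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} returning plain
#' character sequences named by record ID (description after the first
#' whitespace is dropped, as is conventional).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_io(sprintf(
                    "failed to parse FASTA '%s': %s", path, conditionMessage(e))))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
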