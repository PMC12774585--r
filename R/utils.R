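# Internal helpers: coordinates, sequence arithmetic, conditions.
#
# Coordinate convention used throughout the package: 0-based, half-open,
# plus-strand genomic intervals [start, end). Strand is applied only when a
# sequence is extracted. GFF3 (1-based, inclusive) is converted at the
# parser boundary and nowhere else.

#' Convert GFF3 coordinates to the internal convention
#'
#' GFF3 intervals are 1-based and inclusive; internally the package uses
#' 0-based half-open intervals. These two helpers are exact inverses.
#'
#' @param start,end Integer vectors of interval bounds.
#' @return A two-column integer matrix with columns `start` and `end`.
#' @export
gffToInternal <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname gffToInternal
#' @export
internalToGff <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

# condition constructors ----------------------------------------------------

.cdCondition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "crisprDonorError", "error", "condition"),
    list(message = message, call = call)
  )
}

.cdStop <- function(class, fmt, ...) {
  stop(.cdCondition(class, sprintf(fmt, ...), call = sys.call(-1)))
}

.formatError     <- function(fmt, ...) .cdStop("formatError", fmt, ...)
.annotationError <- function(fmt, ...) .cdStop("annotationError", fmt, ...)
.rangeError      <- function(fmt, ...) .cdStop("rangeError", fmt, ...)
.inputError      <- function(fmt, ...) .cdStop("inputError", fmt, ...)
.configError     <- function(fmt, ...) .cdStop("configError", fmt, ...)
.vectorError     <- function(fmt, ...) .cdStop("vectorError", fmt, ...)
.designError     <- function(fmt, ...) .cdStop("designError", fmt, ...)

.cdWarn <- function(fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = "crisprDonorWarning"))
}

# sequence helpers ----------------------------------------------------------

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()]; `N` is preserved.
#'
#' @param x A character vector of DNA strings (alphabet ACGTN).
#' @return A character vector of the same length.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  out
}

# Translate a DNA string with the standard code; returns an amino-acid
# string, '*' for stops. Length must be a multiple of 3.
.translateDna <- function(x) {
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

# Single-codon lookup used by the silent-mutation search (faster and with
# clearer failure modes than constructing a DNAString per codon).
.codonToAa <- local({
  code <- NULL
  function(codon) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    aa <- code[[codon]]
    if (is.null(aa)) .inputError("not a codon: '%s'", codon)
    aa
  }
})

.isDnaAcgt <- function(x) {
  !grepl("[^ACGT]", x)
}

.isDnaAcgtn <- function(x) {
  !grepl("[^ACGTN]", x)
}

# All (overlapping) 0-based start offsets of fixed pattern `pat` in `s`.
.findAll <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Longest homopolymer run length in a sequence.
.maxHomopolymer <- function(x) {
  r <- rle(strsplit(x, "")[[1]])
  if (length(r$lengths) == 0L) 0L else max(r$lengths)
}

# Deterministic seeded evaluation that does not disturb the caller's RNG.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random open reading frame body of `n_codons` sense codons (no ATG
# requirement, no stop codons).
.randomOrf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T"), stringsAsFactors = FALSE),
                  1L, paste, collapse = "")
  sense <- setdiff(codons, stops)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
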