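# S4 classes for the design pipeline.

setOldClass("data.frame")

# A feature table is an ordinary data.frame with columns
#   start, end   : integer, 0-based half-open
#   strand       : "+" or "-"
#   type         : GenBank feature key (misc_feature, CDS, primer_bind, ...)
#   label        : short display label (Ape-style /label qualifier)
#   note         : free-text /note qualifier ("" if absent)
.emptyFeatures <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             type = character(0), label = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

.feature <- function(start, end, strand, type, label, note = "") {
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = strand, type = type, label = label, note = note,
             stringsAsFactors = FALSE)
}

.checkFeatures <- function(df, seqlen, topology = "linear") {
  need <- c("start", "end", "strand", "type", "label", "note")
  if (!all(need %in% names(df)))
    return(sprintf("feature table must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return(NULL)
  if (any(df$start < 0L) || any(df$end < df$start))
    return("feature intervals must satisfy 0 <= start <= end")
  if (any(df$end > seqlen))
    return("feature interval exceeds sequence bounds")
  if (!all(df$strand %in% c("+", "-")))
    return("feature strand must be '+' or '-'")
  NULL
}

#' GenomeAssembly: a set of named contig sequences
#'
#' Wraps a [Biostrings::DNAStringSet] restricted to the alphabet
#' A/C/G/T/N, with unique contig names. All package coordinates are
#' 0-based half-open positions on the plus strand of these contigs.
#'
#' @slot sequences A `DNAStringSet`, one entry per contig.
#' @export
setClass("GenomeAssembly", representation(sequences = "DNAStringSet"))

setValidity("GenomeAssembly", function(object) {
  s <- object@sequences
  nm <- names(s)
  if (is.null(nm) || any(!nzchar(nm))) return("every contig must be named")
  if (anyDuplicated(nm)) return("contig names must be unique")
  if (any(Biostrings::width(s) == 0L)) return("empty contig sequence")
  freq <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T", "N"))
  if (any(rowSums(freq) != Biostrings::width(s)))
    return("contig sequences must use only A, C, G, T, N")
  TRUE
})

#' IsoformModel: one transcript's exon/CDS structure
#'
#' Coordinates are internal (0-based half-open, plus strand). `startCodon`
#' is the genomic position of the first CDS base (for minus-strand genes
#' this is the numerically largest CDS base); `stopCodon` is the genomic
#' position of the first base of the stop codon in transcript order. The
#' CDS includes the stop codon.
#'
#' @slot isoformId Transcript identifier.
#' @slot strand `"+"` or `"-"` (copied from the gene for convenience).
#' @slot contig Contig name.
#' @slot exons,cds Two-column integer matrices (`start`, `end`), sorted in
#'   genomic order, non-overlapping.
#' @slot startCodon,stopCodon Integer genomic positions (see above).
#' @export
setClass("IsoformModel", representation(
  isoformId = "character", contig = "character", strand = "character",
  exons = "matrix", cds = "matrix",
  startCodon = "integer", stopCodon = "integer"))

setValidity("IsoformModel", function(object) {
  cds <- object@cds
  if (nrow(cds) == 0L) return("isoform has no CDS")
  if (any(cds[, 2] < cds[, 1])) return("malformed CDS interval")
  if (is.unsorted(cds[, 1], strictly = TRUE) && nrow(cds) > 1L)
    return("CDS intervals must be sorted in genomic order")
  if (nrow(cds) > 1L && any(cds[-1L, 1] < cds[-nrow(cds), 2]))
    return("CDS intervals must not overlap")
  if (sum(cds[, 2] - cds[, 1]) %% 3L != 0L)
    return("total CDS length must be a multiple of 3")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

#' GeneModel: a gene locus and its isoforms
#'
#' @slot geneId,symbol Identifiers from the annotation.
#' @slot contig,strand Location; all isoforms share both.
#' @slot isoforms A list of [IsoformModel-class] objects (at least one).
#' @export
setClass("GeneModel", representation(
  geneId = "character", symbol = "character",
  contig = "character", strand = "character", isoforms = "list"))

setValidity("GeneModel", function(object) {
  if (length(object@isoforms) < 1L) return("gene must have >= 1 isoform")
  ok <- vapply(object@isoforms, function(i) is(i, "IsoformModel"), logical(1))
  if (!all(ok)) return("isoforms must be IsoformModel objects")
  same <- vapply(object@isoforms, function(i)
    i@contig == object@contig && i@strand == object@strand, logical(1))
  if (!all(same)) return("all isoforms must share the gene's contig and strand")
  TRUE
})

#' EfficiencyMatrix: position-weight guide efficiency model
#'
#' A 20 x 4 table of finite weights indexed by protospacer position
#' (1..20, PAM-distal to PAM-proximal) and base (A, C, G, T). The score of
#' a protospacer is the sum of the weights of its bases. This is a
#' configurable plug-in; the default matrix shipped with the package is a
#' synthetic stand-in (see its provenance header).
#'
#' @slot weights Numeric 20 x 4 matrix, columns named A, C, G, T.
#' @slot name,provenance Free-text identification of the matrix.
#' @export
setClass("EfficiencyMatrix", representation(
  weights = "matrix", name = "character", provenance = "character"))

setValidity("EfficiencyMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != 20L || ncol(w) != 4L)
    return("weights must be a numeric 20 x 4 matrix")
  if (!identical(colnames(w), c("A", "C", "G", "T")))
    return("weight columns must be named A, C, G, T")
  if (any(!is.finite(w))) return("weights must all be finite")
  TRUE
})

#' AssemblyMap: an annotated sequence record
#'
#' The unit of all pipeline outputs; serializable to a GenBank flat file
#' and parseable back with sequence, topology and features preserved.
#'
#' @slot name Record name (GenBank LOCUS).
#' @slot sequence Uppercase DNA string.
#' @slot topology `"linear"` or `"circular"`.
#' @slot features Feature data.frame (see [writeGenbank()]).
#' @slot provenance Character vector of free-text notes (GenBank COMMENT).
#' @slot metadata Arbitrary list of bookkeeping values (offset tables,
#'   insertion points); not serialized to GenBank.
#' @export
setClass("AssemblyMap", representation(
  name = "character", sequence = "character", topology = "character",
  features = "data.frame", provenance = "character", metadata = "list"))

setValidity("AssemblyMap", function(object) {
  if (!object@topology %in% c("linear", "circular"))
    return("topology must be 'linear' or 'circular'")
  if (!.isDnaAcgtn(object@sequence))
    return("sequence must use only A, C, G, T, N")
  msg <- .checkFeatures(object@features, nchar(object@sequence))
  if (!is.null(msg)) return(msg)
  TRUE
})

#' VectorTemplate: an annotated cloning backbone
#'
#' A circular vector with bookkeeping spans: where homology arms are
#' inserted, where the payload cassette and the screening marker sit, and
#' where the LoxP sites are. Spans are 0-based half-open intervals on the
#' stored (origin-rotated, non-wrapping) sequence.
#'
#' @slot name Vector name.
#' @slot sequence Circular DNA sequence (stored rotated so no annotated
#'   feature wraps the origin).
#' @slot features Feature data.frame.
#' @slot leftArmSlot,rightArmSlot Length-2 integer vectors, possibly
#'   zero-length intervals, where arms are inserted.
#' @slot cassetteSpan,markerSpan Length-2 integer vectors (may be `c(0L,0L)`
#'   when absent, e.g. the guide vector has no marker).
#' @slot loxpSpans 2 x 2 integer matrix (rows = the two LoxP sites), or a
#'   0-row matrix when the vector carries none.
#' @slot frameOffset Integer 0..2, reading-frame register of the cassette
#'   fusion junction.
#' @slot kind `"tagN"`, `"tagC"`, `"deletion"`, or `"guide"`.
#' @export
setClass("VectorTemplate", representation(
  name = "character", sequence = "character", features = "data.frame",
  leftArmSlot = "integer", rightArmSlot = "integer",
  cassetteSpan = "integer", markerSpan = "integer",
  loxpSpans = "matrix", frameOffset = "integer", kind = "character"))

setValidity("VectorTemplate", function(object) {
  n <- nchar(object@sequence)
  msg <- .checkFeatures(object@features, n)
  if (!is.null(msg)) return(msg)
  if (!object@kind %in% c("tagN", "tagC", "deletion", "guide"))
    return("kind must be tagN, tagC, deletion or guide")
  lox <- object@loxpSpans
  if (nrow(lox) == 2L) {
    len <- lox[, 2] - lox[, 1]
    if (any(len != 34L)) return("LoxP spans must be 34 bp")
    s1 <- substr(object@sequence, lox[1, 1] + 1L, lox[1, 2])
    s2 <- substr(object@sequence, lox[2, 1] + 1L, lox[2, 2])
    if (!identical(s1, s2))
      return("the two LoxP sites must be sequence-identical (same orientation)")
    mk <- object@markerSpan
    if (mk[2] > mk[1] && !(mk[1] >= lox[1, 2] && mk[2] <= lox[2, 1]))
      return("marker span must lie between the LoxP spans")
  } else if (nrow(lox) != 0L) {
    return("loxpSpans must have 0 or 2 rows")
  }
  if (object@kind %in% c("tagN", "tagC")) {
    cs <- object@cassetteSpan
    if (cs[2] <= cs[1]) return("tagging template must have a cassette span")
    cass <- substr(object@sequence, cs[1] + 1L, cs[2])
    reg <- object@frameOffset
    body <- substr(cass, reg + 1L, reg + 3L * ((nchar(cass) - reg) %/% 3L))
    aa <- .translateDna(body)
    if (grepl("\\*", aa))
      return("cassette must translate without internal stop in its register")
  }
  TRUE
})

# show methods --------------------------------------------------------------

setMethod("show", "GenomeAssembly", function(object) {
  s <- object@sequences
  cat(sprintf("GenomeAssembly with %d contig(s), %s bp total\n",
              length(s), format(sum(Biostrings::width(s)), big.mark = ",")))
  for (i in seq_len(min(length(s), 6L)))
    cat(sprintf("  %s: %d bp\n", names(s)[i], Biostrings::width(s)[i]))
  if (length(s) > 6L) cat("  ...\n")
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s) on %s(%s), %d isoform(s): %s\n",
              object@geneId, object@symbol, object@contig, object@strand,
              length(object@isoforms),
              paste(vapply(object@isoforms, function(i) i@isoformId,
                           character(1)), collapse = ", ")))
})

setMethod("show", "IsoformModel", function(object) {
  cat(sprintf(
    "IsoformModel %s [%s(%s)] %d CDS segment(s), CDS %d bp, start %d, stop %d\n",
    object@isoformId, object@contig, object@strand, nrow(object@cds),
    sum(object@cds[, 2] - object@cds[, 1]), object@startCodon,
    object@stopCodon))
})

setMethod("show", "AssemblyMap", function(object) {
  cat(sprintf("AssemblyMap '%s': %d bp %s, %d feature(s)\n", object@name,
              nchar(object@sequence), object@topology,
              nrow(object@features)))
})

setMethod("show", "VectorTemplate", function(object) {
  cat(sprintf("VectorTemplate '%s' (%s): %d bp circular, %d feature(s)\n",
              object@name, object@kind, nchar(object@sequence),
              nrow(object@features)))
})

setMethod("show", "EfficiencyMatrix", function(object) {
  cat(sprintf("EfficiencyMatrix '%s' (20 x 4)\n", object@name))
})

# accessors -----------------------------------------------------------------

#' Accessors for package classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
contigNames <- function(x) names(x@sequences)

#' @rdname accessors
#' @export
contigLengths <- function(x) {
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
}

#' @rdname accessors
#' @export
geneId <- function(x) x@geneId

#' @rdname accessors
#' @export
isoforms <- function(x) x@isoforms

#' @rdname accessors
#' @export
isoformId <- function(x) x@isoformId

#' @rdname accessors
#' @export
cdsIntervals <- function(x) x@cds

#' @rdname accessors
#' @export
startCodon <- function(x) x@startCodon

#' @rdname accessors
#' @export
stopCodon <- function(x) x@stopCodon

#' @rdname accessors
#' @export
mapName <- function(x) x@name

#' @rdname accessors
#' @export
mapSequence <- function(x) x@sequence

#' @rdname accessors
#' @export
mapTopology <- function(x) x@topology

#' @rdname accessors
#' @export
mapFeatures <- function(x) x@features

#' @rdname accessors
#' @export
mapProvenance <- function(x) x@provenance

#' @rdname accessors
#' @export
vectorName <- function(x) x@name

#' @rdname accessors
#' @export
vectorKind <- function(x) x@kind

#' Compare two assembly maps on their serializable content
#'
#' Equality on name, sequence, topology, features (all columns, in order)
#' and provenance; `metadata` is bookkeeping and is ignored, matching what
#' a GenBank round trip preserves.
#'
#' @param a,b [AssemblyMap-class] objects.
#' @return `TRUE` or `FALSE`.
#' @export
sameMap <- function(a, b) {
  identical(a@name, b@name) &&
    identical(a@sequence, b@sequence) &&
    identical(a@topology, b@topology) &&
    isTRUE(all.equal(a@features, b@features, check.attributes = FALSE)) &&
    identical(a@provenance, b@provenance)
}
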