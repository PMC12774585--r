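# FASTA / GFF3 input and region extraction.

#' Read a genome FASTA file into a GenomeAssembly
#'
#' Sequences are uppercased; the alphabet is restricted to A/C/G/T/N.
#' Records with other letters (including IUPAC ambiguity codes other than
#' N), empty records, and malformed headers raise a format error naming
#' the offending record where it can be identified.
#'
#' @param path Path to a FASTA file (multi-record; wrapped or unwrapped
#'   lines).
#' @return A [GenomeAssembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "acgt"), fa)
#' contigLengths(parseFasta(fa))
#' @export
parseFasta <- function(path) {
  if (!file.exists(path)) .formatError("FASTA file not found: %s", path)
  bad <- FALSE
  seqs <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
             error = function(e)
               .formatError("cannot parse FASTA '%s': %s", path,
                            conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w))) {
        bad <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (bad)
    .formatError("record '%s' in '%s' contains non-nucleotide characters",
                 .firstBadFastaRecord(path), path)
  if (length(seqs) == 0L) .formatError("no FASTA records in '%s'", path)
  # first whitespace token of the header is the contig name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(seqs))))
    .formatError("malformed (empty) FASTA header in '%s'", path)
  if (any(Biostrings::width(seqs) == 0L))
    .formatError("empty FASTA record '%s' in '%s'",
                 names(seqs)[Biostrings::width(seqs) == 0L][1], path)
  up <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(up) <- names(seqs)
  freq <- Biostrings::letterFrequency(up, letters = c("A", "C", "G", "T", "N"))
  offending <- rowSums(freq) != Biostrings::width(up)
  if (any(offending))
    .formatError("record '%s' in '%s' contains non-A/C/G/T/N characters",
                 names(up)[offending][1], path)
  if (anyDuplicated(names(up)))
    .formatError("duplicate contig name '%s' in '%s'",
                 names(up)[duplicated(names(up))][1], path)
  methods::new("GenomeAssembly", sequences = up)
}

# Identify the record holding an invalid letter, for error reporting only
# (parsing itself is done by Biostrings).
.firstBadFastaRecord <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- "<unknown>"
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      rec <- sub("\\s.*$", "", sub("^>", "", ln))
    } else if (grepl("[^ACGTNacgtn[:space:]]", ln)) {
      return(rec)
    }
  }
  rec
}

#' Build a GenomeAssembly from in-memory sequences
#'
#' @param sequences Named character vector or `DNAStringSet` of contigs.
#' @return A [GenomeAssembly-class].
#' @export
genomeAssembly <- function(sequences) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  methods::new("GenomeAssembly", sequences = sequences)
}

#' Extract a genomic region
#'
#' Returns the plus-strand substring for `strand = "+"` and its reverse
#' complement for `strand = "-"`. Coordinates are 0-based half-open; the
#' result has exactly `end - start` characters.
#'
#' @param assembly A [GenomeAssembly-class].
#' @param contig Contig name.
#' @param start,end Interval bounds, `0 <= start <= end <= contig length`.
#' @param strand `"+"` (default) or `"-"`.
#' @return A character DNA string.
#' @examples
#' ga <- genomeAssembly(c(chrT = "ACGTT"))
#' extractRegion(ga, "chrT", 0, 5, "-")  # "AACGT"
#' @export
extractRegion <- function(assembly, contig, start, end, strand = "+") {
  stopifnot(is(assembly, "GenomeAssembly"))
  if (!contig %in% contigNames(assembly))
    .rangeError("unknown contig '%s'", contig)
  n <- contigLengths(assembly)[[contig]]
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start || end > n)
    .rangeError("interval [%s, %s) out of bounds for contig '%s' (%d bp)",
                start, end, contig, n)
  if (!strand %in% c("+", "-")) .inputError("strand must be '+' or '-'")
  if (end == start) return("")
  s <- Biostrings::subseq(assembly@sequences[[contig]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Parse GFF3 gene models against an assembly
#'
#' Reads gene/mRNA/CDS rows (via \pkg{rtracklayer}), links CDS to mRNA to
#' gene through `Parent` attributes, converts the 1-based inclusive GFF3
#' coordinates to the internal 0-based half-open convention, and validates
#' every isoform against the genome sequence: total CDS length divisible
#' by 3, spliced CDS beginning with ATG, ending with a stop codon, and
#' free of internal stops. Violations raise an annotation error naming the
#' isoform.
#'
#' @param path Path to a GFF3 file.
#' @param assembly The [GenomeAssembly-class] the coordinates refer to.
#' @return A named list of [GeneModel-class] objects (names = gene IDs).
#' @export
parseGff3 <- function(path, assembly) {
  stopifnot(is(assembly, "GenomeAssembly"))
  if (!file.exists(path)) .formatError("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   .formatError("cannot parse GFF3 '%s': %s", path,
                                conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p)
      if (length(p) == 0L) NA_character_ else as.character(p[1]), character(1))
  } else rep(NA_character_, length(gr))
  seqid <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)

  gix <- which(type == "gene")
  mix <- which(type == "mRNA")
  cix <- which(type %in% c("CDS", "exon"))
  if (length(gix) == 0L) .annotationError("no gene features in '%s'", path)
  geneById <- stats::setNames(gix, ids[gix])

  models <- list()
  for (g in gix) {
    gid <- ids[g]
    if (is.na(gid)) .annotationError("gene feature without ID in '%s'", path)
    sym <- if ("Name" %in% names(md) && !is.na(md$Name[g]))
      as.character(md$Name[g]) else gid
    misx <- mix[parents[mix] == gid & !is.na(parents[mix])]
    if (length(misx) == 0L)
      .annotationError("gene '%s' has no mRNA children", gid)
    isos <- lapply(misx, function(m) {
      mid <- ids[m]
      if (is.na(mid))
        .annotationError("mRNA of gene '%s' lacks an ID", gid)
      if (seqid[m] != seqid[g] || strand[m] != strand[g])
        .annotationError("mRNA '%s' disagrees with gene '%s' on contig/strand",
                         mid, gid)
      kid <- cix[parents[cix] == mid & !is.na(parents[cix])]
      cdsrows <- kid[type[kid] == "CDS"]
      exrows <- kid[type[kid] == "exon"]
      if (length(cdsrows) == 0L)
        .annotationError("isoform '%s' has no CDS rows", mid)
      cds <- gffToInternal(st[cdsrows], en[cdsrows])
      cds <- cds[order(cds[, 1]), , drop = FALSE]
      exons <- if (length(exrows) > 0L) {
        e <- gffToInternal(st[exrows], en[exrows])
        e[order(e[, 1]), , drop = FALSE]
      } else cds
      .buildIsoform(mid, seqid[g], strand[g], exons, cds, assembly)
    })
    models[[gid]] <- methods::new("GeneModel", geneId = gid, symbol = sym,
                                  contig = seqid[g], strand = strand[g],
                                  isoforms = isos)
  }

  # referential integrity: every Parent must resolve to a known ID
  known <- ids[!is.na(ids)]
  dangling <- parents[c(mix, cix)]
  dangling <- dangling[!is.na(dangling) & !(dangling %in% known)]
  if (length(dangling) > 0L)
    .annotationError("GFF3 row with unknown Parent '%s' in '%s'",
                     dangling[1], path)
  models
}

.buildIsoform <- function(mid, contig, strand, exons, cds, assembly) {
  total <- sum(cds[, 2] - cds[, 1])
  if (total %% 3L != 0L)
    .annotationError("isoform '%s': CDS length %d not divisible by 3",
                     mid, total)
  spliced <- splicedCds(assembly, contig, strand, cds)
  if (substr(spliced, 1L, 3L) != "ATG")
    .annotationError("isoform '%s': spliced CDS does not start with ATG", mid)
  aa <- .translateDna(spliced)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    .annotationError("isoform '%s': spliced CDS does not end with a stop codon",
                     mid)
  if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
    .annotationError("isoform '%s': internal stop codon in spliced CDS", mid)
  if (strand == "+") {
    startPos <- cds[1L, 1L]
    stopPos <- cds[nrow(cds), 2L] - 3L
  } else {
    startPos <- cds[nrow(cds), 2L] - 1L
    stopPos <- cds[1L, 1L] + 2L
  }
  methods::new("IsoformModel", isoformId = mid, contig = contig,
               strand = strand, exons = exons, cds = cds,
               startCodon = as.integer(startPos),
               stopCodon = as.integer(stopPos))
}

#' Spliced, strand-corrected CDS sequence
#'
#' Concatenates `extractRegion` over the CDS intervals in transcription
#' order (genomic order for plus-strand genes, reverse for minus).
#'
#' @param assembly A [GenomeAssembly-class].
#' @param contig,strand Location of the gene.
#' @param cds Two-column internal-coordinate matrix of CDS intervals in
#'   genomic order.
#' @return The coding sequence as a character string, 5' to 3'.
#' @export
splicedCds <- function(assembly, contig, strand, cds) {
  parts <- vapply(seq_len(nrow(cds)), function(i)
    extractRegion(assembly, contig, cds[i, 1], cds[i, 2], strand),
    character(1))
  if (strand == "-") parts <- rev(parts)
  paste(parts, collapse = "")
}
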