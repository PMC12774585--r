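# Built-in vector templates and conversion between AssemblyMap and
# VectorTemplate.
#
# The true sequences of the pHD tagging/deletion backbones are not
# public, so the built-in templates use synthetic stand-in sequences
# with the correct feature topology: arm slots flanked by the documented
# restriction sites, an SspB/linker/fluorophore fusion cassette, a
# floxable 3xP3-DsRed screening marker between two identical LoxP
# sites, and (for the guide vector) a U6 promoter with a BbsI golden-
# gate slot in front of the gRNA scaffold. Every record is labeled as a
# synthetic stand-in. Users can substitute real GenBank files.

.LOXP <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"   # canonical 34-mer
# The 34-mer reads stop-free only when codons start at its first base;
# 34 = 1 (mod 3), so a fixed 2-nt spacer on the payload side of the LoxP
# pair brings the residual insert after floxing to a multiple of 3. The
# carry codon across the junction reads T + CC = Ser.
.LOX_SPACER <- "CC"
.SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACT",
                    "TGAAAAAGTGGCACCGAGTCGGTGC")
.RESITES <- c(NdeI = "CATATG", PmeI = "GTTTAAAC", MluI = "ACGCGT",
              EcoRI = "GAATTC", NotI = "GCGGCCGC", AscI = "GGCGCGCC",
              XhoI = "CTCGAG", SrfI = "GCCCGGGC", BglII = "AGATCT")

# Random filler free of BbsI recognition sequences (either strand).
.filler <- function(n) {
  s <- .randomDna(n)
  while (grepl("GAAGAC", s, fixed = TRUE) || grepl("GTCTTC", s, fixed = TRUE)) {
    s <- sub("GAAGAC", "GAAGAA", s, fixed = TRUE)
    s <- sub("GTCTTC", "GTCTTG", s, fixed = TRUE)
  }
  s
}

# sequential record builder: accumulates sequence parts and features
.newBuild <- function() {
  env <- new.env()
  env$seq <- character(0); env$feat <- list(); env$pos <- 0L
  env
}

.addPart <- function(b, seqchr, type = NA, label = NA, note = "",
                     strand = "+") {
  n <- nchar(seqchr)
  if (!is.na(type) && n > 0L)
    b$feat[[length(b$feat) + 1L]] <-
      .feature(b$pos, b$pos + n, strand, type, label, note)
  b$seq <- c(b$seq, seqchr)
  b$pos <- b$pos + n
  invisible(b$pos)
}

.addMark <- function(b, type, label, note = "") {
  # zero-length marker (arm slots): recorded as a feature of width 0 is
  # not representable in GenBank, so slots are stored as 2-bp anchors
  # spanning the slot boundary is avoided; instead we register the
  # position and emit a 0-width entry handled specially below.
  b$feat[[length(b$feat) + 1L]] <-
    .feature(b$pos, b$pos, "+", type, label, note)
  invisible(b$pos)
}

.finishBuild <- function(b, name, topology, provenance) {
  feats <- do.call(rbind, b$feat)
  # GenBank cannot express zero-width locations: widen slot anchors to
  # 1 bp covering the base just before the slot boundary (or after, at
  # position 0); the slot position itself is kept in the note.
  zero <- feats$end == feats$start
  if (any(zero)) {
    at <- feats$start[zero]
    feats$note[zero] <- sprintf("slot_at=%d%s", at,
                                ifelse(nzchar(feats$note[zero]),
                                       paste0("; ", feats$note[zero]), ""))
    feats$start[zero] <- pmax(at - 1L, 0L)
    feats$end[zero] <- feats$start[zero] + 1L
  }
  assemblyMap(name = name, sequence = paste(b$seq, collapse = ""),
              topology = topology, features = feats,
              provenance = provenance)
}

.addSites <- function(b, sites) {
  for (nm in sites)
    .addPart(b, .RESITES[[nm]], "misc_feature", paste0(nm, " site"))
}

# Shared synthetic parts, generated once per session under a fixed seed
# so the built-in templates are deterministic.
.builtinParts <- local({
  parts <- NULL
  function() {
    if (!is.null(parts)) return(parts)
    parts <<- .withSeed(20260101L, {
      list(
        backbone_a = .filler(700L),
        backbone_b = .filler(180L),
        sspb = .randomOrf(113L),                       # 339 nt
        egfp = .randomOrf(240L),                       # 720 nt
        mcherry = .randomOrf(237L),                    # 711 nt
        linker_gs = .randomOrf(15L),                   # 45 nt, in-frame
        marker_prom = .filler(300L),
        dsred = paste0("ATG", .randomOrf(225L), "TAA"),  # 681 nt ORF
        marker_term = .filler(150L),
        attp = .filler(50L),
        u6 = .filler(250L),
        stuffer = .filler(20L))
    })
    parts
  }
})

.markerParts <- function(b) {
  p <- .builtinParts()
  start <- b$pos
  .addPart(b, p$marker_prom, "promoter", "3xP3 promoter",
           "synthetic stand-in")
  .addPart(b, p$dsred, "CDS", "DsRed", "synthetic stand-in ORF")
  .addPart(b, p$marker_term, "terminator", "terminator",
           "synthetic stand-in")
  c(start, b$pos)
}

.cassetteNote <- function(kind)
  sprintf("kind=%s; frame_offset=0; synthetic stand-in fusion cassette", kind)

# Build one pHD tagging template as an annotated AssemblyMap.
.buildTaggingTemplate <- function(fluor = c("EGFP", "mCherry"),
                                  terminus = c("N", "C")) {
  fluor <- match.arg(fluor); terminus <- match.arg(terminus)
  p <- .builtinParts()
  fp <- if (fluor == "EGFP") p$egfp else p$mcherry
  kind <- if (terminus == "N") "tagN" else "tagC"
  name <- if (terminus == "N")
    sprintf("pHD-SspB-ExLK-%s-DsRed", fluor) else
    sprintf("pHD-%s-ExLK-SspB-DsRed", fluor)
  b <- .newBuild()
  .addPart(b, p$backbone_a, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  if (terminus == "N") {
    .addSites(b, c("EcoRI", "NotI", "NdeI"))
    .addMark(b, "misc_feature", "HA_left_slot")
    cstart <- b$pos
    .addPart(b, p$sspb, "CDS", "SspB(R73Q)", "synthetic stand-in ORF")
    .addPart(b, paste0(.RESITES[["MluI"]], p$linker_gs), "misc_feature",
             "ExLK linker", "extended flexible linker; in-frame MluI")
    .addPart(b, fp, "CDS", fluor, "synthetic stand-in ORF")
    cend <- b$pos
    .addPart(b, .LOXP, "misc_feature", "loxP")
    mk <- .markerParts(b)
    .addPart(b, .LOXP, "misc_feature", "loxP")
    .addPart(b, .LOX_SPACER, "misc_feature", "frame spacer",
             "keeps residual insert in frame after floxing")
    .addMark(b, "misc_feature", "HA_right_slot")
    .addSites(b, c("AscI", "XhoI", "PmeI"))
  } else {
    .addSites(b, c("SrfI", "EcoRI", "NotI"))
    .addMark(b, "misc_feature", "HA_left_slot")
    .addPart(b, .LOXP, "misc_feature", "loxP")
    mk <- .markerParts(b)
    .addPart(b, .LOXP, "misc_feature", "loxP")
    .addPart(b, .LOX_SPACER, "misc_feature", "frame spacer",
             "keeps residual insert in frame after floxing")
    cstart <- b$pos
    .addPart(b, fp, "CDS", fluor, "synthetic stand-in ORF")
    .addPart(b, paste0(.RESITES[["MluI"]], p$linker_gs), "misc_feature",
             "ExLK linker", "extended flexible linker; in-frame MluI")
    .addPart(b, p$sspb, "CDS", "SspB(R73Q)", "synthetic stand-in ORF")
    cend <- b$pos
    .addMark(b, "misc_feature", "HA_right_slot")
    .addSites(b, c("BglII", "XhoI", "PmeI"))
  }
  .addPart(b, p$backbone_b, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  # whole-record bookkeeping feature carrying kind + cassette register
  b$feat <- c(list(.feature(0L, b$pos, "+", "source", name,
                            .cassetteNote(kind))), b$feat)
  m <- .finishBuild(b, name, "circular",
                    provenance = sprintf(
                      "synthetic stand-in %s-terminal tagging vector (%s)",
                      terminus, fluor))
  m@metadata <- list(cassette = c(cstart, cend), marker = mk)
  m
}

.buildDeletionTemplate <- function(attp = FALSE) {
  p <- .builtinParts()
  name <- if (attp) "pHD-DsRed-attP" else "pHD-DsRed"
  b <- .newBuild()
  .addPart(b, p$backbone_a, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  .addSites(b, c("EcoRI", "NotI"))
  .addMark(b, "misc_feature", "HA_left_slot")
  cstart <- b$pos
  .addPart(b, .LOXP, "misc_feature", "loxP")
  mk <- .markerParts(b)
  .addPart(b, .LOXP, "misc_feature", "loxP")
  if (attp) .addPart(b, p$attp, "misc_feature", "attP",
                     "synthetic stand-in landing site")
  cend <- b$pos
  .addMark(b, "misc_feature", "HA_right_slot")
  .addSites(b, c("AscI", "XhoI"))
  .addPart(b, p$backbone_b, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  b$feat <- c(list(.feature(0L, b$pos, "+", "source", name,
                            "kind=deletion; synthetic stand-in")), b$feat)
  m <- .finishBuild(b, name, "circular",
                    provenance = "synthetic stand-in deletion vector")
  m@metadata <- list(cassette = c(cstart, cend), marker = mk)
  m
}

.buildGuideTemplate <- function() {
  p <- .builtinParts()
  b <- .newBuild()
  .addPart(b, p$backbone_a, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  .addPart(b, p$u6, "promoter", "U6 promoter", "synthetic stand-in")
  slotStart <- b$pos
  # golden-gate slot: BbsI sites point outward so digestion removes both
  # recognition sequences and exposes GAAG / GTTT overhangs
  .addPart(b, "CTTC", "misc_feature", "BbsI overhang (left)")
  .addPart(b, "AAGTCTTC", "misc_feature", "BbsI", "recognition, bottom strand")
  .addPart(b, p$stuffer, "misc_feature", "stuffer",
           "released by BbsI digestion")
  .addPart(b, "GAAGACAA", "misc_feature", "BbsI", "recognition, top strand")
  slotEnd <- b$pos  # scaffold GTTT doubles as the right overhang
  .addPart(b, .SCAFFOLD, "misc_feature", "gRNA scaffold")
  .addPart(b, "TTTTTTT", "terminator", "U6 terminator")
  .addPart(b, p$backbone_b, "misc_feature", "backbone",
           "synthetic stand-in backbone")
  b$feat <- c(list(.feature(0L, b$pos, "+", "source", "pU6-BbsI-chiRNA",
                            "kind=guide; synthetic stand-in")), b$feat)
  m <- .finishBuild(b, "pU6-BbsI-chiRNA", "circular",
                    provenance = "synthetic stand-in guide RNA vector")
  m@metadata <- list(slot = c(slotStart, slotEnd))
  m
}

#' Construct the built-in templates in code
#'
#' Deterministically rebuilds the seven shipped templates as annotated
#' [AssemblyMap-class] records. Used to generate the packaged GenBank
#' files; [loadBuiltinVectors()] is the user-facing loader.
#'
#' @return Named list of [AssemblyMap-class] objects.
#' @export
makeBuiltinTemplateMaps <- function() {
  maps <- list(
    .buildTaggingTemplate("EGFP", "N"),
    .buildTaggingTemplate("mCherry", "N"),
    .buildTaggingTemplate("EGFP", "C"),
    .buildTaggingTemplate("mCherry", "C"),
    .buildDeletionTemplate(attp = FALSE),
    .buildDeletionTemplate(attp = TRUE),
    .buildGuideTemplate())
  stats::setNames(maps, vapply(maps, mapName, character(1)))
}

# slot position recovery: a slot feature is a 1-bp anchor whose true
# zero-width position is in its note ("slot_at=<pos>").
.slotPosition <- function(feats, label) {
  i <- which(feats$label == label)
  if (length(i) != 1L) return(NULL)
  m <- regmatches(feats$note[i], regexec("slot_at=(\\d+)", feats$note[i]))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else feats$start[i]
}

#' Interpret an annotated map as a VectorTemplate
#'
#' Recognized feature labels: `HA_left_slot` / `HA_right_slot` (required),
#' `cassette` or a pair of CDS features plus linker forming the cassette,
#' an optional `loxP` pair, a marker, and a `source` note
#' `kind=tagN|tagC|deletion|guide`. Custom user vectors need at minimum
#' the two arm-slot labels; kind is inferred when not declared.
#'
#' @param map An [AssemblyMap-class] (e.g. from [readGenbank()]).
#' @return A [VectorTemplate-class].
#' @export
asVectorTemplate <- function(map) {
  stopifnot(is(map, "AssemblyMap"))
  feats <- map@features
  n <- nchar(map@sequence)
  srcNote <- feats$note[feats$type == "source"]
  kind <- NA_character_
  if (length(srcNote) > 0L) {
    m <- regmatches(srcNote[1], regexec("kind=([A-Za-z]+)", srcNote[1]))[[1]]
    if (length(m) == 2L) kind <- m[2]
  }
  frameOffset <- 0L
  if (length(srcNote) > 0L) {
    m <- regmatches(srcNote[1],
                    regexec("frame_offset=(\\d)", srcNote[1]))[[1]]
    if (length(m) == 2L) frameOffset <- as.integer(m[2])
  }
  lox <- feats[feats$label == "loxP", , drop = FALSE]
  loxMat <- if (nrow(lox) > 0L)
    cbind(start = lox$start, end = lox$end) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))

  if (identical(kind, "guide")) {
    return(methods::new("VectorTemplate", name = mapName(map),
                        sequence = map@sequence, features = feats,
                        leftArmSlot = c(0L, 0L), rightArmSlot = c(0L, 0L),
                        cassetteSpan = c(0L, 0L), markerSpan = c(0L, 0L),
                        loxpSpans = loxMat, frameOffset = 0L,
                        kind = "guide"))
  }
  leftAt <- .slotPosition(feats, "HA_left_slot")
  rightAt <- .slotPosition(feats, "HA_right_slot")
  if (is.null(leftAt) || is.null(rightAt))
    .vectorError("vector '%s' lacks HA_left_slot / HA_right_slot features",
                 mapName(map))
  markerRows <- feats[feats$label %in% c("DsRed", "3xP3-DsRed"), ,
                      drop = FALSE]
  markerSpan <- if (nrow(markerRows) > 0L)
    c(min(markerRows$start), max(markerRows$end)) else c(0L, 0L)

  # cassette: explicit label wins; otherwise the fusion CDS/linker block
  cassRows <- feats[feats$label == "cassette", , drop = FALSE]
  if (nrow(cassRows) == 0L)
    cassRows <- feats[feats$label %in%
                        c("SspB(R73Q)", "EGFP", "mCherry", "ExLK linker"), ,
                      drop = FALSE]
  cassetteSpan <- if (nrow(cassRows) > 0L)
    c(min(cassRows$start), max(cassRows$end)) else
    c(as.integer(leftAt), as.integer(rightAt))
  if (is.na(kind)) {
    kind <- if (nrow(cassRows) == 0L) "deletion"
    else if (nrow(loxMat) == 2L && cassetteSpan[1] < loxMat[1, 1]) "tagN"
    else "tagC"
  }
  methods::new("VectorTemplate", name = mapName(map),
               sequence = map@sequence, features = feats,
               leftArmSlot = c(as.integer(leftAt), as.integer(leftAt)),
               rightArmSlot = c(as.integer(rightAt), as.integer(rightAt)),
               cassetteSpan = as.integer(cassetteSpan),
               markerSpan = as.integer(markerSpan),
               loxpSpans = loxMat, frameOffset = frameOffset, kind = kind)
}

#' Load the built-in vector templates
#'
#' Reads the seven shipped GenBank files (four SspB/fluorophore tagging
#' vectors, two DsRed deletion vectors, the U6/BbsI guide vector),
#' converts them to [VectorTemplate-class] objects and validates their
#' invariants.
#'
#' @return Named list of [VectorTemplate-class] objects.
#' @export
loadBuiltinVectors <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- system.file("extdata", "vectors", package = "crisprDonor",
                       mustWork = TRUE)
    files <- sort(list.files(dir, pattern = "\\.gb$", full.names = TRUE))
    if (length(files) != 7L)
      .vectorError("expected 7 built-in vector files, found %d",
                   length(files))
    out <- lapply(files, function(f) {
      tpl <- asVectorTemplate(readGenbank(f))
      methods::validObject(tpl)
      tpl
    })
    cache <<- stats::setNames(out, vapply(out, vectorName, character(1)))
    cache
  }
})

#' Resolve a vector argument to a VectorTemplate
#'
#' Accepts a built-in template name, a path to a GenBank file, or a
#' ready [VectorTemplate-class].
#'
#' @param vector Name, path or template.
#' @return A validated [VectorTemplate-class].
#' @export
resolveVector <- function(vector) {
  if (is(vector, "VectorTemplate")) return(vector)
  stopifnot(is.character(vector), length(vector) == 1L)
  builtins <- loadBuiltinVectors()
  if (vector %in% names(builtins)) return(builtins[[vector]])
  if (file.exists(vector)) {
    tpl <- asVectorTemplate(readGenbank(vector))
    methods::validObject(tpl)
    return(tpl)
  }
  .vectorError("unknown vector '%s' (not a built-in name: %s; not a file)",
               vector, paste(names(builtins), collapse = ", "))
}
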