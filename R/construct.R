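# Donor construction: homology arms, silent PAM mutation, tagging and
# deletion maps, Cre/LoxP simulation, frame validation, guide oligos.

#' Extract homology arms around an insertion point or cut pair
#'
#' For tagging, `at` is a single genomic boundary (the insertion point):
#' the left arm is `arm_length` bases ending there, the right arm
#' `arm_length` bases starting there. For deletion, `at` is the pair of
#' cut positions `c(cut_N, cut_C)`: the left arm ends at the first cut,
#' the right arm starts at the second. Arms are exact plus-strand
#' genomic substrings; an arm running off the contig is shortened with a
#' warning.
#'
#' @param assembly A [GenomeAssembly-class].
#' @param contig Contig name.
#' @param at Integer vector of length 1 (insertion boundary) or 2 (cut
#'   pair).
#' @param arm_length Arm length in bp (default 1000; 0 gives two empty
#'   arms, with a warning).
#' @return List with `left` and `right`, each a list of `sequence`,
#'   `start`, `end`, `clipped`.
#' @export
extractHomologyArms <- function(assembly, contig, at, arm_length = 1000L) {
  at <- as.integer(at)
  arm_length <- as.integer(arm_length)
  if (arm_length < 0L) .inputError("arm_length must be >= 0")
  if (arm_length == 0L) .cdWarn("arm_length 0: arms are empty (degenerate)")
  if (!length(at) %in% 1:2) .inputError("'at' must have length 1 or 2")
  leftEnd <- at[1]
  rightStart <- if (length(at) == 2L) at[2] else at[1]
  if (rightStart < leftEnd) .inputError("cut positions out of order")
  n <- contigLengths(assembly)[[contig]]
  ls <- leftEnd - arm_length
  re <- rightStart + arm_length
  clippedL <- ls < 0L; clippedR <- re > n
  if (clippedL) {
    .cdWarn("left arm shortened to %d bp (contig start)", leftEnd)
    ls <- 0L
  }
  if (clippedR) {
    .cdWarn("right arm shortened to %d bp (contig end)", n - rightStart)
    re <- n
  }
  list(
    left = list(sequence = extractRegion(assembly, contig, ls, leftEnd, "+"),
                start = ls, end = leftEnd, clipped = clippedL),
    right = list(sequence = extractRegion(assembly, contig, rightStart, re, "+"),
                 start = rightStart, end = re, clipped = clippedR))
}

# ---- CDS coordinate arithmetic --------------------------------------------

# transcript-order cumulative CDS interval table
.cdsTable <- function(isoform) {
  cds <- isoform@cds
  if (isoform@strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ,
                                        drop = FALSE]
  len <- cds[, 2] - cds[, 1]
  list(cds = cds, len = len, cum = cumsum(len), strand = isoform@strand)
}

# 0-based transcript index of a genomic position, or NA if non-coding
.cdsLocalIndex <- function(isoform, gpos) {
  tb <- .cdsTable(isoform)
  before <- 0L
  for (k in seq_along(tb$len)) {
    s <- tb$cds[k, 1]; e <- tb$cds[k, 2]
    if (gpos >= s && gpos < e) {
      off <- if (tb$strand == "+") gpos - s else (e - 1L) - gpos
      return(before + off)
    }
    before <- before + tb$len[k]
  }
  NA_integer_
}

# genomic position of a 0-based transcript index
.cdsGenomicPos <- function(isoform, tidx) {
  tb <- .cdsTable(isoform)
  before <- 0L
  for (k in seq_along(tb$len)) {
    if (tidx < before + tb$len[k]) {
      off <- tidx - before
      return(as.integer(if (tb$strand == "+") tb$cds[k, 1] + off
                        else tb$cds[k, 2] - 1L - off))
    }
    before <- before + tb$len[k]
  }
  .rangeError("transcript index %d beyond CDS", tidx)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# ---- silent PAM mutation --------------------------------------------------

# mutable view over genome + arm segments; substitutions allowed only
# inside an arm segment
.armContext <- function(arms, assembly, contig) {
  segs <- lapply(arms, function(a)
    list(start = a$start, end = a$end,
         chars = strsplit(a$sequence, "")[[1]]))
  getBase <- function(gpos) {
    for (s in segs) if (gpos >= s$start && gpos < s$end)
      return(s$chars[gpos - s$start + 1L])
    extractRegion(assembly, contig, gpos, gpos + 1L, "+")
  }
  inArm <- function(gpos) {
    any(vapply(segs, function(s) gpos >= s$start && gpos < s$end,
               logical(1)))
  }
  setBase <- function(gpos, base) {
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      if (gpos >= s$start && gpos < s$end) {
        segs[[i]]$chars[gpos - s$start + 1L] <<- base
        return(invisible(TRUE))
      }
    }
    .rangeError("position %d not inside a homology arm", gpos)
  }
  result <- function() {
    lapply(seq_along(segs), function(i) {
      a <- arms[[i]]
      a$sequence <- paste(segs[[i]]$chars, collapse = "")
      a
    })
  }
  list(getBase = getBase, setBase = setBase, inArm = inArm,
       result = result)
}

# plus-strand genomic positions whose mutation disrupts the PAM's GG
.pamGgPositions <- function(guide) {
  ps <- guide$pam_start
  if (guide$strand == "+") c(ps + 1L, ps + 2L) else c(ps - 2L, ps - 1L)
}

.pamDisrupted <- function(ctx, guide) {
  pp <- .pamGgPositions(guide)
  b <- c(ctx$getBase(pp[1]), ctx$getBase(pp[2]))
  if (guide$strand == "+") !(b[1] == "G" && b[2] == "G")
  else !(b[1] == "C" && b[2] == "C")
}

# genomic positions of the PAM-proximal 10-nt protospacer seed
.seedPositions <- function(guide) {
  ps <- guide$pam_start
  if (guide$strand == "+") seq.int(ps - 10L, ps - 1L)
  else seq.int(ps + 1L, ps + 10L)
}

# attempt one synonymous substitution at genomic position `p`; on
# success applies it and returns a report row, else NULL
.trySynonymous <- function(ctx, isoform, p, wanted = NULL) {
  tidx <- .cdsLocalIndex(isoform, p)
  if (is.na(tidx)) return(NULL)
  codon_i <- tidx %/% 3L
  o <- tidx %% 3L
  gpositions <- vapply(codon_i * 3L + 0:2, function(t)
    .cdsGenomicPos(isoform, t), integer(1))
  plusBases <- vapply(gpositions, ctx$getBase, character(1))
  txBases <- if (isoform@strand == "+") plusBases else
    unname(.COMP[plusBases])
  codon <- paste(txBases, collapse = "")
  aa <- .codonToAa(codon)
  cur <- txBases[o + 1L]
  for (alt in c("A", "C", "G", "T")) {
    if (alt == cur) next
    newTx <- txBases; newTx[o + 1L] <- alt
    newCodon <- paste(newTx, collapse = "")
    if (.codonToAa(newCodon) != aa) next
    plusAlt <- if (isoform@strand == "+") alt else .COMP[[alt]]
    old <- ctx$getBase(p)
    ctx$setBase(p, plusAlt)
    if (is.null(wanted) || isTRUE(wanted())) {
      return(data.frame(genomic_pos = p, ref = old, alt = plusAlt,
                        codon_before = codon, codon_after = newCodon,
                        aa = aa, context = "coding",
                        stringsAsFactors = FALSE))
    }
    ctx$setBase(p, old)  # revert: synonymous but goal not reached
  }
  NULL
}

#' Introduce a silent PAM-disrupting mutation into a homology arm
#'
#' Keeps the donor from being re-cut after repair. Priority: (1) a
#' synonymous single-base change at a PAM GG base lying in annotated
#' CDS; (2) a direct substitution at a PAM GG base lying outside CDS
#' (flagged "non-coding"); (3) synonymous substitutions in the
#' PAM-proximal 10-nt protospacer seed (two changes at distinct codons
#' preferred, one accepted). If nothing disrupts the site without an
#' amino-acid change, a hard error instructs the user to pick another
#' guide. All candidate positions must fall inside an arm.
#'
#' @param arm A single arm (list with `sequence`, `start`, `end`) or a
#'   list of arms as returned by [extractHomologyArms()].
#' @param guide One-row guide-site data.frame.
#' @param isoform The [IsoformModel-class] supplying the reading frame
#'   (may be `NULL` for fully non-coding loci).
#' @param assembly The [GenomeAssembly-class] (context for codons that
#'   extend past the arm).
#' @param contig Contig name.
#' @param allow_pam When `FALSE`, skip the PAM-base strategies and go
#'   straight to seed mutations (used when the payload junction would
#'   otherwise recreate the target site).
#' @return List with `arms` (same shape as the input, mutated) and
#'   `report` (one row per substitution: position, ref/alt base, codon
#'   before/after, amino acid, context).
#' @export
mutatePamSilent <- function(arm, guide, isoform, assembly, contig,
                            allow_pam = TRUE) {
  arms <- if (!is.null(arm$sequence)) list(arm) else arm
  single <- !is.null(arm$sequence)
  stopifnot(nrow(guide) == 1L)
  span <- .siteSpan(guide$pam_start, guide$strand)
  overlaps <- any(vapply(arms, function(a)
    span$start < a$end && span$end > a$start, logical(1)))
  if (!overlaps)
    .inputError("guide site does not overlap the homology arm(s)")
  ctx <- .armContext(arms, assembly, contig)
  report <- list()
  disrupted <- function() .pamDisrupted(ctx, guide)

  pamPos <- .pamGgPositions(guide)
  pamPos <- pamPos[vapply(pamPos, ctx$inArm, logical(1))]
  if (!allow_pam) pamPos <- integer(0)
  # (1) synonymous change at a coding PAM base
  if (!is.null(isoform)) {
    for (p in pamPos) {
      row <- .trySynonymous(ctx, isoform, p, wanted = disrupted)
      if (!is.null(row)) { row$kind <- "PAM"; report[["pam"]] <- row; break }
    }
  }
  # (2) direct change at a non-coding PAM base
  if (length(report) == 0L) {
    for (p in pamPos) {
      coding <- !is.null(isoform) && !is.na(.cdsLocalIndex(isoform, p))
      if (coding) next
      old <- ctx$getBase(p)
      newb <- if (guide$strand == "+") "T" else "A"   # G->T on the PAM strand
      ctx$setBase(p, newb)
      if (disrupted()) {
        report[["pam"]] <- data.frame(
          genomic_pos = p, ref = old, alt = newb, codon_before = NA,
          codon_after = NA, aa = NA, context = "non-coding", kind = "PAM",
          stringsAsFactors = FALSE)
        break
      }
      ctx$setBase(p, old)
    }
  }
  # (3) synonymous seed changes: any change kills the exact match
  # (seed bases outside annotated CDS may change freely)
  if (length(report) == 0L) {
    usedCodons <- integer(0)
    for (p in .seedPositions(guide)) {
      if (!ctx$inArm(p)) next
      tidx <- if (is.null(isoform)) NA_integer_ else
        .cdsLocalIndex(isoform, p)
      if (is.na(tidx)) {
        # non-coding seed base: any substitution is silent
        old <- ctx$getBase(p)
        ctx$setBase(p, if (old == "T") "A" else "T")
        report[[paste0("seed", length(report) + 1L)]] <- data.frame(
          genomic_pos = p, ref = old, alt = ctx$getBase(p),
          codon_before = NA, codon_after = NA, aa = NA,
          context = "non-coding", kind = "seed", stringsAsFactors = FALSE)
        if (length(report) >= 2L) break
        next
      }
      if ((tidx %/% 3L) %in% usedCodons) next
      row <- .trySynonymous(ctx, isoform, p, wanted = NULL)
      if (!is.null(row)) {
        row$kind <- "seed"
        report[[paste0("seed", length(report) + 1L)]] <- row
        usedCodons <- c(usedCodons, tidx %/% 3L)
        if (length(report) >= 2L) break
      }
    }
    if (length(report) == 0L)
      .designError(paste("no synonymous mutation can disrupt the guide",
                         "target in the donor - pick another guide"))
  }
  out <- ctx$result()
  list(arms = if (single) out[[1]] else out,
       report = do.call(rbind, unname(report)))
}

# ---- map assembly helpers -------------------------------------------------

.geneSpan <- function(isoform) {
  c(min(isoform@exons[, 1]), max(isoform@exons[, 2]))
}

.insertionPoint <- function(isoform, terminus) {
  if (terminus == "N") {
    if (isoform@strand == "+") isoform@startCodon + 3L
    else isoform@startCodon - 2L
  } else {
    if (isoform@strand == "+") isoform@stopCodon
    else isoform@stopCodon + 1L
  }
}

#' Select an isoform from a gene model
#'
#' When `isoform` is `NULL` the first isoform in annotation order is
#' used, with a warning if the gene has more than one — consult the
#' annotation source and choose explicitly for real designs.
#'
#' @param gene A [GeneModel-class].
#' @param isoform Isoform ID or `NULL`.
#' @return An [IsoformModel-class].
#' @export
selectIsoform <- function(gene, isoform = NULL) {
  isos <- gene@isoforms
  if (is.null(isoform)) {
    if (length(isos) > 1L)
      .cdWarn("gene '%s' has %d isoforms; defaulting to '%s'",
              gene@geneId, length(isos), isos[[1]]@isoformId)
    return(isos[[1]])
  }
  ids <- vapply(isos, function(i) i@isoformId, character(1))
  hit <- which(ids == isoform)
  if (length(hit) != 1L)
    .inputError("unknown isoform '%s' for gene '%s' (available: %s)",
                isoform, gene@geneId, paste(ids, collapse = ", "))
  isos[[hit]]
}

# locus-relative features for the unaltered locus
.locusFeatures <- function(gene, isoform, lb, guides, primers, arms) {
  f <- list()
  off <- lb[1]
  f[[1]] <- .feature(0L, lb[2] - lb[1], gene@strand, "source",
                     gene@geneId,
                     sprintf("genomic locus [%d, %d) on %s", lb[1], lb[2],
                             gene@contig))
  gs <- .geneSpan(isoform)
  f[[2]] <- .feature(gs[1] - off, gs[2] - off, gene@strand, "gene",
                     gene@symbol, sprintf("gene_id=%s", gene@geneId))
  cds <- isoform@cds
  for (i in seq_len(nrow(cds)))
    f[[length(f) + 1L]] <- .feature(cds[i, 1] - off, cds[i, 2] - off,
                                    gene@strand, "CDS", isoform@isoformId,
                                    sprintf("CDS segment %d", i))
  for (gi in seq_len(NROW(guides))) {
    g <- guides[gi, , drop = FALSE]
    sp <- .siteSpan(g$pam_start, g$strand)
    f[[length(f) + 1L]] <- .feature(
      sp$start - off, sp$end - off, g$strand, "misc_feature",
      sprintf("gRNA %s", g$protospacer),
      sprintf("protospacer+PAM; cut at %d", g$cut_pos))
  }
  if (!is.null(arms)) {
    f[[length(f) + 1L]] <- .feature(arms$left$start - off,
                                    arms$left$end - off, "+",
                                    "misc_feature", "HA_left",
                                    "left homology arm")
    f[[length(f) + 1L]] <- .feature(arms$right$start - off,
                                    arms$right$end - off, "+",
                                    "misc_feature", "HA_right",
                                    "right homology arm")
  }
  if (!is.null(primers)) {
    pr <- primers$pairs
    if (!is.null(pr) && nrow(pr) > 0L) {
      p <- pr[1L, ]
      f[[length(f) + 1L]] <- .feature(p$fwd_genomic_start - off,
                                      p$fwd_genomic_start + p$fwd_length - off,
                                      "+", "primer_bind", "amp_F",
                                      sprintf("amplification forward; Tm %.1f",
                                              p$fwd_tm))
      f[[length(f) + 1L]] <- .feature(p$rev_genomic_start - p$rev_length + 1L - off,
                                      p$rev_genomic_start + 1L - off,
                                      "-", "primer_bind", "amp_R",
                                      sprintf("amplification reverse; Tm %.1f",
                                              p$rev_tm))
    }
    sq <- primers$sequencing
    if (!is.null(sq) && nrow(sq) > 0L) {
      for (side in unique(sq$side)) {
        s <- sq[sq$side == side, ][1L, ]
        st <- if (s$strand == "+") s$genomic_start else
          s$genomic_start - s$length + 1L
        f[[length(f) + 1L]] <- .feature(st - off, st + s$length - off,
                                        s$strand, "primer_bind",
                                        sprintf("seq_%s", substr(side, 1, 2)),
                                        sprintf("sequencing primer; Tm %.1f",
                                                s$tm))
      }
    }
  }
  feats <- do.call(rbind, f)
  # clip to the locus (primers/arms can poke past a clipped window)
  feats$start <- pmax(feats$start, 0L)
  feats$end <- pmin(feats$end, lb[2] - lb[1])
  feats <- feats[feats$end > feats$start, , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

# payload of a template: sequence + features between the arm slots
.templatePayload <- function(tpl) {
  a <- tpl@leftArmSlot[2]; b <- tpl@rightArmSlot[1]
  if (b < a) .vectorError("vector '%s': right slot precedes left slot",
                          tpl@name)
  feats <- tpl@features
  inside <- feats$start >= a & feats$end <= b & feats$type != "source"
  pf <- feats[inside, , drop = FALSE]
  pf$start <- pf$start - a; pf$end <- pf$end - a
  rownames(pf) <- NULL
  list(sequence = substr(tpl@sequence, a + 1L, b), features = pf,
       len = b - a)
}

.flipFeatures <- function(feats, len) {
  if (nrow(feats) == 0L) return(feats)
  ns <- len - feats$end; ne <- len - feats$start
  feats$start <- ns; feats$end <- ne
  feats$strand <- ifelse(feats$strand == "+", "-", "+")
  feats[order(feats$start, feats$end), , drop = FALSE]
}

# substitute mutated arm bases into a locus-local sequence
.applyArmEdits <- function(seqchr, off, arms) {
  for (a in arms) {
    if (a$end <= a$start) next
    substr(seqchr, a$start - off + 1L, a$end - off) <- a$sequence
  }
  seqchr
}

# donor plasmid: template with arms inserted into the slots
.armedDonor <- function(tpl, donorLeft, donorRight, name) {
  a <- tpl@leftArmSlot[1]; b <- tpl@rightArmSlot[1]
  seqchr <- paste0(substr(tpl@sequence, 1L, a), donorLeft,
                   substr(tpl@sequence, a + 1L, b), donorRight,
                   substr(tpl@sequence, b + 1L, nchar(tpl@sequence)))
  nl <- nchar(donorLeft); nr <- nchar(donorRight)
  feats <- tpl@features
  shift <- function(x) ifelse(x <= a, x, ifelse(x <= b, x + nl, x + nl + nr))
  feats$start <- as.integer(shift(feats$start))
  feats$end <- as.integer(shift(feats$end))
  src <- feats$type == "source"
  feats$start[src] <- 0L; feats$end[src] <- nchar(seqchr)
  feats <- rbind(feats,
                 .feature(a, a + nl, "+", "misc_feature", "HA_left",
                          "left homology arm (donor)"),
                 .feature(b + nl, b + nl + nr, "+", "misc_feature",
                          "HA_right", "right homology arm (donor)"))
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  rownames(feats) <- NULL
  assemblyMap(name = name, sequence = seqchr, topology = "circular",
              features = feats,
              provenance = c(sprintf("donor assembled from template %s",
                                     tpl@name)))
}

# ---- tagging and deletion designs ----------------------------------------

#' Build the three cloning maps for an endogenous tagging design
#'
#' Inserts the template's payload (fusion cassette + floxable marker)
#' immediately after the start codon's ATG (N-terminal) or immediately
#' before the stop codon (C-terminal) of the chosen isoform. Produces the
#' guide vector map (BbsI golden-gate simulation), the unaltered locus
#' map, and the edited locus map paired with the circular donor plasmid.
#' Homology arms carry the silent PAM mutation; the design is rejected
#' with a hard error if Cre/LoxP excision of the marker would leave the
#' fusion out of frame.
#'
#' @param assembly A [GenomeAssembly-class].
#' @param gene A [GeneModel-class].
#' @param terminus `"N"` or `"C"`.
#' @param guide One-row guide-site data.frame (pick from [rankGuides()]).
#' @param vector Tagging vector: built-in name, GenBank path or
#'   [VectorTemplate-class].
#' @param config A [designConfig()] list.
#' @param isoform Isoform ID (default: first, with a warning).
#' @param guide_vector Guide vector (default the built-in U6/BbsI one).
#' @param primers Optional precomputed [pickPrimerPairs()] result; when
#'   `NULL` primers are designed around the cut site.
#' @return List with `guide` (map), `locus` (map), `edited` (list of the
#'   edited-locus map and the donor plasmid map), `arms`, `mutation_report`,
#'   `frame_report`, `primers`, `oligos`, `warnings`.
#' @export
buildTaggingMaps <- function(assembly, gene, terminus, guide, vector,
                             config = designConfig(), isoform = NULL,
                             guide_vector = "pU6-BbsI-chiRNA",
                             primers = NULL) {
  terminus <- match.arg(terminus, c("N", "C"))
  if (NROW(guide) != 1L || anyNA(guide$cut_pos))
    .inputError("'guide' must be one valid guide-site row")
  iso <- if (is(isoform, "IsoformModel")) isoform
         else selectIsoform(gene, isoform)
  tpl <- resolveVector(vector)
  wantKind <- if (terminus == "N") "tagN" else "tagC"
  if (!tpl@kind %in% c("tagN", "tagC"))
    .inputError("vector '%s' is not a tagging template", tpl@name)
  if (tpl@kind != wantKind)
    .inputError("vector '%s' is a %s-terminal template but terminus=%s",
                tpl@name, if (tpl@kind == "tagN") "N" else "C", terminus)
  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  contig <- gene@contig
  n <- contigLengths(assembly)[[contig]]
  ip <- .insertionPoint(iso, terminus)
  gs <- .geneSpan(iso)
  lb <- c(max(0L, gs[1] - config$locus_margin),
          min(n, gs[2] + config$locus_margin))
  cutDist <- abs(guide$cut_pos - ip)
  if (cutDist > config$max_cut_distance)
    collect(.cdWarn(
      "guide cut site is %d bp from the insertion point (threshold %d)",
      cutDist, config$max_cut_distance))

  arms <- collect(extractHomologyArms(assembly, contig, ip,
                                      config$arm_length))
  mut <- mutatePamSilent(list(arms$left, arms$right), guide, iso,
                         assembly, contig)
  arms$left <- mut$arms[[1]]; arms$right <- mut$arms[[2]]

  if (is.null(primers)) {
    windows <- collect(primerWindows(guide$cut_pos, lb, config))
    primers <- collect(pickPrimerPairs(assembly, contig, windows, config))
  }

  locusSeq <- extractRegion(assembly, contig, lb[1], lb[2], "+")
  locusFeats <- .locusFeatures(gene, iso, lb, guide, primers, arms)
  locusMap <- assemblyMap(
    name = sprintf("%s_locus", gene@geneId), sequence = locusSeq,
    topology = "linear", features = locusFeats,
    provenance = sprintf("unaltered locus of %s [%d, %d) on %s",
                         gene@geneId, lb[1], lb[2], contig))

  payload <- .templatePayload(tpl)
  pseq <- payload$sequence; pfeat <- payload$features
  if (gene@strand == "-") {
    pseq <- revComp(pseq)
    pfeat <- .flipFeatures(pfeat, payload$len)
  }
  ipl <- ip - lb[1]
  buildEdited <- function() {
    s <- .applyArmEdits(locusSeq, lb[1], list(arms$left, arms$right))
    paste0(substr(s, 1L, ipl), pseq, substr(s, ipl + 1L, nchar(s)))
  }
  editedSeq <- buildEdited()
  # the payload junction itself may recreate the target site (an intact
  # protospacer in one arm completed by a coincidental NGG at the
  # cassette edge): if so, fall back to seed mutations and rebuild
  siteStr <- paste0(guide$protospacer, guide$pam)
  if (grepl(siteStr, editedSeq, fixed = TRUE) ||
      grepl(revComp(siteStr), editedSeq, fixed = TRUE)) {
    mut2 <- mutatePamSilent(list(arms$left, arms$right), guide, iso,
                            assembly, contig, allow_pam = FALSE)
    arms$left <- mut2$arms[[1]]; arms$right <- mut2$arms[[2]]
    mut$report <- rbind(mut$report, mut2$report)
    editedSeq <- buildEdited()
    if (grepl(siteStr, editedSeq, fixed = TRUE) ||
        grepl(revComp(siteStr), editedSeq, fixed = TRUE))
      .designError("payload junction recreates the guide site and no seed mutation can disrupt it - pick another guide")
  }
  K <- payload$len
  shiftF <- locusFeats
  move <- shiftF$start >= ipl
  shiftF$start[move] <- shiftF$start[move] + K
  straddle <- shiftF$start < ipl & shiftF$end > ipl
  shiftF$end[shiftF$end > ipl | straddle] <-
    shiftF$end[shiftF$end > ipl | straddle] + K
  pf <- pfeat; pf$start <- pf$start + ipl; pf$end <- pf$end + ipl
  editedFeats <- rbind(shiftF, pf,
                       .feature(ipl, ipl + K, gene@strand, "misc_feature",
                                "HDR_payload",
                                sprintf("integrated payload from %s",
                                        tpl@name)))
  if (!is.null(mut$report) && nrow(mut$report) > 0L) {
    for (i in seq_len(nrow(mut$report))) {
      mp <- mut$report$genomic_pos[i] - lb[1]
      mp <- mp + if (mp >= ipl) K else 0L
      editedFeats <- rbind(editedFeats,
                           .feature(mp, mp + 1L, "+", "misc_feature",
                                    "silent mutation",
                                    sprintf("%s>%s (%s, %s)",
                                            mut$report$ref[i],
                                            mut$report$alt[i],
                                            mut$report$kind[i],
                                            mut$report$context[i])))
    }
  }
  editedFeats <- editedFeats[order(editedFeats$start, editedFeats$end), ,
                             drop = FALSE]
  rownames(editedFeats) <- NULL
  editedMap <- assemblyMap(
    name = sprintf("%s_edited", gene@geneId), sequence = editedSeq,
    topology = "linear", features = editedFeats,
    provenance = c(sprintf("edited locus of %s: %s-terminal tag from %s",
                           gene@geneId, terminus, tpl@name),
                   sprintf("payload %d bp inserted at genomic %d", K, ip)),
    metadata = list(locus_offset = lb[1], insertion_point = ip,
                    insert_len = K, terminus = terminus,
                    gene_strand = gene@strand))

  donorLeft <- if (gene@strand == "+") arms$left$sequence else
    revComp(arms$right$sequence)
  donorRight <- if (gene@strand == "+") arms$right$sequence else
    revComp(arms$left$sequence)
  donorMap <- .armedDonor(tpl, donorLeft, donorRight,
                          sprintf("%s_donor_%s", gene@geneId, tpl@name))

  oligos <- designGuideOligos(guide, guide_vector)
  guideMap <- oligos$map
  guideMap@name <- sprintf("%s_guides", gene@geneId)

  floxed <- suppressWarnings(simulateFlox(editedMap))
  frameReport <- validateFrame(floxed, iso, terminus)
  if (!frameReport$pass)
    .designError("floxed fusion is out of frame (%s); template/guide combination rejected",
                 frameReport$message)

  list(guide = guideMap, locus = locusMap,
       edited = list(genomic = editedMap, donor = donorMap),
       arms = arms, mutation_report = mut$report,
       frame_report = frameReport, primers = primers, oligos = oligos,
       warnings = warnings)
}

#' Build the three cloning maps for a two-cut gene deletion design
#'
#' The region between the two cut sites is replaced by the deletion
#' vector's payload (floxable DsRed marker, optionally with an attP
#' landing site), giving the exact length identity
#' `len(edited) = len(locus) - (cut_C - cut_N) + len(payload)`.
#'
#' @inheritParams buildTaggingMaps
#' @param guide_N,guide_C One-row guide tables; `guide_N`'s cut must lie
#'   strictly left of `guide_C`'s cut on the plus strand.
#' @return Same shape as [buildTaggingMaps()] (no `frame_report`); the
#'   guide map carries both guide plasmids as two records.
#' @export
buildDeletionMaps <- function(assembly, gene, guide_N, guide_C, vector,
                              config = designConfig(), isoform = NULL,
                              guide_vector = "pU6-BbsI-chiRNA",
                              primers = NULL) {
  iso <- if (is(isoform, "IsoformModel")) isoform
         else selectIsoform(gene, isoform)
  tpl <- resolveVector(vector)
  if (tpl@kind != "deletion")
    .inputError("vector '%s' is not a deletion template", tpl@name)
  if (NROW(guide_N) != 1L || NROW(guide_C) != 1L ||
      anyNA(c(guide_N$cut_pos, guide_C$cut_pos)))
    .inputError("'guide_N'/'guide_C' must be single valid guide-site rows")
  cutN <- guide_N$cut_pos; cutC <- guide_C$cut_pos
  if (cutN >= cutC)
    .inputError("deletion cuts inverted or equal (cut_N=%d, cut_C=%d)",
                cutN, cutC)
  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  contig <- gene@contig
  n <- contigLengths(assembly)[[contig]]
  gs <- .geneSpan(iso)
  lb <- c(max(0L, min(gs[1], cutN) - config$locus_margin),
          min(n, max(gs[2], cutC) + config$locus_margin))
  arms <- collect(extractHomologyArms(assembly, contig, c(cutN, cutC),
                                      config$arm_length))
  # mutate only if an intact guide site survives inside an arm
  reports <- list()
  for (g in list(guide_N, guide_C)) {
    span <- .siteSpan(g$pam_start, g$strand)
    inLeft <- span$start >= arms$left$start && span$end <= arms$left$end
    inRight <- span$start >= arms$right$start && span$end <= arms$right$end
    if (inLeft || inRight) {
      mut <- mutatePamSilent(list(arms$left, arms$right), g, iso,
                             assembly, contig)
      arms$left <- mut$arms[[1]]; arms$right <- mut$arms[[2]]
      reports[[length(reports) + 1L]] <- mut$report
    }
  }
  mutReport <- if (length(reports) > 0L) do.call(rbind, reports) else NULL

  guides2 <- rbind(guide_N, guide_C)
  if (is.null(primers)) {
    primers <- list()
    for (nm in c("N", "C")) {
      cut <- if (nm == "N") cutN else cutC
      w <- collect(primerWindows(cut, lb, config))
      primers[[nm]] <- collect(pickPrimerPairs(assembly, contig, w, config))
    }
  }
  locusSeq <- extractRegion(assembly, contig, lb[1], lb[2], "+")
  locusFeats <- .locusFeatures(gene, iso, lb, guides2, primers$N, arms)
  locusMap <- assemblyMap(
    name = sprintf("%s_locus", gene@geneId), sequence = locusSeq,
    topology = "linear", features = locusFeats,
    provenance = sprintf("unaltered locus of %s [%d, %d) on %s",
                         gene@geneId, lb[1], lb[2], contig))

  payload <- .templatePayload(tpl)
  cutNl <- cutN - lb[1]; cutCl <- cutC - lb[1]
  buildEdited <- function() {
    s <- .applyArmEdits(locusSeq, lb[1], list(arms$left, arms$right))
    paste0(substr(s, 1L, cutNl), payload$sequence,
           substr(s, cutCl + 1L, nchar(s)))
  }
  editedSeq <- buildEdited()
  # a cut/payload junction can coincidentally recreate a target site;
  # disrupt it with seed mutations where the arms allow
  for (g in list(guide_N, guide_C)) {
    siteStr <- paste0(g$protospacer, g$pam)
    if (grepl(siteStr, editedSeq, fixed = TRUE) ||
        grepl(revComp(siteStr), editedSeq, fixed = TRUE)) {
      mut <- mutatePamSilent(list(arms$left, arms$right), g, iso,
                             assembly, contig, allow_pam = FALSE)
      arms$left <- mut$arms[[1]]; arms$right <- mut$arms[[2]]
      reports[[length(reports) + 1L]] <- mut$report
      editedSeq <- buildEdited()
    }
  }
  mutReport <- if (length(reports) > 0L) do.call(rbind, reports) else NULL
  K <- payload$len; removed <- cutC - cutN
  keep <- locusFeats[locusFeats$end <= cutNl | locusFeats$start >= cutCl |
                       locusFeats$type == "source", , drop = FALSE]
  shift <- keep$start >= cutCl
  keep$start[shift] <- keep$start[shift] - removed + K
  keep$end[keep$end >= cutCl] <- keep$end[keep$end >= cutCl] - removed + K
  keep$end[keep$type == "source"] <- nchar(editedSeq)
  pf <- payload$features
  pf$start <- pf$start + cutNl; pf$end <- pf$end + cutNl
  editedFeats <- rbind(keep, pf,
                       .feature(cutNl, cutNl + K, "+", "misc_feature",
                                "deletion cassette",
                                sprintf("%s: replaced genomic [%d, %d)",
                                        gene@geneId, cutN, cutC)))
  editedFeats <- editedFeats[order(editedFeats$start, editedFeats$end), ,
                             drop = FALSE]
  rownames(editedFeats) <- NULL
  editedMap <- assemblyMap(
    name = sprintf("%s_edited", gene@geneId), sequence = editedSeq,
    topology = "linear", features = editedFeats,
    provenance = c(sprintf("deletion of %s: genomic [%d, %d) replaced by %s payload",
                           gene@geneId, cutN, cutC, tpl@name)),
    metadata = list(locus_offset = lb[1], cut_N = cutN, cut_C = cutC,
                    insert_len = K))
  donorMap <- .armedDonor(tpl, arms$left$sequence, arms$right$sequence,
                          sprintf("%s_donor_%s", gene@geneId, tpl@name))
  oligosN <- designGuideOligos(guide_N, guide_vector)
  oligosC <- designGuideOligos(guide_C, guide_vector)
  gmN <- oligosN$map; gmN@name <- sprintf("%s_guide_N", gene@geneId)
  gmC <- oligosC$map; gmC@name <- sprintf("%s_guide_C", gene@geneId)

  list(guide = list(gmN, gmC), locus = locusMap,
       edited = list(genomic = editedMap, donor = donorMap),
       arms = arms, mutation_report = mutReport,
       primers = primers, oligos = list(N = oligosN, C = oligosC),
       warnings = warnings)
}

# ---- Cre/LoxP simulation and frame validation -----------------------------

#' Simulate Cre-mediated excision between two LoxP sites
#'
#' Requires exactly two identical, same-orientation LoxP features
#' (label `loxP`). The sequence between their start positions is
#' excised, leaving a single 34-bp LoxP scar; features inside the
#' excised span are dropped, downstream features shifted, and a
#' provenance note is added. Zero, one, more than two, or inverted LoxP
#' sites raise an error (inversion simulation is out of scope).
#'
#' @param map An [AssemblyMap-class].
#' @return The floxed [AssemblyMap-class].
#' @export
simulateFlox <- function(map) {
  stopifnot(is(map, "AssemblyMap"))
  feats <- map@features
  li <- which(feats$label == "loxP")
  if (length(li) != 2L)
    .inputError("flox requires exactly two loxP features (found %d)",
                length(li))
  l1 <- feats[li[1], ]; l2 <- feats[li[2], ]
  if (l1$strand != l2$strand)
    .inputError("loxP sites are inverted; inversion simulation is not supported")
  s1 <- min(l1$start, l2$start); s2 <- max(l1$start, l2$start)
  seq1 <- substr(map@sequence, l1$start + 1L, l1$end)
  seq2 <- substr(map@sequence, l2$start + 1L, l2$end)
  if (!identical(seq1, seq2))
    .inputError("the two loxP features are not sequence-identical")
  removed <- s2 - s1
  newSeq <- paste0(substr(map@sequence, 1L, s1),
                   substr(map@sequence, s2 + 1L, nchar(map@sequence)))
  adj <- function(x) ifelse(x <= s1, x, ifelse(x < s2, s1, x - removed))
  ns <- as.integer(adj(feats$start)); ne <- as.integer(adj(feats$end))
  keep <- ne > ns
  nf <- feats[keep, , drop = FALSE]
  nf$start <- ns[keep]; nf$end <- ne[keep]
  rownames(nf) <- NULL
  md <- map@metadata
  if (!is.null(md$insert_len)) md$insert_len <- md$insert_len - removed
  assemblyMap(
    name = paste0(map@name, "_floxed"), sequence = newSeq,
    topology = map@topology, features = nf,
    provenance = c(map@provenance,
                   sprintf("Cre/LoxP excision: removed %d bp [%d, %d); one 34-bp loxP scar retained",
                           removed, s1, s2)),
    metadata = md)
}

#' Validate the reading frame of a floxed tagging design
#'
#' Translates from the isoform's ATG through the residual insert (fusion
#' cassette plus the retained LoxP scar, which serves as a peptide
#' linker) into the downstream coding sequence. Passes iff the inserted
#' length is a multiple of 3 and the fusion carries no premature stop.
#'
#' @param floxed_map Edited-locus [AssemblyMap-class] after
#'   [simulateFlox()] (metadata from [buildTaggingMaps()] required).
#' @param isoform The tagged [IsoformModel-class].
#' @param terminus `"N"` or `"C"`.
#' @return List report: `pass`, `frame_offset` (inserted length mod 3),
#'   `peptide` (fusion-junction peptide, inserted residues with 5 flanking
#'   residues each side), `insert_len`, `message`.
#' @export
validateFrame <- function(floxed_map, isoform, terminus) {
  md <- floxed_map@metadata
  need <- c("locus_offset", "insertion_point", "insert_len")
  if (!all(need %in% names(md)))
    .inputError("map lacks design metadata; pass the edited map from buildTaggingMaps")
  off <- md$locus_offset
  ipl <- md$insertion_point - off
  K <- md$insert_len
  strand <- isoform@strand
  cds <- isoform@cds
  cdsl <- cbind(cds[, 1] - off, cds[, 2] - off)
  segs <- list()
  for (i in seq_len(nrow(cdsl))) {
    s <- cdsl[i, 1]; e <- cdsl[i, 2]
    if (e <= ipl) {
      segs[[length(segs) + 1L]] <- c(s, e, 0L)
    } else if (s >= ipl) {
      segs[[length(segs) + 1L]] <- c(s + K, e + K, 0L)
    } else {
      segs[[length(segs) + 1L]] <- c(s, ipl, 0L)
      segs[[length(segs) + 1L]] <- c(ipl + K, e + K, 0L)
    }
  }
  segs[[length(segs) + 1L]] <- c(ipl, ipl + K, 1L)  # the insert, coding
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(m)), function(i) {
    s <- substr(floxed_map@sequence, m[i, 1] + 1L, m[i, 2])
    if (strand == "-") revComp(s) else s
  }, character(1))
  ord <- if (strand == "-") rev(seq_len(nrow(m))) else seq_len(nrow(m))
  fusion <- paste(seqs[ord], collapse = "")
  frameOffset <- K %% 3L
  insBefore <- 0L
  for (i in ord) {
    if (m[i, 3] == 1L) break
    insBefore <- insBefore + (m[i, 2] - m[i, 1])
  }
  pad <- nchar(fusion) %% 3L
  aa <- .translateDna(substr(fusion, 1L, nchar(fusion) - pad))
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  hasStop <- grepl("\\*", internal)
  startsM <- startsWith(aa, "M")
  endsStop <- endsWith(aa, "*")
  pass <- frameOffset == 0L && !hasStop && startsM && endsStop && pad == 0L
  a0 <- insBefore %/% 3L + 1L
  a1 <- min(nchar(aa), (insBefore + K - 1L) %/% 3L + 1L)
  peptide <- substr(aa, max(1L, a0 - 5L), min(nchar(aa), a1 + 5L))
  msg <- if (pass) "in frame, no premature stop" else paste0(
    if (frameOffset != 0L) sprintf("insert length %d not a multiple of 3 (offset %d); ",
                                   K, frameOffset) else "",
    if (hasStop) "premature stop in fusion; " else "",
    if (!startsM) "fusion does not start with Met; " else "",
    if (!endsStop && frameOffset == 0L) "fusion does not end at the stop codon; " else "")
  list(pass = pass, frame_offset = frameOffset, peptide = peptide,
       insert_len = K, message = trimws(msg))
}

# ---- guide oligos / golden gate -------------------------------------------

#' Design BbsI golden-gate oligos and simulate guide-vector assembly
#'
#' The annealed oligo pair carries the protospacer with CTTC / AAAC
#' overhangs; BbsI digestion of the U6 vector (two outward-facing sites
#' released with the stuffer) followed by ligation is simulated in
#' silico, yielding the final guide plasmid map with the spacer seated
#' between the U6 promoter and the gRNA scaffold and no residual BbsI
#' site.
#'
#' @param guide One-row guide-site data.frame.
#' @param guide_vector Guide vector (name, path or
#'   [VectorTemplate-class]) with two BbsI sites flanking the slot.
#' @return List with `forward`, `reverse` (oligo sequences 5'->3') and
#'   `map` (circular [AssemblyMap-class]).
#' @export
designGuideOligos <- function(guide, guide_vector = "pU6-BbsI-chiRNA") {
  stopifnot(nrow(guide) == 1L)
  tpl <- resolveVector(guide_vector)
  p <- guide$protospacer
  fwd <- if (startsWith(p, "G")) paste0("CTTC", p) else paste0("CTTCG", p)
  core <- substr(fwd, 5L, nchar(fwd))
  rev <- paste0("AAAC", revComp(core))
  # rev = AAAC + revcomp(G-extended spacer); its last base is the C
  # complementary to the spacer's leading G
  seqchr <- tpl@sequence
  rTop <- .findAll(seqchr, "GAAGAC")    # cuts rightward: top r+8/bottom r+12
  rBot <- .findAll(seqchr, "GTCTTC")    # cuts leftward:  top t-6/bottom t-2
  if (length(rTop) != 1L || length(rBot) != 1L)
    .vectorError("guide vector '%s' must contain exactly two BbsI sites (found %d)",
                 tpl@name, length(rTop) + length(rBot))
  t <- rBot; r <- rTop
  if (t - 6L < 0L || r + 12L > nchar(seqchr) || t >= r)
    .vectorError("BbsI sites in '%s' are not arranged around a slot", tpl@name)
  leftCut <- t - 6L            # top-strand boundary; bottom overhang GAAG
  rightCut <- r + 8L           # top-strand boundary; top overhang GTTT
  leftOverhang <- revComp(substr(seqchr, leftCut + 1L, leftCut + 4L))
  rightOverhang <- substr(seqchr, rightCut + 1L, rightCut + 4L)
  if (!identical(substr(fwd, 1L, 4L), revComp(leftOverhang)))
    .vectorError("forward-oligo overhang does not match the digested vector")
  if (!identical(substr(rev, 1L, 4L), revComp(rightOverhang)))
    .vectorError("reverse-oligo overhang does not match the digested vector")
  newSeq <- paste0(substr(seqchr, 1L, leftCut), fwd,
                   substr(seqchr, rightCut + 1L, nchar(seqchr)))
  delta <- nchar(fwd) - (rightCut - leftCut)
  feats <- tpl@features
  keep <- feats$end <= leftCut | feats$start >= rightCut |
    feats$type == "source"
  nf <- feats[keep, , drop = FALSE]
  shift <- nf$start >= rightCut
  nf$start[shift] <- nf$start[shift] + delta
  nf$end[nf$end >= rightCut] <- nf$end[nf$end >= rightCut] + delta
  nf$end[nf$type == "source"] <- nchar(newSeq)
  spacerAt <- leftCut + nchar(fwd) - 20L
  nf <- rbind(nf,
              .feature(leftCut, leftCut + nchar(fwd), "+", "misc_feature",
                       "guide oligo insert", "BbsI golden-gate insert"),
              .feature(spacerAt, spacerAt + 20L, "+", "misc_feature",
                       "protospacer", sprintf("targets %s:%d (%s)",
                                              guide$contig, guide$cut_pos,
                                              guide$strand)))
  nf <- nf[order(nf$start, nf$end), , drop = FALSE]
  rownames(nf) <- NULL
  doubled <- paste0(newSeq, substr(newSeq, 1L, 12L))
  if (grepl("GAAGAC", doubled, fixed = TRUE) ||
      grepl("GTCTTC", doubled, fixed = TRUE))
    .cdWarn("assembled guide vector retains a BbsI site (spacer-encoded)")
  map <- assemblyMap(
    name = sprintf("%s_with_spacer", tpl@name), sequence = newSeq,
    topology = "circular", features = nf,
    provenance = c(sprintf("golden-gate assembly of %s with spacer %s",
                           tpl@name, p)))
  list(forward = fwd, reverse = rev, map = map)
}
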