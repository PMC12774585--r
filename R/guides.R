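# SpCas9 target-site enumeration and off-target counting.
#
# A guide site is stored as one row of a data.frame with columns
#   protospacer  20-nt sequence on the protospacer strand
#   pam          3-nt PAM (NGG) on the protospacer strand
#   strand       "+" or "-"
#   contig       contig name
#   pam_start    genomic position (0-based) of the PAM base that comes
#                first in the PAM's own 5'->3' reading order
#   cut_pos      genomic coordinate of the blunt cut (pam_start -/+ 3)
#   anchor_distance  signed bp from cut_pos to the anchor position
#   overlaps_anchor  TRUE when the protospacer overlaps the anchor codon
# plus, after annotation, `efficiency`, `ot0`..`ot3`, `ot_total`,
# `has_exact_offtarget`.

#' Genomic cut position of an SpCas9 site
#'
#' The blunt cut lies 3 bp 5' of the PAM (between protospacer bases 17 and
#' 18). Under the package convention this is `pam_start - 3` for a
#' plus-strand site and `pam_start + 3` for a minus-strand site.
#'
#' @param pam_start Genomic position of the PAM's first base (0-based).
#' @param strand `"+"` or `"-"`.
#' @return Integer genomic position.
#' @examples
#' cutPosition(100, "+")  # 97
#' cutPosition(100, "-")  # 103
#' @export
cutPosition <- function(pam_start, strand) {
  if (!all(strand %in% c("+", "-"))) .inputError("strand must be '+' or '-'")
  as.integer(ifelse(strand == "+", pam_start - 3L, pam_start + 3L))
}

# Enumerate every PAM-adjacent site on both strands of one contig,
# restricted to candidates whose protospacer fits inside the contig.
# Returns the bare site table (no anchor columns). `include_nag` adds
# NAG-PAM sites (off by default).
.enumerateSites <- function(seqchr, contig, protospacer_len = 20L,
                            include_nag = FALSE) {
  n <- nchar(seqchr)
  L <- as.integer(protospacer_len)
  out <- list()

  plusPam <- function(dinuc) {
    # plus-strand PAM N<dinuc> occupies [g, g+3); protospacer [g-L, g)
    gg <- .findAll(seqchr, dinuc)
    ps <- gg - 1L
    ps <- ps[ps - L >= 0L & ps + 3L <= n]
    if (length(ps) == 0L) return(NULL)
    data.frame(
      protospacer = substring(seqchr, ps - L + 1L, ps),
      pam = substring(seqchr, ps + 1L, ps + 3L),
      strand = "+", contig = contig, pam_start = ps,
      stringsAsFactors = FALSE)
  }
  minusPam <- function(dinuc_rc) {
    # minus-strand PAM appears on plus as <dinuc_rc>N at [q, q+3);
    # protospacer occupies plus [q+3, q+3+L); pam_start = q + 2
    qq <- .findAll(seqchr, dinuc_rc)
    qq <- qq[qq + 3L + L <= n & qq >= 0L]
    if (length(qq) == 0L) return(NULL)
    data.frame(
      protospacer = revComp(substring(seqchr, qq + 4L, qq + 3L + L)),
      pam = revComp(substring(seqchr, qq + 1L, qq + 3L)),
      strand = "-", contig = contig, pam_start = qq + 2L,
      stringsAsFactors = FALSE)
  }

  out[["pgg"]] <- plusPam("GG")
  out[["mgg"]] <- minusPam("CC")
  if (include_nag) {
    out[["pag"]] <- plusPam("AG")
    out[["mag"]] <- minusPam("CT")
  }
  sites <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sites))
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), contig = character(0),
                      pam_start = integer(0), stringsAsFactors = FALSE))
  rownames(sites) <- NULL
  # ambiguous bases invalidate a site
  keep <- !grepl("N", sites$protospacer, fixed = TRUE) &
    !grepl("N", sites$pam, fixed = TRUE)
  sites[keep, , drop = FALSE]
}

#' Scan for SpCas9 target sites around an anchor position
#'
#' Enumerates all NGG-adjacent 20-nt protospacers on both strands of
#' `contig` whose cut position falls within `anchor_pos +/- window_bp`,
#' sorted by `|anchor_distance|` ascending, ties broken by cut position,
#' then PAM position, then strand (`"+"` before `"-"`). Sites containing
#' N are excluded. A window running past the contig is clipped with a
#' warning.
#'
#' @param assembly A [GenomeAssembly-class].
#' @param contig Contig name.
#' @param anchor_pos Genomic anchor (0-based), e.g. the first base of the
#'   start or stop codon.
#' @param window_bp Half-width of the cut-position window (> 0).
#' @param protospacer_len Protospacer length (default 20).
#' @param include_nag Also accept NAG PAMs (default `FALSE`).
#' @return A guide-site data.frame (see package overview); zero rows when
#'   nothing matches.
#' @export
scanGuides <- function(assembly, contig, anchor_pos, window_bp = 20L,
                       protospacer_len = 20L, include_nag = FALSE) {
  stopifnot(is(assembly, "GenomeAssembly"))
  if (!contig %in% contigNames(assembly))
    .rangeError("unknown contig '%s'", contig)
  n <- contigLengths(assembly)[[contig]]
  anchor_pos <- as.integer(anchor_pos)
  window_bp <- as.integer(window_bp)
  if (anchor_pos < 0L || anchor_pos >= n)
    .rangeError("anchor %d outside contig '%s' (%d bp)", anchor_pos, contig, n)
  if (window_bp <= 0L) .inputError("window_bp must be > 0")
  if (anchor_pos - window_bp < 0L || anchor_pos + window_bp > n)
    .cdWarn("guide window around %d clipped to contig '%s' bounds",
            anchor_pos, contig)
  # restrict the scan to the window plus a margin covering any site whose
  # cut could fall inside it (site span <= 23 bp around the cut)
  margin <- protospacer_len + 25L
  r0 <- max(0L, anchor_pos - window_bp - margin)
  r1 <- min(n, anchor_pos + window_bp + margin)
  seqchr <- as.character(Biostrings::subseq(assembly@sequences[[contig]],
                                            r0 + 1L, r1))
  sites <- .enumerateSites(seqchr, contig, protospacer_len, include_nag)
  if (nrow(sites) > 0L) {
    sites$pam_start <- sites$pam_start + r0
    # drop sites whose protospacer would poke past the scanned region only
    # if they also poke past the contig (they cannot: region is clipped to
    # the contig, and any site cutting inside the window lies within it)
    sites$cut_pos <- cutPosition(sites$pam_start, sites$strand)
    sites <- sites[abs(sites$cut_pos - anchor_pos) <= window_bp, ,
                   drop = FALSE]
  } else {
    sites$cut_pos <- integer(0)
  }
  sites$anchor_distance <- sites$cut_pos - anchor_pos
  span <- .protospacerSpan(sites$pam_start, sites$strand, protospacer_len)
  sites$overlaps_anchor <- span$start < (anchor_pos + 3L) &
    span$end > anchor_pos
  ord <- order(abs(sites$anchor_distance), sites$cut_pos, sites$pam_start,
               sites$strand, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Plus-strand interval occupied by the protospacer.
.protospacerSpan <- function(pam_start, strand, L = 20L) {
  start <- ifelse(strand == "+", pam_start - L, pam_start + 1L)
  list(start = as.integer(start), end = as.integer(start) + L)
}

# Plus-strand interval occupied by protospacer plus PAM.
.siteSpan <- function(pam_start, strand, L = 20L) {
  start <- ifelse(strand == "+", pam_start - L, pam_start - 2L)
  list(start = as.integer(start), end = as.integer(start) + L + 3L)
}

#' Count genome-wide off-targets of a guide
#'
#' For each mismatch count `m` in `0..max_mismatch`, counts the NGG-
#' adjacent 20-nt windows on both strands of the whole assembly whose
#' Hamming distance to the protospacer is exactly `m`, excluding the
#' site's own locus. Candidate windows containing N never match a PAM and
#' N inside a protospacer counts as a mismatch.
#'
#' @param site A one-row guide-site data.frame (from [scanGuides()]).
#' @param assembly A [GenomeAssembly-class].
#' @param max_mismatch Maximum mismatch count tabulated (default 3).
#' @param include_nag Also treat NAG-PAM windows as candidate off-targets.
#' @param index Optional precomputed site index from
#'   [buildOfftargetIndex()]; pass it when counting many guides against
#'   the same assembly.
#' @return Named integer vector `ot0`..`ot<max_mismatch>`.
#' @export
countOfftargets <- function(site, assembly, max_mismatch = 3L,
                            include_nag = FALSE, index = NULL) {
  stopifnot(nrow(site) == 1L)
  if (is.null(index)) index <- buildOfftargetIndex(assembly, include_nag)
  L <- nchar(site$protospacer)
  if (nrow(index$sites) == 0L) {
    return(stats::setNames(rep(0L, max_mismatch + 1L),
                           paste0("ot", 0:max_mismatch)))
  }
  target <- strsplit(site$protospacer, "")[[1]]
  mm <- colSums(index$mat != target)
  self <- index$sites$contig == site$contig &
    index$sites$strand == site$strand &
    index$sites$pam_start == site$pam_start
  mm <- mm[!self]
  counts <- vapply(0:max_mismatch, function(m) sum(mm == m), integer(1))
  stats::setNames(counts, paste0("ot", 0:max_mismatch))
}

#' Precompute the genome-wide candidate-site index
#'
#' Enumerates every PAM-adjacent protospacer in the assembly once so that
#' [countOfftargets()] can be called for many guides without rescanning.
#'
#' @inheritParams countOfftargets
#' @param assembly A [GenomeAssembly-class].
#' @return An opaque list (`sites` table plus a base matrix).
#' @export
buildOfftargetIndex <- function(assembly, include_nag = FALSE) {
  stopifnot(is(assembly, "GenomeAssembly"))
  per <- lapply(contigNames(assembly), function(cn)
    .enumerateSites(as.character(assembly@sequences[[cn]]), cn,
                    include_nag = include_nag))
  sites <- do.call(rbind, per)
  rownames(sites) <- NULL
  mat <- if (nrow(sites) > 0L)
    matrix(unlist(strsplit(sites$protospacer, ""), use.names = FALSE),
           nrow = 20L) else matrix(character(0), nrow = 20L)
  list(sites = sites, mat = mat)
}

#' Annotate scanned guides with efficiency scores and off-target counts
#'
#' Convenience wrapper filling the `efficiency`, `ot0..ot3`, `ot_total`
#' and `has_exact_offtarget` columns used by [rankGuides()].
#'
#' @param sites Guide-site data.frame from [scanGuides()].
#' @param assembly The [GenomeAssembly-class] scanned.
#' @param matrix An [EfficiencyMatrix-class]; default matrix when `NULL`.
#' @param max_mismatch,include_nag,index Passed to [countOfftargets()].
#' @return The input with annotation columns added.
#' @export
annotateGuides <- function(sites, assembly, matrix = NULL,
                           max_mismatch = 3L, include_nag = FALSE,
                           index = NULL) {
  if (is.null(matrix)) matrix <- defaultEfficiencyMatrix()
  if (nrow(sites) == 0L) {
    sites$efficiency <- numeric(0)
    for (m in 0:max_mismatch) sites[[paste0("ot", m)]] <- integer(0)
    sites$ot_total <- integer(0)
    sites$has_exact_offtarget <- logical(0)
    return(sites)
  }
  sites$efficiency <- efficiencyScore(sites$protospacer, matrix)
  idx <- if (is.null(index)) buildOfftargetIndex(assembly, include_nag)
         else index
  ots <- t(vapply(seq_len(nrow(sites)), function(i)
    countOfftargets(sites[i, , drop = FALSE], assembly,
                    max_mismatch = max_mismatch,
                    include_nag = include_nag, index = idx),
    integer(max_mismatch + 1L)))
  colnames(ots) <- paste0("ot", 0:max_mismatch)
  sites <- cbind(sites, as.data.frame(ots))
  mmcols <- paste0("ot", seq_len(max_mismatch))
  sites$ot_total <- as.integer(rowSums(sites[, mmcols, drop = FALSE]))
  sites$has_exact_offtarget <- sites$ot0 > 0L
  sites
}
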