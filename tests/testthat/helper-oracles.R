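# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written as plain loops over every offset,
# independent of the package's vectorized scanning code.

.fxCache <- new.env(parent = emptyenv())

# the default synthetic mini-genome, parsed once per test run
miniFixture <- function(seed = 42L, planted = 0L) {
  key <- sprintf("fx_%d_%d", seed, planted)
  if (!is.null(.fxCache[[key]])) return(.fxCache[[key]])
  dir <- file.path(tempdir(), key)
  fx <- makeMiniGenome(fixtureSpec(seed = seed,
                                   planted_duplicates = planted),
                       dir = dir)
  ga <- parseFasta(fx$fasta)
  genes <- suppressWarnings(parseGff3(fx$gff3, ga))
  .fxCache[[key]] <- list(fx = fx, assembly = ga, genes = genes, dir = dir)
  .fxCache[[key]]
}

sharedIndex <- function(assembly, key) {
  k <- paste0("idx_", key)
  if (is.null(.fxCache[[k]])) .fxCache[[k]] <- buildOfftargetIndex(assembly)
  .fxCache[[k]]
}

comp1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rcOracle <- function(s) {
  b <- strsplit(s, "")[[1]]
  paste(rev(unname(comp1[b])), collapse = "")
}

# brute-force enumeration of every NGG site on both strands, looping
# over every offset of the sequence
bruteSites <- function(seqchr, contig = "chr") {
  n <- nchar(seqchr)
  rows <- list()
  for (i in 0:(n - 1L)) {
    # plus strand: protospacer [i, i+20), PAM [i+20, i+23)
    if (i + 23L <= n) {
      pam <- substr(seqchr, i + 21L, i + 23L)
      proto <- substr(seqchr, i + 1L, i + 20L)
      if (substr(pam, 2, 3) == "GG" && !grepl("N", paste0(proto, pam)))
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = proto, pam = pam, strand = "+", contig = contig,
          pam_start = i + 20L, stringsAsFactors = FALSE)
    }
    # minus strand: plus-strand CCN at [i, i+3), protospacer [i+3, i+23)
    if (i + 23L <= n) {
      pamPlus <- substr(seqchr, i + 1L, i + 3L)
      protoPlus <- substr(seqchr, i + 4L, i + 23L)
      if (substr(pamPlus, 1, 2) == "CC" &&
          !grepl("N", paste0(pamPlus, protoPlus)))
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = rcOracle(protoPlus), pam = rcOracle(pamPlus),
          strand = "-", contig = contig, pam_start = i + 2L,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), contig = character(0),
                      pam_start = integer(0)))
  do.call(rbind, rows)
}

# brute-force window scan with the documented composite sort key
bruteScan <- function(seqchr, contig, anchor, window) {
  s <- bruteSites(seqchr, contig)
  if (nrow(s) == 0L) return(s)
  s$cut_pos <- ifelse(s$strand == "+", s$pam_start - 3L, s$pam_start + 3L)
  s <- s[abs(s$cut_pos - anchor) <= window, , drop = FALSE]
  ord <- order(abs(s$cut_pos - anchor), s$cut_pos, s$pam_start, s$strand,
               method = "radix")
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  s
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force genome-wide off-target tabulation for one guide
bruteOfftargets <- function(guide, candidates, max_mm = 3L) {
  mm <- vapply(seq_len(nrow(candidates)), function(i)
    hamming(guide$protospacer, candidates$protospacer[i]), integer(1))
  self <- candidates$contig == guide$contig &
    candidates$strand == guide$strand &
    candidates$pam_start == guide$pam_start
  mm <- mm[!self]
  stats::setNames(vapply(0:max_mm, function(m) sum(mm == m), integer(1)),
                  paste0("ot", 0:max_mm))
}

# all brute-force candidate sites of an assembly (for off-target oracles)
bruteAllSites <- function(assembly) {
  do.call(rbind, lapply(contigNames(assembly), function(cn)
    bruteSites(as.character(assembly@sequences[[cn]]), cn)))
}

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independently coded SantaLucia-1998 nearest-neighbor Tm (deliberately
# re-typed, structured differently from the implementation)
nnTmOracle <- function(s, conc_nM = 50, na_mM = 50) {
  dh <- list(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
             TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
             CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
             GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
  ds <- list(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
             TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
             CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
             GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
  b <- strsplit(s, "")[[1]]
  H <- 0; S <- 0
  for (i in seq_len(length(b) - 1L)) {
    key <- paste0(b[i], b[i + 1L])
    H <- H + dh[[key]]; S <- S + ds[[key]]
  }
  for (term in c(b[1], b[length(b)])) {
    if (term %in% c("A", "T")) { H <- H + 2.3; S <- S + 4.1 }
    else { H <- H + 0.1; S <- S - 2.8 }
  }
  S <- S + 0.368 * (length(b) - 1L) * log(na_mM / 1000)
  H * 1000 / (S + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# primer-free placeholder used where primer design is not under test
noPrimers <- list(pairs = NULL, sequencing = NULL)

# one shared tagging design per terminus on the fixture genome
cachedDesign <- function(terminus = "N") {
  key <- paste0("design_", terminus)
  if (!is.null(.fxCache[[key]])) return(.fxCache[[key]])
  fx <- miniFixture()
  g1 <- fx$genes[["g1"]]
  iso <- suppressWarnings(selectIsoform(g1))
  anchor <- if (terminus == "N") startCodon(iso) else stopCodon(iso)
  idx <- sharedIndex(fx$assembly, "fx42")
  ranked <- suppressWarnings(rankGuides(annotateGuides(
    scanGuides(fx$assembly, g1@contig, anchor, 20), fx$assembly,
    index = idx)))
  vec <- if (terminus == "N") "pHD-SspB-ExLK-EGFP-DsRed"
         else "pHD-EGFP-ExLK-SspB-DsRed"
  d <- suppressWarnings(buildTaggingMaps(
    fx$assembly, g1, terminus, ranked[1, , drop = FALSE], vec,
    isoform = iso, primers = noPrimers))
  .fxCache[[key]] <- list(design = d, gene = g1, iso = iso,
                          guide = ranked[1, , drop = FALSE])
  .fxCache[[key]]
}

# standard-genetic-code translation oracle built on a literal codon table
translateOracle <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3L
  paste(vapply(seq_len(n), function(i)
    code[[substr(dna, 3L * i - 2L, 3L * i)]], character(1)), collapse = "")
}
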