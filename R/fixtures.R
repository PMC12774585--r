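# Seeded synthetic mini-genome generator.
#
# Emulates a compact annotated genome so the whole pipeline runs and
# tests offline: intergenic background is i.i.d. uniform ACGT, genes are
# random open reading frames (ATG ... stop, CDS length a multiple of 3)
# optionally interrupted by short GT..AG introns, on alternating
# strands. Identical seeds give byte-identical FASTA/GFF3 output.

#' Specification for the synthetic mini-genome
#'
#' @param n_contigs Number of contigs (genes are placed round-robin).
#' @param contig_length Length of each contig in bp.
#' @param n_genes Number of genes.
#' @param exons_per_gene Coding exons per gene (introns of 60-200 bp are
#'   inserted between them).
#' @param seed Integer seed; the generator is a pure function of these
#'   settings.
#' @param planted_duplicates Number of guide-locus duplicates to plant in
#'   intergenic space (for off-target tests).
#' @return A validated list of class `fixtureSpec`.
#' @export
fixtureSpec <- function(n_contigs = 1L, contig_length = 50000L,
                        n_genes = 5L, exons_per_gene = 2L, seed = 42L,
                        planted_duplicates = 0L) {
  spec <- list(n_contigs = as.integer(n_contigs),
               contig_length = as.integer(contig_length),
               n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               seed = as.integer(seed),
               planted_duplicates = as.integer(planted_duplicates))
  if (spec$n_contigs < 1L || spec$n_genes < 1L || spec$exons_per_gene < 1L)
    .configError("n_contigs, n_genes and exons_per_gene must be >= 1")
  if (spec$seed < 0L) .configError("seed must be a non-negative integer")
  margin <- 3200L
  perContig <- ceiling(spec$n_genes / spec$n_contigs)
  maxGeneLen <- 3L * 320L + 6L + (spec$exons_per_gene - 1L) * 200L
  if ((spec$contig_length - 2L * margin) / perContig < maxGeneLen + 500L)
    .configError("contig_length %d too short for %d gene(s) per contig",
                 spec$contig_length, perContig)
  structure(spec, class = "fixtureSpec")
}

#' Generate the synthetic mini-genome
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory; when non-`NULL`, `genome.fa`, `genes.gff3`
#'   and `truth.tsv` are written there (byte-identical for equal specs).
#' @return List with `assembly` ([GenomeAssembly-class]), `truth` (a
#'   data.frame of per-gene coordinates), `cds` (named list of true
#'   spliced CDS strings), `planted` (data.frame of planted guide-locus
#'   duplicates), and — when `dir` is given — `fasta`, `gff3`, `truth_tsv`
#'   file paths.
#' @export
makeMiniGenome <- function(spec = fixtureSpec(), dir = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  res <- .withSeed(spec$seed, .generateGenome(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    res$fasta <- file.path(dir, "genome.fa")
    res$gff3 <- file.path(dir, "genes.gff3")
    res$truth_tsv <- file.path(dir, "truth.tsv")
    .writeFastaFile(res$assembly, res$fasta)
    .writeGffFile(res$gffRows, res$gff3)
    utils::write.table(res$truth, res$truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

.generateGenome <- function(spec) {
  margin <- 3200L
  stops <- c("TAA", "TAG", "TGA")
  contigs <- lapply(seq_len(spec$n_contigs), function(i)
    strsplit(.randomDna(spec$contig_length), "")[[1]])
  names(contigs) <- paste0("chr", seq_len(spec$n_contigs))

  truth <- list(); cdsSeqs <- list(); gffRows <- list()
  perContig <- ceiling(spec$n_genes / spec$n_contigs)
  spacing <- (spec$contig_length - 2L * margin) %/% perContig

  for (gi in seq_len(spec$n_genes)) {
    ci <- ((gi - 1L) %% spec$n_contigs) + 1L
    slot <- (gi - 1L) %/% spec$n_contigs
    contig <- names(contigs)[ci]
    strand <- if (gi %% 2L == 1L) "+" else "-"
    aa <- sample(160:320, 1L)
    cdsSeq <- paste0("ATG", .randomOrf(aa), sample(stops, 1L))
    total <- nchar(cdsSeq)
    k <- spec$exons_per_gene
    cutpts <- if (k > 1L) {
      pts <- sort(sample(seq(50L, total - 50L), k - 1L))
      while (any(diff(c(0L, pts, total)) < 50L))
        pts <- sort(sample(seq(50L, total - 50L), k - 1L))
      pts
    } else integer(0)
    bounds <- c(0L, cutpts, total)
    pieces <- vapply(seq_len(k), function(j)
      substr(cdsSeq, bounds[j] + 1L, bounds[j + 1L]), character(1))
    introns <- if (k > 1L) vapply(seq_len(k - 1L), function(j)
      paste0("GT", .randomDna(sample(56:196, 1L)), "AG"), character(1))
      else character(0)
    tx <- pieces[1]
    for (j in seq_along(introns)) tx <- paste0(tx, introns[j], pieces[j + 1L])
    L <- nchar(tx)
    start <- margin + slot * spacing + sample(0:400, 1L)
    genomicSeq <- if (strand == "+") tx else revComp(tx)
    contigs[[ci]][(start + 1L):(start + L)] <-
      strsplit(genomicSeq, "")[[1]]

    # transcript-strand offsets of the CDS pieces within tx
    offs <- integer(k); o <- 0L
    for (j in seq_len(k)) {
      offs[j] <- o
      o <- o + nchar(pieces[j]) +
        if (j <= length(introns)) nchar(introns[j]) else 0L
    }
    cds <- t(vapply(seq_len(k), function(j) {
      len <- nchar(pieces[j])
      as.integer(if (strand == "+") c(start + offs[j], start + offs[j] + len)
                 else c(start + L - offs[j] - len, start + L - offs[j]))
    }, integer(2)))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    gid <- paste0("g", gi)
    startCodon <- if (strand == "+") cds[1, 1] else cds[nrow(cds), 2] - 1L
    stopCodon <- if (strand == "+") cds[nrow(cds), 2] - 3L else
      cds[1, 1] + 2L
    truth[[gi]] <- data.frame(
      gene_id = gid, symbol = paste0("gene", gi), contig = contig,
      strand = strand, gene_start = start, gene_end = start + L,
      start_codon = startCodon, stop_codon = stopCodon,
      cds_length = total, n_exons = k, stringsAsFactors = FALSE)
    cdsSeqs[[gid]] <- cdsSeq
    g1 <- internalToGff(start, start + L)
    rows <- list(sprintf("%s\tmini\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=gene%d",
                         contig, g1[1], g1[2], strand, gid, gi),
                 sprintf("%s\tmini\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                         contig, g1[1], g1[2], strand, gid, gid))
    phase <- 0L
    cdsTx <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    for (j in seq_len(k)) {
      e1 <- internalToGff(cds[j, 1], cds[j, 2])
      rows[[length(rows) + 1L]] <-
        sprintf("%s\tmini\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                contig, e1[1], e1[2], strand, gid, j, gid)
    }
    for (jj in seq_len(k)) {
      j <- cdsTx[jj]  # transcript order for phase computation
      e1 <- internalToGff(cds[j, 1], cds[j, 2])
      rows[[length(rows) + 1L]] <-
        sprintf("%s\tmini\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds%d;Parent=%s.t1",
                contig, e1[1], e1[2], strand, phase, gid, jj, gid)
      phase <- (3L - ((cds[j, 2] - cds[j, 1]) - phase) %% 3L) %% 3L
    }
    gffRows[[gi]] <- unlist(rows)
  }

  assembly0 <- genomeAssembly(vapply(contigs, paste, character(1),
                                     collapse = ""))
  planted <- NULL
  if (spec$planted_duplicates > 0L) {
    t1 <- truth[[1]]
    sites <- scanGuides(assembly0, t1$contig, t1$start_codon, 30L)
    if (nrow(sites) == 0L)
      .configError("no guide near gene g1's start codon to duplicate")
    site <- sites[1L, , drop = FALSE]
    sp <- .siteSpan(site$pam_start, site$strand)
    dup <- substr(as.character(assembly0@sequences[[t1$contig]]),
                  sp$start + 1L, sp$end)
    ci <- match(t1$contig, names(contigs))
    for (d in seq_len(spec$planted_duplicates)) {
      at <- 1200L + (d - 1L) * 60L   # intergenic: genes start at `margin`
      contigs[[ci]][(at + 1L):(at + nchar(dup))] <- strsplit(dup, "")[[1]]
    }
    planted <- cbind(site, n_copies = spec$planted_duplicates,
                     planted_at = 1200L)
    assembly0 <- genomeAssembly(vapply(contigs, paste, character(1),
                                       collapse = ""))
  }

  list(assembly = assembly0, truth = do.call(rbind, truth),
       cds = cdsSeqs, planted = planted,
       gffRows = c("##gff-version 3", unlist(gffRows)))
}

.writeFastaFile <- function(assembly, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in contigNames(assembly)) {
    s <- as.character(assembly@sequences[[nm]])
    writeLines(c(paste0(">", nm),
                 substring(s, seq(1L, nchar(s), 70L),
                           pmin(seq(70L, nchar(s) + 69L, 70L), nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

.writeGffFile <- function(rows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}
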