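# Homology arms, silent PAM mutation, map assembly, Cre/LoxP simulation,
# frame validation and guide-oligo golden gate.

test_that("homology arms are exact plus-strand substrings around the anchor", {
  fx <- miniFixture()
  arms <- extractHomologyArms(fx$assembly, "chr1", 5000L, 1000L)
  expect_equal(c(arms$left$start, arms$left$end), c(4000L, 5000L))
  expect_equal(c(arms$right$start, arms$right$end), c(5000L, 6000L))
  expect_equal(nchar(arms$left$sequence), 1000L)
  expect_identical(paste0(arms$left$sequence, arms$right$sequence),
                   extractRegion(fx$assembly, "chr1", 4000, 6000, "+"))
  # cut pair for deletion designs
  arms2 <- extractHomologyArms(fx$assembly, "chr1", c(4000L, 7000L), 1000L)
  expect_equal(c(arms2$left$end, arms2$right$start), c(4000L, 7000L))
  # degenerate and clipped arms warn
  expect_warning(a0 <- extractHomologyArms(fx$assembly, "chr1", 5000L, 0L))
  expect_equal(a0$left$sequence, "")
  expect_warning(ac <- extractHomologyArms(fx$assembly, "chr1", 500L, 1000L),
                 "shortened")
  expect_equal(ac$left$start, 0L)
})

test_that("a coding PAM is disrupted by a synonymous codon change", {
  # engineered plus-strand locus: codon CCG (Pro) donates the first PAM G
  withr::local_seed(51L)
  k <- 12L
  body <- paste(sample(c("GCT", "AAA", "TCT", "CTT"), k - 1L,
                       replace = TRUE), collapse = "")
  cdsSeq <- paste0("ATG", body, "CCG", "GAT",
                   paste(sample(c("GCT", "AAA"), 20, replace = TRUE),
                         collapse = ""), "TAA")
  s0 <- 100L
  contig <- paste0(randomDnaStr(s0), cdsSeq, randomDnaStr(100))
  ga <- genomeAssembly(c(c = contig))
  cds <- cbind(s0, s0 + nchar(cdsSeq))
  iso <- new("IsoformModel", isoformId = "t1", contig = "c", strand = "+",
             exons = cds, cds = cds, startCodon = s0,
             stopCodon = s0 + nchar(cdsSeq) - 3L)
  ps <- s0 + 3L * k + 1L          # PAM = (C, G, G) over codons CCG|GAT
  expect_equal(substr(contig, ps + 1L, ps + 3L), "CGG")
  guide <- data.frame(protospacer = substr(contig, ps - 19L, ps),
                      pam = "CGG", strand = "+", contig = "c",
                      pam_start = ps, cut_pos = ps - 3L,
                      stringsAsFactors = FALSE)
  arm <- list(sequence = substr(contig, s0 + 1L, s0 + nchar(cdsSeq)),
              start = s0, end = s0 + nchar(cdsSeq))
  res <- mutatePamSilent(arm, guide, iso, ga, "c")
  expect_equal(res$report$codon_before, "CCG")
  expect_equal(res$report$codon_after, "CCA")
  expect_equal(res$report$aa, "P")
  expect_equal(res$report$kind, "PAM")
  # PAM no longer NGG in the mutated arm
  rel <- ps - s0
  expect_identical(substr(res$arms$sequence, rel + 2L, rel + 3L), "AG")
  # translation unchanged (independent oracle)
  expect_identical(translateOracle(res$arms$sequence),
                   translateOracle(arm$sequence))
})

test_that("a fully non-coding PAM gets a direct substitution", {
  withr::local_seed(52L)
  contig <- paste0(randomDnaStr(60), "TGG", randomDnaStr(60))
  ga <- genomeAssembly(c(c = contig))
  ps <- 60L
  guide <- data.frame(protospacer = substr(contig, ps - 19L, ps),
                      pam = "TGG", strand = "+", contig = "c",
                      pam_start = ps, cut_pos = ps - 3L,
                      stringsAsFactors = FALSE)
  arm <- list(sequence = contig, start = 0L, end = nchar(contig))
  res <- mutatePamSilent(arm, guide, NULL, ga, "c")
  expect_equal(res$report$context, "non-coding")
  expect_equal(res$report$ref, "G")
  expect_equal(res$report$alt, "T")
})

test_that("an undisruptable site raises a hard design error", {
  # every codon is Trp or Met: no synonymous change exists anywhere
  cdsSeq <- paste0("ATG", strrep("TGG", 30), "TAA")
  s0 <- 30L
  contig <- paste0(strrep("AC", 15), cdsSeq, strrep("CA", 15))
  ga <- genomeAssembly(c(c = contig))
  cds <- cbind(s0, s0 + nchar(cdsSeq))
  iso <- new("IsoformModel", isoformId = "t1", contig = "c", strand = "+",
             exons = cds, cds = cds, startCodon = s0,
             stopCodon = s0 + nchar(cdsSeq) - 3L)
  ps <- s0 + 3L + 3L * 8L          # a TGG codon acting as the NGG PAM
  expect_identical(substr(contig, ps + 1L, ps + 3L), "TGG")
  guide <- data.frame(protospacer = substr(contig, ps - 19L, ps),
                      pam = "TGG", strand = "+", contig = "c",
                      pam_start = ps, cut_pos = ps - 3L,
                      stringsAsFactors = FALSE)
  arm <- list(sequence = cdsSeq, start = s0, end = s0 + nchar(cdsSeq))
  expect_error(mutatePamSilent(arm, guide, iso, ga, "c"),
               "pick another guide", class = "designError")
})

test_that("tagging maps obey the conservation length identity", {
  cd <- cachedDesign("N")
  d <- cd$design
  tpl <- resolveVector("pHD-SspB-ExLK-EGFP-DsRed")
  payloadLen <- tpl@rightArmSlot[1] - tpl@leftArmSlot[2]
  expect_equal(nchar(mapSequence(d$edited$genomic)),
               nchar(mapSequence(d$locus)) + payloadLen)
  # the unaltered locus map is the exact genomic region
  fx <- miniFixture()
  md <- d$edited$genomic@metadata
  lb0 <- md$locus_offset
  expect_identical(mapSequence(d$locus),
                   extractRegion(fx$assembly, cd$gene@contig, lb0,
                                 lb0 + nchar(mapSequence(d$locus)), "+"))
})

test_that("edited-map features map back to genome or vector coordinates", {
  cd <- cachedDesign("N")
  d <- cd$design
  fx <- miniFixture()
  md <- d$edited$genomic@metadata
  ipl <- md$insertion_point - md$locus_offset
  K <- md$insert_len
  es <- mapSequence(d$edited$genomic)
  tpl <- resolveVector("pHD-SspB-ExLK-EGFP-DsRed")
  payload <- substr(tpl@sequence, tpl@leftArmSlot[2] + 1L,
                    tpl@rightArmSlot[1])
  ft <- mapFeatures(d$edited$genomic)
  for (i in seq_len(nrow(ft))) {
    seg <- substr(es, ft$start[i] + 1L, ft$end[i])
    inPayload <- ft$start[i] >= ipl && ft$end[i] <= ipl + K
    if (inPayload) {
      hay <- if (cd$gene@strand == "+") payload else revComp(payload)
      expect_true(grepl(seg, hay, fixed = TRUE),
                  label = sprintf("payload feature '%s'", ft$label[i]))
    } else if (ft$end[i] <= ipl || ft$start[i] >= ipl + K) {
      # pure genomic feature: must match the genome up to the silent edits
      off <- if (ft$start[i] >= ipl + K) K else 0L
      gseq <- extractRegion(fx$assembly, cd$gene@contig,
                            ft$start[i] - off + md$locus_offset,
                            ft$end[i] - off + md$locus_offset, "+")
      mismatches <- sum(strsplit(seg, "")[[1]] != strsplit(gseq, "")[[1]])
      expect_lte(mismatches, nrow(d$mutation_report))
    }
  }
})

test_that("deletion maps obey the replacement length identity", {
  fx <- miniFixture()
  g2 <- fx$genes[["g2"]]
  iso <- suppressWarnings(selectIsoform(g2))
  idx <- sharedIndex(fx$assembly, "fx42")
  rN <- suppressWarnings(rankGuides(annotateGuides(
    scanGuides(fx$assembly, g2@contig, startCodon(iso), 20),
    fx$assembly, index = idx)))
  rC <- suppressWarnings(rankGuides(annotateGuides(
    scanGuides(fx$assembly, g2@contig, stopCodon(iso), 20),
    fx$assembly, index = idx)))
  gN <- rN[1, , drop = FALSE]; gC <- rC[1, , drop = FALSE]
  if (gN$cut_pos > gC$cut_pos) { t2 <- gN; gN <- gC; gC <- t2 }
  d <- suppressWarnings(buildDeletionMaps(
    fx$assembly, g2, gN, gC, "pHD-DsRed-attP", isoform = iso,
    primers = list(N = noPrimers, C = noPrimers)))
  tpl <- resolveVector("pHD-DsRed-attP")
  K <- tpl@rightArmSlot[1] - tpl@leftArmSlot[2]
  expect_equal(nchar(mapSequence(d$edited$genomic)),
               nchar(mapSequence(d$locus)) - (gC$cut_pos - gN$cut_pos) + K)
  ft <- mapFeatures(d$edited$genomic)
  delFeat <- ft[ft$label == "deletion cassette", ]
  expect_equal(nrow(delFeat), 1L)
  expect_match(delFeat$note, "g2")
  expect_match(delFeat$note, sprintf("%d, %d", gN$cut_pos, gC$cut_pos))
  # inverted or equal cuts are rejected
  expect_error(buildDeletionMaps(fx$assembly, g2, gC, gN, "pHD-DsRed",
                                 isoform = iso),
               class = "inputError")
  expect_error(buildDeletionMaps(fx$assembly, g2, gN, gN, "pHD-DsRed",
                                 isoform = iso),
               class = "inputError")
})

test_that("flox excises marker plus one LoxP; refloxing errors", {
  tpls <- loadBuiltinVectors()
  tpl <- tpls[["pHD-SspB-ExLK-EGFP-DsRed"]]
  m <- assemblyMap(tpl@name, tpl@sequence, "circular", tpl@features)
  fl <- simulateFlox(m)
  removed <- unname(tpl@loxpSpans[2, 1] - tpl@loxpSpans[1, 1])
  expect_equal(nchar(mapSequence(fl)), nchar(tpl@sequence) - removed)
  expect_equal(sum(mapFeatures(fl)$label == "loxP"), 1L)
  loxFt <- mapFeatures(fl)[mapFeatures(fl)$label == "loxP", ]
  expect_equal(loxFt$end - loxFt$start, 34L)
  expect_error(simulateFlox(fl), class = "inputError")
})

test_that("floxed designs stay in frame; a 1-bp shift is caught", {
  for (term in c("N", "C")) {
    cd <- cachedDesign(term)
    fl <- simulateFlox(cd$design$edited$genomic)
    rep <- validateFrame(fl, cd$iso, term)
    expect_true(rep$pass)
    expect_equal(rep$frame_offset, 0L)
    expect_equal(rep$insert_len %% 3L, 0L)
    # junction peptide equals an independent translation oracle
    md <- fl@metadata
    ipl <- md$insertion_point - md$locus_offset
    resid <- substr(mapSequence(fl), ipl + 1L, ipl + md$insert_len)
    if (cd$gene@strand == "-") resid <- rcOracle(resid)
    cdsStr <- miniFixture()$fx$cds[[geneId(cd$gene)]]
    fusion <- if (term == "N")
      paste0(substr(cdsStr, 1, 3), resid, substr(cdsStr, 4, nchar(cdsStr)))
    else
      paste0(substr(cdsStr, 1, nchar(cdsStr) - 3L), resid,
             substr(cdsStr, nchar(cdsStr) - 2L, nchar(cdsStr)))
    aa <- translateOracle(fusion)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
    expect_true(grepl(rep$peptide, aa, fixed = TRUE))
  }
  # force a frame shift: one extra base in the payload must fail
  cd <- cachedDesign("N")
  fl <- simulateFlox(cd$design$edited$genomic)
  md <- fl@metadata
  ipl <- md$insertion_point - md$locus_offset
  s <- mapSequence(fl)
  broken <- assemblyMap(fl@name, paste0(substr(s, 1, ipl + 10L), "A",
                                        substr(s, ipl + 11L, nchar(s))),
                        "linear", metadata = within(md, insert_len <- insert_len + 1L))
  repBad <- validateFrame(broken, cd$iso, "N")
  expect_false(repBad$pass)
  expect_equal(repBad$frame_offset, 1L)
})

test_that("the guide no longer matches the donor at zero mismatches", {
  for (term in c("N", "C")) {
    cd <- cachedDesign(term)
    site <- paste0(cd$guide$protospacer, cd$guide$pam)
    for (s in c(mapSequence(cd$design$edited$genomic),
                mapSequence(cd$design$edited$donor))) {
      expect_false(grepl(site, s, fixed = TRUE))
      expect_false(grepl(rcOracle(site), s, fixed = TRUE))
    }
    # and the translated arm CDS is unchanged: frame check passed above
    expect_gte(nrow(cd$design$mutation_report), 1L)
  }
})

test_that("guide oligos follow the overhang rule and reassemble the vector", {
  gG <- data.frame(protospacer = "GACGATCGATCGATCGATCA", pam = "AGG",
                   strand = "+", contig = "c", pam_start = 120L,
                   cut_pos = 117L, stringsAsFactors = FALSE)
  res <- designGuideOligos(gG)
  expect_equal(res$forward, "CTTCGACGATCGATCGATCGATCA")
  expect_equal(res$reverse, paste0("AAAC", rcOracle("ACGATCGATCGATCGATCA"),
                                   "C"))
  # annealed core: revcomp(reverse minus overhang) == forward minus overhang
  expect_identical(rcOracle(substr(res$reverse, 5, nchar(res$reverse))),
                   substr(res$forward, 5, nchar(res$forward)))
  # non-G protospacer gains a 5' G
  gA <- gG; gA$protospacer <- "ACGATCGATCGATCGATCAT"
  resA <- designGuideOligos(gA)
  expect_equal(resA$forward, paste0("CTTCG", gA$protospacer))
  expect_equal(nchar(resA$reverse), 25L)

  # golden-gate product: spacer exactly once, downstream of the U6
  # promoter, and no residual BbsI recognition site
  m <- res$map
  s <- mapSequence(m)
  hits <- gregexpr("GACGATCGATCGATCGATCA", s, fixed = TRUE)[[1]]
  expect_length(hits, 1L)
  ft <- mapFeatures(m)
  u6 <- ft[ft$label == "U6 promoter", ]
  expect_lt(u6$end, hits[1])
  expect_false(grepl("GAAGAC", s, fixed = TRUE))
  expect_false(grepl("GTCTTC", s, fixed = TRUE))
  expect_equal(mapTopology(m), "circular")
  # a vector without BbsI sites is rejected
  expect_error(designGuideOligos(gG, "pHD-DsRed"), class = "vectorError")
})
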