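# Genome FASTA/GFF3 parsing, coordinate conventions, region extraction.

test_that("parseFasta normalizes case, keeps N, and rejects bad records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ACGT"), fa)
  expect_equal(unname(contigLengths(parseFasta(fa))), 4L)
  expect_equal(as.character(parseFasta(fa)@sequences[["chrT"]]), "ACGT")

  writeLines(c(">chrT desc text", "acgtn", "ACGT"), fa)
  ga <- parseFasta(fa)
  expect_equal(contigNames(ga), "chrT")   # header truncated at whitespace
  expect_equal(as.character(ga@sequences[["chrT"]]), "ACGTNACGT")

  writeLines(c(">good", "ACGT", ">bad", "ACXGT"), fa)
  expect_error(parseFasta(fa), "bad", class = "formatError")

  writeLines(c(">empty", "", ">ok", "ACGT"), fa)
  expect_error(parseFasta(fa), "empty", class = "formatError")
})

test_that("extractRegion honors strand and bounds", {
  ga <- genomeAssembly(c(chrT = "ACGTT"))
  expect_equal(extractRegion(ga, "chrT", 0, 5, "-"), "AACGT")
  expect_equal(extractRegion(ga, "chrT", 0, 5, "+"), "ACGTT")
  expect_equal(extractRegion(ga, "chrT", 3, 3, "+"), "")
  expect_error(extractRegion(ga, "chrT", 0, 6), class = "rangeError")
  expect_error(extractRegion(ga, "chrT", -1, 3), class = "rangeError")
  expect_error(extractRegion(ga, "nope", 0, 1), class = "rangeError")
})

test_that("reverse complement round-trips on random sequences", {
  withr::local_seed(11L)
  for (i in 1:20) {
    s <- randomDnaStr(sample(1:200, 1))
    expect_identical(revComp(revComp(s)), s)
    expect_identical(revComp(s), rcOracle(s))
  }
})

test_that("GFF3 <-> internal coordinate conversion is the identity", {
  withr::local_seed(7L)
  start1 <- sample(1:1000000, 1000, replace = TRUE)
  end1 <- start1 + sample(0:5000, 1000, replace = TRUE)
  internal <- gffToInternal(start1, end1)
  back <- internalToGff(internal[, "start"], internal[, "end"])
  expect_identical(back[, "start"], as.integer(start1))
  expect_identical(back[, "end"], as.integer(end1))
  # widths agree: GFF3 inclusive width = internal half-open width
  expect_identical(internal[, "end"] - internal[, "start"],
                   as.integer(end1 - start1 + 1L))
})

test_that("fixture gene models parse, validate and match the generator's truth", {
  fx <- miniFixture()
  expect_setequal(names(fx$genes), fx$fx$truth$gene_id)
  for (gid in names(fx$genes)) {
    g <- fx$genes[[gid]]
    iso <- suppressWarnings(selectIsoform(g))
    tr <- fx$fx$truth[fx$fx$truth$gene_id == gid, ]
    expect_equal(g@strand, tr$strand)
    expect_equal(startCodon(iso), tr$start_codon)
    expect_equal(stopCodon(iso), tr$stop_codon)
    # spliced CDS equals the generator's stored CDS string exactly
    spliced <- splicedCds(fx$assembly, g@contig, g@strand,
                          cdsIntervals(iso))
    expect_identical(spliced, fx$fx$cds[[gid]])
    # translates without internal stop (independent codon-table oracle)
    aa <- translateOracle(spliced)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
    expect_true(endsWith(aa, "*"))
  }
})

test_that("minus-strand start codon is the numerically largest CDS base", {
  fx <- miniFixture()
  minus <- Filter(function(g) g@strand == "-", fx$genes)
  expect_gt(length(minus), 0L)
  for (g in minus) {
    iso <- suppressWarnings(selectIsoform(g))
    expect_equal(startCodon(iso), max(cdsIntervals(iso)[, 2]) - 1L)
  }
})

test_that("annotation errors name the offender", {
  fx <- miniFixture()
  gff <- withr::local_tempfile(fileext = ".gff3")
  # an otherwise valid annotation with one dangling Parent reference
  writeLines(c(readLines(fx$fx$gff3),
               "chr1\tx\tCDS\t100\t199\t.\t+\t0\tID=cX;Parent=missing"),
             gff)
  expect_error(suppressWarnings(parseGff3(gff, fx$assembly)), "missing",
               class = "annotationError")

  # CDS length not divisible by 3
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t101\t104\t.\t+\t.\tID=gB",
               "chr1\tx\tmRNA\t101\t104\t.\t+\t.\tID=gB.t1;Parent=gB",
               "chr1\tx\tCDS\t101\t104\t.\t+\t0\tID=c2;Parent=gB.t1"),
             gff)
  expect_error(parseGff3(gff, fx$assembly), "gB.t1",
               class = "annotationError")
})
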