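# SpCas9 site scanning and off-target counting against brute-force
# oracles.

test_that("a single engineered NGG site is found with correct geometry", {
  ga <- genomeAssembly(c(t1 = "GACGATCGATCGATCGATCAAGG"))
  sites <- suppressWarnings(scanGuides(ga, "t1", 20, 23))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$protospacer, "GACGATCGATCGATCGATCA")
  expect_equal(sites$pam, "AGG")
  expect_equal(sites$strand, "+")
  expect_equal(sites$pam_start, 20L)
  expect_equal(sites$cut_pos, 17L)
})

test_that("poly-A sequence yields no guide sites", {
  ga <- genomeAssembly(c(a = strrep("A", 300)))
  expect_equal(nrow(scanGuides(ga, "a", 150, 50)), 0L)
})

test_that("cut position follows SpCas9 blunt-cut geometry", {
  expect_equal(cutPosition(100, "+"), 97L)
  expect_equal(cutPosition(100, "-"), 103L)
  expect_error(cutPosition(100, "x"), class = "inputError")
  # the cut always lies inside the protospacer interval
  withr::local_seed(5L)
  for (i in 1:50) {
    ps <- sample(30:5000, 1); st <- sample(c("+", "-"), 1)
    cut <- cutPosition(ps, st)
    span <- if (st == "+") c(ps - 20L, ps) else c(ps + 1L, ps + 21L)
    expect_true(cut >= span[1] && cut < span[2])
  }
})

test_that("scanner matches a brute-force enumeration on random sequences", {
  withr::local_seed(101L)
  for (i in 1:25) {
    n <- sample(200:1200, 1)
    s <- randomDnaStr(n)
    ga <- genomeAssembly(c(chr = s))
    anchor <- sample(50:(n - 50), 1)
    window <- sample(c(20L, 60L, 150L), 1)
    got <- suppressWarnings(scanGuides(ga, "chr", anchor, window))
    want <- bruteScan(s, "chr", anchor, window)
    expect_equal(got[, c("protospacer", "pam", "strand", "pam_start")],
                 want[, c("protospacer", "pam", "strand", "pam_start")])
  }
})

test_that("scan of the fixture start codon equals the brute-force oracle", {
  fx <- miniFixture()
  g1 <- fx$genes[["g1"]]
  iso <- suppressWarnings(selectIsoform(g1))
  got <- scanGuides(fx$assembly, g1@contig, startCodon(iso), 100)
  s <- as.character(fx$assembly@sequences[[g1@contig]])
  want <- bruteScan(s, g1@contig, startCodon(iso), 100)
  expect_equal(got[, c("protospacer", "pam", "strand", "pam_start",
                       "cut_pos")],
               want[, c("protospacer", "pam", "strand", "pam_start",
                        "cut_pos")])
})

test_that("scanning the reverse complement flips strands and mirrors", {
  withr::local_seed(202L)
  s <- randomDnaStr(800)
  ga1 <- genomeAssembly(c(chr = s))
  ga2 <- genomeAssembly(c(chr = revComp(s)))
  a <- suppressWarnings(scanGuides(ga1, "chr", 400, 400))
  b <- suppressWarnings(scanGuides(ga2, "chr", 399, 400))
  keyA <- sort(paste(a$protospacer, a$pam))
  keyB <- sort(paste(b$protospacer, b$pam))
  expect_identical(keyA, keyB)
  # strands flip one-to-one
  expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
})

test_that("off-target counts equal an exhaustive Hamming oracle", {
  withr::local_seed(303L)
  s <- randomDnaStr(2500)
  ga <- genomeAssembly(c(c1 = s))
  idx <- buildOfftargetIndex(ga)
  cand <- bruteAllSites(ga)
  sites <- suppressWarnings(scanGuides(ga, "c1", 1250, 300))
  expect_gt(nrow(sites), 3L)
  for (i in seq_len(min(8L, nrow(sites)))) {
    g <- sites[i, , drop = FALSE]
    got <- countOfftargets(g, ga, index = idx)
    want <- bruteOfftargets(g, cand)
    expect_identical(got, want)
  }
})

test_that("a guide unique in the genome has zero exact off-targets", {
  ga <- genomeAssembly(c(t1 = paste0(strrep("AT", 50),
                                     "GACGATCGATCGATCGATCAAGG",
                                     strrep("TA", 50))))
  sites <- suppressWarnings(scanGuides(ga, "t1", 117, 120))
  g <- sites[sites$protospacer == "GACGATCGATCGATCGATCA", , drop = FALSE]
  expect_equal(nrow(g), 1L)
  expect_equal(countOfftargets(g, ga)[["ot0"]], 0L)
})

test_that("a planted duplicate locus is counted as one exact off-target", {
  fx <- miniFixture(seed = 42L, planted = 1L)
  planted <- fx$fx$planted
  expect_equal(planted$n_copies, 1L)
  got <- countOfftargets(planted[, 1:5], fx$assembly)
  expect_equal(got[["ot0"]], 1L)
})

test_that("off-target counts are invariant under contig relabeling and order", {
  withr::local_seed(404L)
  s1 <- randomDnaStr(900); s2 <- randomDnaStr(700)
  gaA <- genomeAssembly(c(x = s1, y = s2))
  gaB <- genomeAssembly(c(beta = s2, alpha = s1))
  sites <- suppressWarnings(scanGuides(gaA, "x", 450, 200))
  g <- sites[1, , drop = FALSE]
  a <- countOfftargets(g, gaA)
  g2 <- g; g2$contig <- "alpha"
  b <- countOfftargets(g2, gaB)
  expect_identical(a, b)
})
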