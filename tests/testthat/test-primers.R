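# Melting temperature, primer windows and pair selection.

test_that("Wallace rule Tm and its base-count symmetry", {
  expect_equal(meltingTemp("ACGTACGTACGTACGTACGT", method = "wallace"), 60)
  withr::local_seed(21L)
  for (i in 1:10) {
    s <- randomDnaStr(sample(10:30, 1))
    expect_equal(meltingTemp(s, method = "wallace"),
                 meltingTemp(revComp(s), method = "wallace"))
  }
  expect_error(meltingTemp("ACGTNACGT"), class = "inputError")
  expect_error(meltingTemp("ACG"), class = "inputError")
})

test_that("nearest-neighbor Tm matches an independent re-summation", {
  withr::local_seed(22L)
  for (i in 1:20) {
    s <- randomDnaStr(20)
    expect_equal(meltingTemp(s, method = "nn"), nnTmOracle(s),
                 tolerance = 0.01)
  }
  # parameters flow through
  s <- randomDnaStr(22)
  expect_equal(meltingTemp(s, params = list(conc_nM = 250, na_mM = 100)),
               nnTmOracle(s, conc_nM = 250, na_mM = 100), tolerance = 0.01)
})

test_that("primer windows sit 400-600 and 1000-1200 bp from the cut", {
  w <- primerWindows(5000, c(0, 10000))
  expect_equal(c(w$upstream_far$start, w$upstream_far$end), c(3800, 4000))
  expect_equal(c(w$upstream_near$start, w$upstream_near$end), c(4400, 4600))
  expect_equal(c(w$downstream_near$start, w$downstream_near$end),
               c(5400, 5600))
  expect_equal(c(w$downstream_far$start, w$downstream_far$end),
               c(6000, 6200))
  expect_equal(w$upstream_far$role, "amplification")
  expect_equal(w$downstream_near$role, "sequencing")

  # window fully outside the locus comes back empty with a warning
  warns <- testthat::capture_warnings(w2 <- primerWindows(100, c(0, 10000)))
  expect_true(any(grepl("upstream_far", warns)))
  expect_equal(w2$upstream_far$end, w2$upstream_far$start)
  # partial overlap is clipped
  w3 <- suppressWarnings(primerWindows(1100, c(0, 10000)))
  expect_equal(c(w3$upstream_far$start, w3$upstream_far$end), c(0, 100))
})

test_that("candidate filtering equals a brute-force enumeration oracle", {
  withr::local_seed(23L)
  s <- randomDnaStr(2000)
  ga <- genomeAssembly(c(z = s))
  cfg <- designConfig()
  win <- list(start = 400L, end = 600L, role = "sequencing",
              side = "upstream")
  res <- suppressWarnings(pickPrimerPairs(ga, "z", list(upstream_near = win),
                                          cfg))
  # oracle: enumerate every (position, length), filter sequentially
  pass <- list(); counts <- c(gc = 0L, homo = 0L, tm = 0L, self3 = 0L)
  for (p in 400:599) {
    for (L in 18:27) {
      seqp <- substr(s, p + 1L, p + L)
      gc <- sum(strsplit(seqp, "")[[1]] %in% c("G", "C")) / L
      if (gc < 0.30 || gc > 0.70) { counts["gc"] <- counts["gc"] + 1L; next }
      if (grepl("AAAAA|CCCCC|GGGGG|TTTTT", seqp)) {
        counts["homo"] <- counts["homo"] + 1L; next
      }
      tm <- nnTmOracle(seqp)
      if (tm < 57 || tm > 63) { counts["tm"] <- counts["tm"] + 1L; next }
      s3 <- 0L
      for (k in 1:12) {
        suf <- substr(seqp, L - k + 1L, L)
        if (identical(suf, rcOracle(suf))) s3 <- k
      }
      if (s3 > 3L) { counts["self3"] <- counts["self3"] + 1L; next }
      pass[[length(pass) + 1L]] <- c(p, L)
    }
  }
  expect_equal(nrow(res$candidates), length(pass))
  expect_equal(res$diagnostics$fail_gc, unname(counts["gc"]))
  expect_equal(res$diagnostics$fail_homopolymer, unname(counts["homo"]))
  expect_equal(res$diagnostics$fail_tm, unname(counts["tm"]))
  expect_equal(res$diagnostics$fail_self3, unname(counts["self3"]))
})

test_that("amplification pairs respect windows, product size and determinism", {
  fx <- miniFixture()
  g1 <- fx$genes[["g1"]]
  iso <- suppressWarnings(selectIsoform(g1))
  cut <- startCodon(iso)
  cfg <- designConfig()
  lb <- c(cut - 2000L, cut + 2000L)
  w <- primerWindows(cut, lb, cfg)
  res <- pickPrimerPairs(fx$assembly, g1@contig, w, cfg)
  expect_gt(nrow(res$pairs), 0L)
  chr <- as.character(fx$assembly@sequences[[g1@contig]])
  for (i in seq_len(nrow(res$pairs))) {
    p <- res$pairs[i, ]
    # forward 5' end in the upstream far window
    expect_true(p$fwd_genomic_start >= w$upstream_far$start &&
                p$fwd_genomic_start < w$upstream_far$end)
    expect_true(p$rev_genomic_start >= w$downstream_far$start &&
                p$rev_genomic_start < w$downstream_far$end)
    # primers are exact (revcomp) substrings of the genome
    expect_identical(substr(chr, p$fwd_genomic_start + 1L,
                            p$fwd_genomic_start + p$fwd_length),
                     p$fwd_sequence)
    expect_identical(rcOracle(substr(chr, p$rev_genomic_start - p$rev_length + 2L,
                                     p$rev_genomic_start + 1L)),
                     p$rev_sequence)
    expect_equal(p$product_size,
                 p$rev_genomic_start + 1L - p$fwd_genomic_start)
    # the amplicon contains both 1000-bp homology arms around the cut
    expect_lte(p$fwd_genomic_start, cut - 1000L)
    expect_gte(p$rev_genomic_start + 1L, cut + 1000L)
  }
  # sequencing primers lie strictly inside the top amplification product
  top <- res$pairs[1, ]
  for (i in seq_len(nrow(res$sequencing))) {
    sq <- res$sequencing[i, ]
    expect_gt(sq$genomic_start, top$fwd_genomic_start)
    expect_lt(sq$genomic_start, top$rev_genomic_start)
  }
  res2 <- pickPrimerPairs(fx$assembly, g1@contig, w, cfg)
  expect_identical(res, res2)
})

test_that("impossible constraint ranges are rejected", {
  fx <- miniFixture()
  cfg <- designConfig()
  cfg$primer_tm <- c(70, 60)
  w <- primerWindows(5000, c(0, 10000))
  expect_error(pickPrimerPairs(fx$assembly, "chr1", w, cfg),
               class = "configError")
  expect_error(designConfig(amp_window = c(1200, 1000)),
               class = "configError")
})
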