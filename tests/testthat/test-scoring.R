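# Position-weight efficiency scoring and composite guide ranking.

emptyMatrix <- function(fill = 0) {
  w <- matrix(fill, 20, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  new("EfficiencyMatrix", weights = w, name = "test",
      provenance = character(0))
}

fakeSite <- function(protospacer = strrep("A", 20), efficiency = 1,
                     ot = c(0L, 0L, 0L, 0L), dist = 0L, cut = 100L,
                     ps = 120L, strand = "+") {
  data.frame(protospacer = protospacer, pam = "AGG", strand = strand,
             contig = "c", pam_start = ps, cut_pos = cut,
             anchor_distance = dist, efficiency = efficiency,
             ot0 = ot[1], ot1 = ot[2], ot2 = ot[3], ot3 = ot[4],
             ot_total = sum(ot[2:4]), has_exact_offtarget = ot[1] > 0L,
             stringsAsFactors = FALSE)
}

test_that("efficiency score is the per-position weight sum", {
  p <- strrep("ACGT", 5)
  expect_equal(efficiencyScore(p, emptyMatrix(0)), 0)
  m <- emptyMatrix(0); m@weights[1, "A"] <- 1
  expect_equal(efficiencyScore(paste0("A", strrep("C", 19)), m), 1)
  expect_equal(efficiencyScore(paste0("C", strrep("C", 19)), m), 0)

  # random protospacers vs a hand-rolled sum
  withr::local_seed(9L)
  m2 <- emptyMatrix(); m2@weights[] <- round(runif(80), 3)
  for (i in 1:10) {
    p <- randomDnaStr(20)
    b <- strsplit(p, "")[[1]]
    want <- 0
    for (j in 1:20) want <- want + as.numeric(m2@weights[j, b[j]])
    expect_equal(efficiencyScore(p, m2), want)
  }
  expect_error(efficiencyScore("ACGT"), class = "inputError")
  expect_error(efficiencyScore(strrep("N", 20)), class = "inputError")
})

test_that("increasing a weight never decreases a matching score", {
  withr::local_seed(10L)
  m <- emptyMatrix(); m@weights[] <- runif(80)
  for (i in 1:15) {
    p <- randomDnaStr(20)
    pos <- sample(20, 1); base <- substr(p, pos, pos)
    m2 <- m; m2@weights[pos, base] <- m2@weights[pos, base] + runif(1)
    expect_gte(efficiencyScore(p, m2), efficiencyScore(p, m))
  }
})

test_that("ranking follows efficiency, then off-target burden, then distance", {
  a <- fakeSite(efficiency = 5, cut = 100L, ps = 120L)
  b <- fakeSite(efficiency = 3, cut = 101L, ps = 121L)
  r <- rankGuides(rbind(b, a))
  expect_equal(r$efficiency, c(5, 3))

  a <- fakeSite(efficiency = 4, ot = c(0L, 0L, 0L, 0L), cut = 100L)
  b <- fakeSite(efficiency = 4, ot = c(0L, 3L, 2L, 2L), cut = 101L)
  r <- rankGuides(rbind(b, a))
  expect_equal(r$ot_total, c(0L, 7L))

  # exact off-target sites are demoted to the end but kept and flagged
  a <- fakeSite(efficiency = 9, ot = c(2L, 0L, 0L, 0L), cut = 100L)
  b <- fakeSite(efficiency = 1, ot = c(0L, 0L, 0L, 0L), cut = 101L)
  r <- rankGuides(rbind(a, b))
  expect_equal(r$efficiency, c(1, 9))
  expect_equal(r$has_exact_offtarget, c(FALSE, TRUE))
})

test_that("ranking matches an independent comparator on a 10-site table", {
  withr::local_seed(12L)
  sites <- do.call(rbind, lapply(1:10, function(i)
    fakeSite(efficiency = sample(1:4, 1),
             ot = c(sample(0:1, 1), sample(0:3, 1), sample(0:3, 1), 0L),
             dist = sample(-15:15, 1), cut = 100L + i, ps = 120L + i)))
  r <- rankGuides(sites)
  key <- with(sites, order(has_exact_offtarget, -efficiency, ot_total,
                           abs(anchor_distance), cut_pos, pam_start,
                           strand))
  expect_equal(r$cut_pos, sites$cut_pos[key])
  # permutation of the input; re-ranking is the identity
  expect_setequal(r$cut_pos, sites$cut_pos)
  r2 <- rankGuides(r)
  expect_equal(r2[, names(r)], r[, names(r)])
  expect_equal(nrow(rankGuides(sites[0, ])), 0L)
})

test_that("matrix files parse with provenance and reject malformed input", {
  m <- defaultEfficiencyMatrix()
  expect_s4_class(m, "EfficiencyMatrix")
  expect_true(any(grepl("stand-in", m@provenance)))
  expect_equal(dim(m@weights), c(20L, 4L))

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test matrix", "A C G T",
               vapply(1:20, function(i) "0.1 0.2 0.3 0.4", character(1))),
             f)
  m2 <- readEfficiencyMatrix(f)
  expect_equal(unname(m2@weights[5, ]), c(0.1, 0.2, 0.3, 0.4))
  writeLines(c("A C G T", "0.1 0.2"), f)
  expect_error(readEfficiencyMatrix(f), class = "formatError")
})
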