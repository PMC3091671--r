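# In-silico digestion: cut-site detection, complete digestion, size
# selection, and the second tier.

test_that("cut sites match the worked examples and a brute-force scan", {
  e <- tier1Enzymes()
  expect_equal(findCutSites("AAGGCCTT", e$HaeIII), 4L)
  expect_equal(findCutSites("AATATT", e$SspI), 3L)
  expect_equal(findCutSites("TTTTTT", e$HaeIII), integer())
  # overlapping occurrences: GGGCCC has GGCC at 2 and nothing else; GGCCGGCC twice
  expect_equal(findCutSites("GGCCGGCC", e$HaeIII), c(2L, 6L))

  set.seed(31)
  s <- randomDna(10000)
  for (enz in e)
    expect_equal(findCutSites(s, enz),
                 cutSitesOracle(s, enzymeMotif(enz), enzymeCutOffset(enz)),
                 info = enzymeName(enz))
})

test_that("non-palindromic enzymes are rejected", {
  expect_error(RestrictionEnzyme("EcoP15I", "CAGCAG", 2L), "palindromic")
})

test_that("complete digestion reconstructs the input and honors the cut union", {
  e <- tier1Enzymes()
  f <- digestSeq("AAGGCCTT", list(e$HaeIII))
  expect_equal(unname(as.character(fragmentSeqs(f))), c("AAGG", "CCTT"))

  none <- digestSeq("TTTTCTTT", list(e$HaeIII))
  expect_equal(length(none), 1L)
  expect_equal(unname(as.character(fragmentSeqs(none))), "TTTTCTTT")

  set.seed(17)
  for (rep in 1:5) {
    s <- randomDna(8000)
    f <- digestSeq(s, e)
    # reconstruction
    expect_identical(paste(as.character(fragmentSeqs(f)), collapse = ""), s)
    # multi-enzyme digest == digest from the merged cut set
    cuts <- sort(unique(unlist(lapply(e, function(z) findCutSites(s, z)))))
    bounds <- c(0L, cuts, nchar(s))
    expect_equal(unname(fragmentWidths(f)), diff(bounds))
    # coordinates are faithful: seq == source[start:end]
    info <- fragmentInfo(f)
    expect_identical(unname(as.character(fragmentSeqs(f))),
                     substring(s, info$start, info$end))
  }
})

test_that("digestion is idempotent and strand-symmetric", {
  e <- tier1Enzymes()
  set.seed(53)
  s <- randomDna(6000)
  f <- digestSeq(s, e)
  # re-digesting each fragment with the same enzymes leaves it whole
  redigested <- lapply(as.character(fragmentSeqs(f)),
                       function(x) length(digestSeq(x, e)))
  expect_true(all(unlist(redigested) == 1L))
  # palindromic enzymes: the reverse complement digests into mirrored pieces
  frc <- digestSeq(revcompOracle(s), e)
  expect_equal(unname(fragmentWidths(frc)), rev(unname(fragmentWidths(f))))
  expect_equal(unname(as.character(fragmentSeqs(frc))),
               rev(vapply(unname(as.character(fragmentSeqs(f))),
                          revcompOracle, character(1L), USE.NAMES = FALSE)))
})

test_that("size selection is an inclusive length filter preserving order", {
  set.seed(3)
  frs <- makeFragments(vapply(c(100L, 320L, 350L, 351L), randomDna, character(1L)))
  sel <- sizeSelect(frs, c(300L, 350L))
  expect_equal(unname(fragmentWidths(sel)), c(320L, 350L))

  g <- randomDna(10000)
  f <- digestSeq(g, tier1Enzymes())
  ident <- sizeSelect(f, c(1L, nchar(g)))
  expect_equal(length(ident), length(f))

  sel2 <- sizeSelect(f, c(200L, 300L))
  w <- fragmentWidths(f)
  expect_equal(unname(fragmentInfo(sel2)$fragId),
               unname(fragmentInfo(f)$fragId[w >= 200L & w <= 300L]))
})

test_that("tier-2 digestion nests within parents with lifted coordinates", {
  expect_error(secondTierDigest(makeFragments("ACGT"), list()), "non-empty")

  # 300 bp fragment with a single AluI site yielding pieces of 120 and 180:
  # only the 120 bp piece falls in [110, 140]
  strip <- function(x) {
    while (grepl("AGCT", x, fixed = TRUE)) x <- gsub("AGCT", "AGAT", x, fixed = TRUE)
    x
  }
  left <- strip(randomDna(118, seed = 8))
  right <- strip(randomDna(178, seed = 9))
  s <- paste0(left, "AGCT", right)
  expect_equal(nchar(s), 300L)
  t1 <- makeFragments(s, tier = 1L, starts = 501L)
  t2 <- secondTierDigest(t1, list(RestrictionEnzyme("AluI", "AGCT", 2L)),
                         c(110L, 140L))
  expect_equal(length(t2), 1L)
  expect_equal(unname(fragmentWidths(t2)), 120L)
  expect_equal(unname(fragmentInfo(t2)$parent), unname(fragmentInfo(t1)$fragId))
  expect_equal(unname(fragmentInfo(t2)$start), 501L)

  # a tier-1 fragment with no tier-2 site and length 330 yields nothing
  s330 <- strip(randomDna(330, seed = 10))
  t2none <- secondTierDigest(makeFragments(s330, tier = 1L),
                             list(RestrictionEnzyme("AluI", "AGCT", 2L)),
                             c(110L, 140L))
  expect_equal(length(t2none), 0L)

  # on a simulated genome every tier-2 fragment nests inside its parent
  g <- generateGenome(200000, seed = 12)
  f1 <- sizeSelect(digestSeq(g, tier1Enzymes()), c(300L, 350L))
  f2 <- secondTierDigest(f1, tier2Enzymes(), c(110L, 140L))
  if (length(f2)) {
    i1 <- fragmentInfo(f1); i2 <- fragmentInfo(f2)
    pi <- match(i2$parent, i1$fragId)
    expect_false(anyNA(pi))
    expect_true(all(i2$start >= i1$start[pi] & i2$end <= i1$end[pi]))
    expect_true(all(i2$tier == 2L))
    w <- fragmentWidths(f2)
    expect_true(all(w >= 110L & w <= 140L))
    # sequences match source coordinates
    src <- as.character(genomeSeq(g))
    expect_identical(unname(as.character(fragmentSeqs(f2))),
                     substring(src, i2$start, i2$end))
  }
})

test_that("the banding diagnostic flags repeat-rich windows", {
  g <- generateGenome(50000, seed = 30)
  unit <- randomDna(320, seed = 31)
  p <- plantComplications(g, nRepeats = 30, repeatUnit = unit, seed = 32)
  f <- digestSeq(p$genome, tier1Enzymes())
  diag <- fragmentLengthDiagnostic(f, c(250L, 400L), genome = p$genome,
                                   maxRepeatCount = 5L)
  expect_true(diag$nInWindow > 0L)
  expect_true(diag$nRepeatInWindow >= 0L)
  diagStrict <- fragmentLengthDiagnostic(f, c(250L, 400L), genome = p$genome,
                                         maxRepeatCount = 0L)
  expect_true(diagStrict$bandingFlag || diagStrict$nRepeatInWindow == 0L)
})
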