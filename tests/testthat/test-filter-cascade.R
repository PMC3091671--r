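# The five-stage false-positive filter cascade and its bookkeeping.

mkCand <- function(refId, pos, refAllele, altAllele, depth = 5L, score = 100) {
  data.frame(refId = refId, pos = as.integer(pos), refAllele = refAllele,
             altAllele = altAllele, depth = depth, alleleScore = score,
             flankLeft = 60L, flankRight = 60L, stringsAsFactors = FALSE)
}

test_that("the paralog filter eliminates exactly the self-called sites", {
  cand <- mkCand(c("r1", "r1", "r2"), c(10L, 20L, 30L),
                 c("A", "C", "G"), c("G", "T", "A"))
  none <- paralogFilter(cand, cand[0, ])
  expect_identical(none$kept, cand)
  expect_equal(nrow(none$eliminated), 0L)

  self <- mkCand("r1", 20L, "C", "A")  # same site, any allele
  out <- paralogFilter(cand, self)
  expect_equal(nrow(out$eliminated), 1L)
  expect_equal(out$eliminated$pos, 20L)
  expect_equal(out$kept$pos, c(10L, 30L))
})

test_that("allele-swap verification demands reciprocal genotype-A evidence", {
  ref <- randomDna(200, seed = 91)
  refs <- makeRefs(c(r = ref))
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  altAt <- function(p) setdiff(c("A", "C", "G", "T"), refChars[p])[1L]

  # genotype-A reads cover position 100 (4 reads) but not position 30
  aReads <- makeReads(c(substr(ref, 81L, 120L), substr(ref, 85L, 124L),
                        revcompOracle(substr(ref, 90L, 129L)),
                        substr(ref, 95L, 134L)))
  covered <- mkCand("r", 100L, refChars[100L], altAt(100L))
  uncovered <- mkCand("r", 30L, refChars[30L], altAt(30L))
  cand <- rbind(covered, uncovered)

  out <- alleleSwapVerify(cand, aReads, refs)
  expect_equal(out$kept$pos, 100L)
  expect_equal(out$eliminated$pos, 30L)
  # the reciprocal call recovers the original reference allele
  expect_true(any(out$swapCalls$pos == 100L &
                    out$swapCalls$altAllele == refChars[100L]))

  # batched and per-site substitution agree on this sparse instance
  batched <- swapAlleles(cand, refs)
  perSite <- swapAlleles(cand, refs, perSite = TRUE)
  bc <- as.character(refSeqs(batched))[["r"]]
  expect_identical(substr(bc, 100L, 100L), covered$altAllele)
  expect_identical(substr(bc, 30L, 30L), uncovered$altAllele)
  for (k in seq_along(perSite)) {
    ps <- as.character(refSeqs(perSite[[k]]))[["r"]]
    expect_identical(substr(ps, cand$pos[k], cand$pos[k]), cand$altAllele[k])
  }
})

test_that("library screening eliminates candidates on flagged references only", {
  lib <- randomDna(400, seed = 92)
  hot <- paste0(randomDna(100, seed = 93), substr(lib, 51L, 80L),
                randomDna(100, seed = 94))
  cold <- randomDna(230, seed = 95)
  refs <- makeRefs(c(hot = hot, cold = cold))
  cand <- mkCand(c("hot", "cold"), c(50L, 60L), c("A", "C"), c("G", "T"))

  out <- libraryScreenCandidates(cand, refs, Biostrings::DNAStringSet(lib))
  expect_equal(out$eliminated$refId, "hot")
  expect_equal(out$kept$refId, "cold")

  empty <- libraryScreenCandidates(cand, refs, Biostrings::DNAStringSet())
  expect_identical(empty$kept, cand)
})

test_that("the consistency screen requires unanimous alternate support", {
  cand <- mkCand("r", 50L, "A", "G")
  unanimous <- data.frame(refId = "r", pos = 50L, base = "G", count = 5L,
                          qualSum = 150)
  out <- alleleConsistencyScreen(cand, unanimous)
  expect_equal(nrow(out$kept), 1L)

  mixed <- rbind(unanimous,
                 data.frame(refId = "r", pos = 50L, base = "T", count = 1L,
                            qualSum = 30))
  out2 <- alleleConsistencyScreen(cand, mixed)
  expect_equal(nrow(out2$eliminated), 1L)

  # a reference-allele read counts as different under strict unanimity only
  refRead <- rbind(unanimous,
                   data.frame(refId = "r", pos = 50L, base = "A", count = 1L,
                              qualSum = 30))
  expect_equal(nrow(alleleConsistencyScreen(cand, refRead, strict = TRUE)$eliminated), 1L)
  expect_equal(nrow(alleleConsistencyScreen(cand, refRead, strict = FALSE)$eliminated), 0L)
})

test_that("the cascade preserves conservation arithmetic and stage order", {
  ref <- randomDna(300, seed = 96)
  refs <- makeRefs(c(r = ref))
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  alt <- function(p) setdiff(c("A", "C", "G", "T"), refChars[p])[1L]
  cand <- mkCand("r", c(100L, 150L), refChars[c(100L, 150L)],
                 c(alt(100L), alt(150L)))
  aReads <- makeReads(c(substr(ref, 81L, 120L), substr(ref, 86L, 125L),
                        substr(ref, 91L, 130L),
                        substr(ref, 131L, 170L), substr(ref, 136L, 175L),
                        substr(ref, 141L, 180L)))
  pileupB <- rbind(
    data.frame(refId = "r", pos = 100L, base = alt(100L), count = 5L, qualSum = 150),
    data.frame(refId = "r", pos = 150L, base = alt(150L), count = 4L, qualSum = 120),
    data.frame(refId = "r", pos = 150L, base = refChars[150L], count = 1L, qualSum = 30))

  out <- runCascade(cand, refs, readsA = aReads, pileupB = pileupB)
  st <- reportStages(out$report)
  expect_identical(st$stage, c("paralog_filter", "allele_swap_verify",
                               "repeat_screen", "contaminant_screen",
                               "allele_consistency_screen"))
  expect_true(all(st$nOut == st$nIn - st$nEliminated))
  expect_equal(st$nIn[-1L], st$nOut[-nrow(st)])
  expect_equal(st$nIn[1L], 2L)
  # the site with a discordant genotype-B read leaves at the last stage
  expect_equal(out$candidates$pos, 100L)
  flags <- out$inputFlags
  expect_equal(flags$stageExited[flags$pos == 150L], "allele_consistency_screen")
  expect_equal(flags$stageExited[flags$pos == 100L], "pass")

  # empty candidates: all-zero report
  outE <- runCascade(cand[0, ], refs, readsA = aReads, pileupB = pileupB)
  expect_equal(nrow(outE$candidates), 0L)
  expect_true(all(reportStages(outE$report)$nIn == 0L))

  # disabling all stages returns the input unchanged
  outD <- runCascade(cand, refs, readsA = aReads, pileupB = pileupB,
                     stages = character())
  expect_equal(nrow(outD$candidates), nrow(cand))

  # a missing stage input is a configuration error naming the stage
  expect_error(runCascade(cand, refs, pileupB = pileupB), "paralog_filter")
  expect_error(runCascade(cand, refs, readsA = aReads,
                          stages = "allele_consistency_screen"),
               "allele_consistency_screen")
})

test_that("filters are pure subset operations", {
  ref <- randomDna(300, seed = 97)
  refs <- makeRefs(c(r = ref))
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  alt <- function(p) setdiff(c("A", "C", "G", "T"), refChars[p])[1L]
  pos <- c(50L, 120L, 200L)
  cand <- mkCand("r", pos, refChars[pos], vapply(pos, alt, character(1L)))
  self <- mkCand("r", 120L, refChars[120L], "N")
  out <- paralogFilter(cand, self)
  joined <- rbind(out$kept, out$eliminated)
  joined <- joined[order(joined$pos), ]
  rownames(joined) <- NULL
  expect_identical(joined, cand)
})
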