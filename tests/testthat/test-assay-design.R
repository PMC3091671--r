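# Flank extraction, the designability heuristic, and the e-PCR style
# primer-specificity screen.

mkCand2 <- function(refId, pos) {
  data.frame(refId = refId, pos = as.integer(pos), refAllele = "A",
             altAllele = "G", depth = 5L, alleleScore = 100,
             flankLeft = 0L, flankRight = 0L, stringsAsFactors = FALSE)
}

test_that("flank extraction truncates at ends and Ns and gates eligibility", {
  ref <- randomDna(300, seed = 101)
  refs <- makeRefs(c(r = ref))

  mid <- extractFlanks(mkCand2("r", 150L), refs, flank = 60L)
  expect_equal(mid$flankLeftLen, 60L)
  expect_equal(mid$flankRightLen, 60L)
  expect_true(mid$eligible)
  expect_identical(mid$flankLeftSeq, substr(ref, 90L, 149L))
  expect_identical(mid$flankRightSeq, substr(ref, 151L, 210L))

  nearEnd <- extractFlanks(mkCand2("r", 31L), refs, flank = 60L)
  expect_equal(nearEnd$flankLeftLen, 30L)
  expect_false(nearEnd$eligible)

  nref <- paste0(substr(ref, 1L, 99L), "N", substr(ref, 101L, 300L))
  nrefs <- makeRefs(c(r = nref))
  cutByN <- extractFlanks(mkCand2("r", 150L), nrefs, flank = 60L)
  expect_equal(cutByN$flankLeftLen, 49L)  # positions 101..149
  expect_false(cutByN$eligible)

  # brute-force window check over a synthetic candidate set
  set.seed(102)
  pos <- sort(sample(5:295, 12L))
  cands <- extractFlanks(mkCand2("r", pos), refs, flank = 60L)
  for (i in seq_len(nrow(cands))) {
    p <- cands$pos[i]
    expect_equal(cands$eligible[i], p - 1L >= 60L && 300L - p >= 60L,
                 info = sprintf("pos %d", p))
    expect_equal(cands$nNeighbors[i], sum(abs(pos - p) <= 60L) - 1L)
  }
})

test_that("the designability proxy is 1 exactly when all criteria hold and is monotone", {
  ref <- randomDna(400, seed = 103)
  refs <- makeRefs(c(r = ref))
  rec <- designabilityScore(extractFlanks(mkCand2("r", 200L), refs), flank = 60L)
  expect_equal(rec$designability, 1.0)

  # a neighboring candidate strictly lowers the score
  pair <- designabilityScore(extractFlanks(mkCand2("r", c(200L, 210L)), refs),
                             flank = 60L)
  expect_lt(pair$designability[1L], 1.0)
  expect_lt(pair$designability[1L], rec$designability)

  # homopolymer runs >= 8 in a flank lower the score, monotonically in length
  mkRun <- function(runLen) {
    s <- paste0(randomDna(150, seed = 104), strrep("A", runLen),
                randomDna(250 - runLen, seed = 105))
    r <- makeRefs(c(r = s))
    designabilityScore(extractFlanks(mkCand2("r", 200L), r), flank = 60L)$designability
  }
  expect_lt(mkRun(9L), mkRun(7L))
  expect_lte(mkRun(11L), mkRun(9L))

  # short flanks lower the score monotonically
  edge <- designabilityScore(extractFlanks(mkCand2("r", 40L), refs), flank = 60L)
  expect_lt(edge$designability, rec$designability)

  # deterministic: identical inputs give bit-identical scores
  again <- designabilityScore(extractFlanks(mkCand2("r", 200L), refs), flank = 60L)
  expect_identical(again$designability, rec$designability)
})

test_that("primer placement enumeration matches the naive oracle", {
  set.seed(106)
  for (rep in 1:6) {
    ref <- randomDna(300)
    st <- sample(200L, 1L)
    primer <- substr(ref, st, st + 19L)
    # perturb the primer with up to 4 substitutions
    ch <- strsplit(primer, "", fixed = TRUE)[[1L]]
    for (j in sample(20L, sample(0:4, 1L)))
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
    primer <- paste(ch, collapse = "")
    got <- rrlSNP:::primerPlacements(primer, ref, nMismatches = 3L, nGaps = 1L)
    want <- primerPlacementsOracle(primer, ref, 3L, 1L)
    expect_identical(got[order(got$start, got$end), ],
                     want[order(want$start, want$end), ],
                     ignore_attr = TRUE)
    # the zero-budget screen reduces to exact string search
    got0 <- rrlSNP:::primerPlacements(primer, ref, 0L, 0L)
    exact <- gregexpr(primer, ref, fixed = TRUE)[[1L]]
    exact <- if (exact[1L] == -1L) integer() else as.integer(exact)
    expect_equal(got0$start, exact)
  }
})

test_that("the e-PCR screen passes single-product pairs and rejects multi-reference hits", {
  refA <- randomDna(400, seed = 107)
  refB <- randomDna(400, seed = 108)
  refs <- makeRefs(c(A = refA, B = refB))

  left <- substr(refA, 101L, 120L)
  right <- revcompOracle(substr(refA, 281L, 300L))  # product 200 bp
  res <- epcrScreen(list(left = left, right = right), refs)
  expect_true(res$pass)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$refId, "A")
  expect_equal(res$hits$productLen, 200L)

  # the same template planted in both references: two hits, fail
  shared <- substr(refA, 101L, 300L)
  refBdup <- paste0(substr(refB, 1L, 100L), shared, substr(refB, 301L, 400L))
  refs2 <- makeRefs(c(A = refA, B = refBdup))
  res2 <- epcrScreen(list(left = left, right = right), refs2)
  expect_false(res2$pass)
  expect_equal(nrow(res2$hits), 2L)
  expect_setequal(res2$hits$refId, c("A", "B"))

  # product outside the admitted size range is not a hit
  farRight <- revcompOracle(substr(refA, 381L, 400L))  # product 300 -> in range
  res3 <- epcrScreen(list(left = left, right = farRight), refs,
                     productRange = c(80L, 250L))
  expect_false(res3$pass)
  expect_equal(nrow(res3$hits), 0L)

  expect_error(epcrScreen(list(left = "ACGT", right = right), refs), "15, 30")
})

test_that("naive primer pairs anchor at the flank ends", {
  ref <- randomDna(300, seed = 109)
  refs <- makeRefs(c(r = ref))
  rec <- extractFlanks(mkCand2("r", 150L), refs, flank = 60L)
  pp <- designPrimerPair(rec)
  expect_identical(pp$left, substr(ref, 90L, 109L))
  expect_identical(pp$right, revcompOracle(substr(ref, 191L, 210L)))
  # the pair amplifies its own locus uniquely: product = 121 bp
  res <- epcrScreen(pp, refs)
  expect_true(res$pass)
  expect_equal(res$hits$productLen, 121L)
})

test_that("the assay table writes the combined [X/Y] flank column", {
  ref <- randomDna(300, seed = 110)
  refs <- makeRefs(c(r = ref))
  rec <- designabilityScore(extractFlanks(mkCand2("r", 150L), refs))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "assay.tsv")
  writeAssayTable(rec, path)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(tab$snp_id, "r_150")
  expect_match(tab$sequence, "\\[A/G\\]")
  expect_equal(nchar(tab$sequence), 60L + 60L + 5L)
})
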