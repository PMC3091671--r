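# Ungapped alignment with unique-best placement, pileup construction, and
# threshold-gated biallelic SNP calling.

test_that("alignment returns unique, ambiguous and unmapped outcomes", {
  refA <- randomDna(400, seed = 81)
  refB <- randomDna(400, seed = 82)
  shared <- substr(refA, 101L, 140L)
  refBshared <- paste0(substr(refB, 1L, 200L), shared, substr(refB, 241L, 400L))
  refs <- makeRefs(c(A = refA, B = refBshared))

  exact <- substr(refA, 51L, 90L)           # unique to refA
  dup <- shared                             # present in both
  nowhere <- randomDna(40, seed = 83)       # matches nothing
  reads <- makeReads(c(exact, dup, nowhere))
  aln <- alignShortReads(reads, refs, maxMismatches = 2L)
  st <- attr(aln, "status")
  expect_identical(st, c("aligned", "ambiguous", "unmapped"))
  expect_equal(aln$refId, "A")
  expect_equal(aln$refStart, 51L)
  expect_equal(aln$mismatchCount, 0L)

  # reverse-strand placement
  rcRead <- makeReads(revcompOracle(substr(refA, 301L, 340L)))
  alnRc <- alignShortReads(rcRead, refs)
  expect_equal(alnRc$strand, "-")
  expect_equal(alnRc$refStart, 301L)
  expect_identical(alnRc$alnSeq, substr(refA, 301L, 340L))
})

test_that("the seeded search agrees with the exhaustive Hamming oracle", {
  set.seed(84)
  refs <- makeRefs(vapply(c(3000L, 2500L, 1500L), randomDna, character(1L)))
  refChars <- as.character(refSeqs(refs))
  n <- 120L
  reads <- character(n)
  for (i in seq_len(n)) {
    kind <- i %% 4L
    w <- sample(36:42, 1L)
    if (kind == 0L) {
      reads[i] <- randomDna(w)  # mostly unmappable
    } else {
      ref <- sample(refChars, 1L)
      st <- sample(nchar(ref) - w + 1L, 1L)
      r <- substr(ref, st, st + w - 1L)
      nmut <- sample(0:3, 1L)  # sometimes beyond the budget
      if (nmut > 0L) {
        ch <- strsplit(r, "", fixed = TRUE)[[1L]]
        at <- sample(w, nmut)
        for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
        r <- paste(ch, collapse = "")
      }
      if (kind == 2L) r <- revcompOracle(r)
      reads[i] <- r
    }
  }
  rs <- makeReads(reads)
  aln <- alignShortReads(rs, refs, maxMismatches = 2L)
  st <- attr(aln, "status")
  for (i in seq_len(n)) {
    oracle <- alignOracle(reads[i], refs, maxMismatches = 2L)
    expect_identical(st[i], oracle$status, info = sprintf("read %d", i))
    if (oracle$status == "aligned") {
      row <- aln[aln$readId == sprintf("rd_%03d", i), ]
      expect_equal(row$refId, oracle$refId, info = sprintf("read %d", i))
      expect_equal(row$refStart, oracle$start, info = sprintf("read %d", i))
      expect_equal(row$strand, oracle$strand, info = sprintf("read %d", i))
      expect_equal(row$mismatchCount, oracle$mm, info = sprintf("read %d", i))
    }
  }
})

test_that("pileups conserve read bases and match a hand-worked fixture", {
  ref <- randomDna(58, seed = 89)  # aperiodic, so placements are unique
  refs <- makeRefs(c(toy = ref))
  # three 40 bp reads: two at 1, one at 10; read 2 carries a mismatch at
  # reference position 20
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  refBase <- refChars[20L]
  mutBase <- setdiff(c("A", "C", "G", "T"), refBase)[1L]
  r1 <- substr(ref, 1L, 40L)
  r2chars <- strsplit(substr(ref, 1L, 40L), "", fixed = TRUE)[[1L]]
  r2chars[20L] <- mutBase
  r2 <- paste(r2chars, collapse = "")
  r3 <- substr(ref, 10L, 49L)
  reads <- makeReads(c(r1, r2, r3), quals = list(rep(30L, 40L), rep(25L, 40L),
                                                 rep(35L, 40L)))
  aln <- alignShortReads(reads, refs)
  expect_equal(nrow(aln), 3L)
  pu <- buildPileup(aln, refs)
  # conservation: total counts equal total aligned bases
  expect_equal(sum(pu$count), 3L * 40L)
  # hand-computed: position 20 has the reference base from r1 and r3, the
  # mutated base from r2
  p20 <- pu[pu$pos == 20L, ]
  expect_equal(p20$count[p20$base == refBase], 2L)
  expect_equal(p20$qualSum[p20$base == refBase], 30 + 35)
  expect_equal(p20$count[p20$base == mutBase], 1L)
  expect_equal(p20$qualSum[p20$base == mutBase], 25)
  # single coverage outside the double-covered core
  expect_equal(sum(pu$count[pu$pos == 45L]), 1L)
  expect_equal(nrow(pu[pu$pos == 50L, ]), 0L)  # zero coverage omitted
})

test_that("SNP calling enforces depth, score, N-reference and biallelic rules", {
  ref <- randomDna(100, seed = 85)
  refs <- makeRefs(c(r = ref))
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  alt <- setdiff(c("A", "C", "G", "T"), refChars[50L])[1L]

  mkPileup <- function(nAlt, nRef, qual = 30) {
    rbind(
      if (nAlt > 0L) data.frame(refId = "r", pos = 50L, base = alt,
                                count = nAlt, qualSum = nAlt * qual),
      if (nRef > 0L) data.frame(refId = "r", pos = 50L, base = refChars[50L],
                                count = nRef, qualSum = nRef * qual))
  }

  # depth 2 never yields a call, whatever the score
  expect_equal(nrow(callSNPs(mkPileup(2L, 0L, 40), refs)), 0L)
  # 3 alt reads at Phred 30, no reference reads: score 90 call
  call <- callSNPs(mkPileup(3L, 0L, 30), refs)
  expect_equal(nrow(call), 1L)
  expect_equal(call$altAllele, alt)
  expect_equal(call$alleleScore, 90)
  expect_equal(call$depth, 3L)
  expect_equal(call$refAllele, refChars[50L])
  # flanks measured to the reference ends
  expect_equal(call$flankLeft, 49L)
  expect_equal(call$flankRight, 50L)
  # score below threshold: 3 alt reads at Phred 3 -> score 9 < 10
  expect_equal(nrow(callSNPs(mkPileup(3L, 0L, 3), refs)), 0L)

  # N reference base blocks the call
  nref <- makeRefs(c(r = paste0(substr(ref, 1L, 49L), "N", substr(ref, 51L, 100L))))
  expect_equal(nrow(callSNPs(mkPileup(3L, 0L, 30), nref)), 0L)

  # monotone in thresholds
  pu <- mkPileup(4L, 2L, 30)
  base <- nrow(callSNPs(pu, refs, minDepth = 3L, minAlleleScore = 10))
  expect_gte(base, nrow(callSNPs(pu, refs, minDepth = 7L, minAlleleScore = 10)))
  expect_gte(base, nrow(callSNPs(pu, refs, minDepth = 3L, minAlleleScore = 1000)))

  # third alleles do not block the call: the best-scoring non-ref allele wins
  third <- setdiff(c("A", "C", "G", "T"), c(refChars[50L], alt))[1L]
  pu3 <- rbind(mkPileup(4L, 2L, 30),
               data.frame(refId = "r", pos = 50L, base = third, count = 1L,
                          qualSum = 20))
  call3 <- callSNPs(pu3, refs)
  expect_equal(nrow(call3), 1L)
  expect_equal(call3$altAllele, alt)
  expect_equal(call3$alleleScore, 4 * 30 - 20)  # competing allele subtracts
  expect_equal(call3$depth, 7L)
})

test_that("flanks stop at the nearest N", {
  ref <- paste0(randomDna(30, seed = 86), "N", randomDna(69, seed = 87))
  refs <- makeRefs(c(r = ref))
  refChars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  alt <- setdiff(c("A", "C", "G", "T"), refChars[60L])[1L]
  pu <- data.frame(refId = "r", pos = 60L, base = alt, count = 3L, qualSum = 90)
  call <- callSNPs(pu, refs)
  expect_equal(call$flankLeft, 28L)   # positions 32..59, stopped by N at 31
  expect_equal(call$flankRight, 40L)  # positions 61..100
})

test_that("alignments and candidates persist as SAM and TSV", {
  ref <- randomDna(300, seed = 88)
  refs <- makeRefs(c(chr = ref))
  reads <- makeReads(c(substr(ref, 10L, 47L), revcompOracle(substr(ref, 100L, 139L))))
  aln <- alignShortReads(reads, refs)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  writeAlignmentsSam(aln, refs, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:chr\tLN:300$", lines)))
  body <- grep("^[^@]", lines, value = TRUE)
  expect_equal(length(body), 2L)
  fields <- strsplit(body, "\t")
  expect_equal(vapply(fields, `[`, character(1L), 6L), c("38M", "40M"))
  expect_equal(vapply(fields, `[`, character(1L), 2L), c("0", "16"))

  cand <- data.frame(refId = "chr", pos = 42L, refAllele = "A",
                     altAllele = "G", depth = 5L, alleleScore = 120,
                     flankLeft = 41L, flankRight = 60L,
                     stringsAsFactors = FALSE)
  tsv <- file.path(dir, "cand.tsv")
  writeCandidatesTsv(cand, tsv)
  expect_equal(readCandidatesTsv(tsv), cand)
  vcf <- file.path(dir, "cand.vcf")
  writeCandidatesVcf(cand, refs, vcf)
  expect_true(any(grepl("^chr\t42\t\\.\tA\tG", readLines(vcf))))
})
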