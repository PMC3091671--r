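# Reference construction: clustering, consensus, quality masking, the
# length/N filter, and the shared-word library screen.

test_that("identical and disjoint reads cluster as expected", {
  s <- randomDna(200, seed = 51)
  reads <- makeReads(c(s, s))
  refs <- clusterLongReads(reads, minOverlap = 40L)
  expect_equal(length(refs), 1L)
  expect_equal(refNReads(refs), 2L)
  expect_identical(refKind(refs), "contig")
  expect_identical(unname(as.character(refSeqs(refs))), s)

  a <- randomDna(150, seed = 52); b <- randomDna(150, seed = 53)
  refs2 <- clusterLongReads(makeReads(c(a, b)), minOverlap = 40L)
  expect_equal(length(refs2), 2L)
  expect_identical(refKind(refs2), c("singleton", "singleton"))
})

test_that("error-free reads tiling a fragment reconstruct it", {
  frag <- randomDna(330, seed = 54)
  fragments <- makeFragments(frag, tier = 1L, starts = 1001L)
  reads <- simulateLongReads(fragments, coverageDepth = 35,
                             homopolymerErrorRate = 0, seed = 55,
                             meanLen = 120, sdLen = 20)
  expect_gte(length(reads), 50L)
  refs <- clusterLongReads(reads, minIdentity = 1.0, minOverlap = 40L,
                           fragments = fragments)
  contigs <- refs[which(refNReads(refs) >= 2L)]
  # the dominant contig reconstructs a substring of the fragment; at this
  # depth it spans the fragment completely
  main <- which.max(Biostrings::width(refSeqs(contigs)))
  cons <- unname(as.character(refSeqs(contigs))[main])
  consFwd <- if (refProvenance(contigs)[[main]]$strand == "-")
    revcompOracle(cons) else cons
  expect_true(grepl(consFwd, frag, fixed = TRUE) || consFwd == frag)
  # with error-free reads and full identity, no chimeras: every contig is a
  # substring of the fragment (either strand)
  for (i in seq_len(length(contigs))) {
    cs <- unname(as.character(refSeqs(contigs))[i])
    expect_true(grepl(cs, frag, fixed = TRUE) ||
                  grepl(revcompOracle(cs), frag, fixed = TRUE))
  }
  # provenance maps consensus columns onto the genome interval of the source
  p <- refProvenance(contigs)[[main]]
  expect_true(all(p$genomePos >= 1001L & p$genomePos <= 1330L))
})

test_that("quality masking is strict at the threshold and length-preserving", {
  refs <- makeRefs(c(x = "ACGTACGTAC"),
                   quals = list(c(40L, 40L, 19L, 20L, 21L, 10L, 40L, 40L, 0L, 25L)))
  masked <- maskLowQuality(refs, threshold = 20L)
  expect_identical(unname(as.character(refSeqs(masked))), "ACNTANGTNC")

  all40 <- makeRefs(c(y = "ACGT"), quals = list(rep(40L, 4L)))
  expect_identical(unname(as.character(refSeqs(maskLowQuality(all40)))), "ACGT")

  all10 <- makeRefs(c(z = "ACGT"), quals = list(rep(10L, 4L)))
  expect_identical(unname(as.character(refSeqs(maskLowQuality(all10)))), "NNNN")

  bad <- makeRefs(c(w = "ACGT"), quals = list(rep(40L, 3L)))
  expect_error(maskLowQuality(bad), "match")
})

test_that("the reference filter partitions on length and N fraction", {
  seqs <- c(short60 = randomDna(60, seed = 56),
            keep61 = paste0(strrep("N", 45L), randomDna(16, seed = 57)),
            n76 = paste0(strrep("N", 76L), randomDna(24, seed = 58)),
            n75 = paste0(strrep("N", 75L), randomDna(25, seed = 59)),
            clean = randomDna(100, seed = 60))
  refs <- makeRefs(seqs)
  out <- filterReferences(refs, minLen = 61L, maxNFraction = 0.75)
  keptIds <- names(refSeqs(out$kept))
  expect_true("short60" %in% names(refSeqs(out$eliminated)))  # < 61 bases
  expect_true("keep61" %in% keptIds)   # 61 bases, 45/61 = 0.738 N
  expect_true("n76" %in% names(refSeqs(out$eliminated)))      # 0.76 > 0.75
  expect_true("n75" %in% keptIds)      # 0.75 allowed
  expect_true("clean" %in% keptIds)
  expect_equal(out$counts[["nIn"]],
               length(out$kept) + length(out$eliminated))
})

test_that("the shared-word screen flags exact 30-mers on either strand only", {
  lib <- randomDna(500, seed = 61)
  word30 <- substr(lib, 101L, 130L)
  carrier <- paste0(randomDna(50, seed = 62), word30, randomDna(50, seed = 63))
  carrierRc <- revcompOracle(carrier)
  word29 <- substr(lib, 201L, 229L)
  nearMiss <- paste0(randomDna(40, seed = 64), word29, randomDna(40, seed = 65))
  clean <- randomDna(120, seed = 66)
  refs <- makeRefs(c(carrier = carrier, carrierRc = carrierRc,
                     nearMiss = nearMiss, clean = clean))
  out <- screenLibrary(refs, Biostrings::DNAStringSet(lib), wordSize = 30L)
  expect_setequal(names(refSeqs(out$flagged)), c("carrier", "carrierRc"))
  expect_setequal(names(refSeqs(out$kept)), c("nearMiss", "clean"))

  # monotone: enlarging the library never un-flags
  bigger <- Biostrings::DNAStringSet(c(lib, nearMiss))
  out2 <- screenLibrary(refs, bigger, wordSize = 30L)
  expect_true(all(names(refSeqs(out$flagged)) %in% names(refSeqs(out2$flagged))))

  expect_error(screenLibrary(refs, Biostrings::DNAStringSet()), "empty")
})

test_that("references wholly inside a planted organellar insert are screened out", {
  g <- generateGenome(150000, seed = 67)
  org <- randomDna(5000, seed = 68)
  p <- plantComplications(g, organellarSeq = org, seed = 69)
  f1 <- sizeSelect(digestSeq(p$genome, tier1Enzymes()), c(300L, 350L))
  reads <- simulateLongReads(f1, coverageDepth = 3, homopolymerErrorRate = 0,
                             seed = 70)
  refs <- clusterLongReads(reads, fragments = f1)
  out <- screenLibrary(refs, p$libraries$organellar, wordSize = 30L)
  ann <- genomeAnnotations(p$genome)
  orgIv <- ann[ann$class == "organellar"]
  inside <- vapply(seq_len(length(refs)), function(i) {
    pr <- refProvenance(refs)[[i]]
    !is.null(pr) && all(pr$genomePos >= GenomicRanges::start(orgIv) &
                          pr$genomePos <= GenomicRanges::end(orgIv))
  }, logical(1L))
  if (any(inside))
    expect_true(all(names(refSeqs(refs))[inside] %in%
                      names(refSeqs(out$flagged))))
  expect_equal(length(out$kept) + length(out$flagged), length(refs))
})

test_that("reference sets persist through FASTA plus sidecar", {
  frag <- randomDna(320, seed = 71)
  fragments <- makeFragments(frag, tier = 1L)
  reads <- simulateLongReads(fragments, coverageDepth = 6,
                             homopolymerErrorRate = 0, seed = 72)
  refs <- clusterLongReads(reads, fragments = fragments)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "refs.fasta")
  writeReferenceSet(refs, fa)
  back <- readReferenceSet(fa)
  expect_identical(as.character(refSeqs(back)), as.character(refSeqs(refs)))
  expect_identical(refNReads(back), refNReads(refs))
  expect_identical(refQuals(back), refQuals(refs))
  expect_identical(refProvenance(back), refProvenance(refs))
})
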