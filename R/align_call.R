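# Ungapped short-read alignment (unique best placement within a mismatch
# budget) and depth/score-thresholded biallelic SNP calling.

#' @importFrom data.table data.table setkey := .N
NULL

SEED_WIDTH <- 12L  # with 3 disjoint exact seeds, any placement with <= 2
                   # mismatches leaves at least one seed intact (pigeonhole)

# Concatenate references into one subject with N spacers long enough that
# no read placement can span two references.
concatRefs <- function(refs, spacer = 60L) {
  chars <- as.character(refSeqs(refs))
  gap <- strrep("N", spacer)
  subject <- paste(chars, collapse = gap)
  starts <- cumsum(c(1L, utils::head(nchar(chars) + spacer, -1L)))
  list(subject = subject, starts = starts, widths = nchar(chars),
       ids = names(refSeqs(refs)))
}

#' Align short reads to a reference set
#'
#' Full-length ungapped alignment with a mismatch budget: each read is
#' placed at the unique position (over all references, offsets and strands)
#' with the minimum mismatch count not exceeding \code{maxMismatches}.
#' Reads with two or more placements tying at the minimum are AMBIGUOUS and
#' discarded entirely (preventing paralog cross-mapping from inflating
#' depth); reads with no qualifying placement are UNMAPPED. N reference
#' bases never match and therefore count as mismatches.
#'
#' The search seeds candidate placements with three disjoint exact 12-mers
#' per read orientation (any placement within a 2-mismatch budget must leave
#' at least one seed exact) and verifies each candidate by a full Hamming
#' count.
#'
#' @param reads A \code{\link{ReadSet-class}}.
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param maxMismatches Mismatch budget per read (default 2).
#' @return A data.frame with one row per uniquely placed read: \code{readId},
#'   \code{refId}, \code{refStart} (1-based on the reference), \code{strand},
#'   \code{mismatchCount}, \code{alnSeq} and \code{alnQuals}
#'   (reference-oriented read sequence and comma-separated Phred scores).
#'   Attributes \code{nAmbiguous} and \code{nUnmapped} carry the discarded
#'   read counts; \code{status} maps every input read to
#'   \code{aligned}/\code{ambiguous}/\code{unmapped}.
#' @export
alignShortReads <- function(reads, refs, maxMismatches = 2L) {
  stopifnot(is(reads, "ReadSet"), is(refs, "ReferenceSet"))
  n <- length(reads)
  empty <- data.frame(readId = character(), refId = character(),
                      refStart = integer(), strand = character(),
                      mismatchCount = integer(), alnSeq = character(),
                      alnQuals = character(), stringsAsFactors = FALSE)
  if (!n || !length(refs)) {
    attr(empty, "nAmbiguous") <- 0L
    attr(empty, "nUnmapped") <- n
    attr(empty, "status") <- rep("unmapped", n)
    return(empty)
  }
  cc <- concatRefs(refs)
  subjRaw <- charToRaw(cc$subject)
  subjLen <- length(subjRaw)
  readStr <- as.character(readSeqs(reads))
  readRc <- vapply(readStr, revcompChar, character(1L), USE.NAMES = FALSE)
  widths <- nchar(readStr)
  if (any(widths < 3L * SEED_WIDTH))
    stop(sprintf("reads shorter than %d bp are not supported by the seeded search",
                 3L * SEED_WIDTH))

  seedOff <- c(0L, SEED_WIDTH, 2L * SEED_WIDTH)
  mkSeeds <- function(strs) {
    do.call(c, lapply(seedOff, function(o) substr(strs, o + 1L, o + SEED_WIDTH)))
  }
  seeds <- c(mkSeeds(readStr), mkSeeds(readRc))
  # seed row -> (read index, strand, offset of seed within oriented read)
  seedRead <- rep(rep(seq_len(n), times = 3L), 2L)
  seedOffv <- rep(rep(seedOff, each = n), 2L)
  seedStrand <- rep(c("+", "-"), each = 3L * n)

  pd <- Biostrings::PDict(DNAStringSet(unname(seeds)))
  m <- Biostrings::matchPDict(pd, DNAString(cc$subject))
  hitStarts <- IRanges::start(m)
  nh <- lengths(hitStarts)
  hs <- unlist(hitStarts, use.names = FALSE)
  if (length(hs)) {
    cand <- data.table(
      read = rep(seedRead, nh),
      strand = rep(seedStrand, nh),
      start = hs - rep(seedOffv, nh))
    cand <- unique(cand)
    cand <- cand[cand$start >= 1L & cand$start + widths[cand$read] - 1L <= subjLen]
    # a placement must lie entirely within one reference (never in a spacer)
    refIdx <- findInterval(cand$start, cc$starts)
    within <- cand$start - cc$starts[refIdx] + 1L
    inRef <- within >= 1L & within + widths[cand$read] - 1L <= cc$widths[refIdx]
    cand <- cand[inRef]
    cand[, "refIdx" := refIdx[inRef]]
    cand[, "within" := within[inRef]]
    # verify by exact Hamming count against the concatenated subject
    mmv <- integer(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$read[r]
      rr <- charToRaw(if (cand$strand[r] == "+") readStr[i] else readRc[i])
      s0 <- cand$start[r]
      mmv[r] <- sum(subjRaw[s0:(s0 + widths[i] - 1L)] != rr)
    }
    cand[, "mm" := mmv]
    cand <- cand[cand$mm <= maxMismatches]
  } else {
    cand <- data.table(read = integer(), strand = character(),
                       start = integer(), refIdx = integer(),
                       within = integer(), mm = integer())
  }

  status <- rep("unmapped", n)
  rows <- vector("list", n)
  info <- readInfo(reads)
  qualsL <- readQuals(reads)
  if (nrow(cand)) {
    best <- cand[, list(minmm = min(mm)), by = "read"]
    cand <- merge(cand, best, by = "read")
    cand <- cand[cand$mm == cand$minmm]
    tally <- cand[, list(nbest = .N), by = "read"]
    amb <- tally$read[tally$nbest > 1L]
    status[amb] <- "ambiguous"
    uni <- cand[cand$read %in% tally$read[tally$nbest == 1L]]
    if (nrow(uni)) {
      for (r in seq_len(nrow(uni))) {
        i <- uni$read[r]
        minus <- uni$strand[r] == "-"
        q <- qualsL[[i]]
        if (minus) q <- rev(q)
        status[i] <- "aligned"
        rows[[i]] <- data.frame(
          readId = info$readId[i], refId = cc$ids[uni$refIdx[r]],
          refStart = uni$within[r], strand = uni$strand[r],
          mismatchCount = uni$mm[r],
          alnSeq = if (minus) readRc[i] else readStr[i],
          alnQuals = paste(q, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(empty), rows[!vapply(rows, is.null, logical(1L))]))
  attr(out, "nAmbiguous") <- sum(status == "ambiguous")
  attr(out, "nUnmapped") <- sum(status == "unmapped")
  attr(out, "status") <- status
  out
}

#' Build a pileup from ungapped alignments
#'
#' Expands every aligned read into per-position allele evidence and
#' aggregates counts and summed Phred qualities per (reference, position,
#' allele). Only A/C/G/T read bases are tracked (no indels); positions with
#' zero coverage are omitted.
#'
#' @param alignments Alignment data.frame from \code{\link{alignShortReads}}.
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @return A data.frame with columns \code{refId}, \code{pos} (1-based),
#'   \code{base}, \code{count}, \code{qualSum}.
#' @export
buildPileup <- function(alignments, refs) {
  stopifnot(is(refs, "ReferenceSet"))
  if (!nrow(alignments))
    return(data.frame(refId = character(), pos = integer(), base = character(),
                      count = integer(), qualSum = numeric(),
                      stringsAsFactors = FALSE))
  if (!all(alignments$refId %in% names(refSeqs(refs))))
    stop("alignments reference unknown reference ids")
  w <- nchar(alignments$alnSeq)
  dt <- data.table(
    refId = rep(alignments$refId, w),
    pos = unlist(lapply(seq_len(nrow(alignments)), function(r)
      alignments$refStart[r] + seq_len(w[r]) - 1L)),
    base = unlist(strsplit(alignments$alnSeq, "", fixed = TRUE)),
    qual = unlist(lapply(strsplit(alignments$alnQuals, ",", fixed = TRUE),
                         as.integer)))
  dt <- dt[dt$base %in% DNA_BASES]
  agg <- dt[, list(count = .N, qualSum = as.numeric(sum(qual))),
            by = c("refId", "pos", "base")]
  setkey(agg, NULL)
  out <- as.data.frame(agg[order(agg$refId, agg$pos, agg$base)])
  rownames(out) <- NULL
  out
}

# Flank lengths: non-N run lengths immediately left/right of pos on the ref.
flankLengths <- function(refChars, pos) {
  left <- 0L
  i <- pos - 1L
  while (i >= 1L && refChars[i] != "N") { left <- left + 1L; i <- i - 1L }
  right <- 0L
  i <- pos + 1L
  while (i <= length(refChars) && refChars[i] != "N") { right <- right + 1L; i <- i + 1L }
  c(left, right)
}

#' Call biallelic SNP candidates from a pileup
#'
#' A candidate is emitted at a column iff (a) the best-scoring non-reference
#' allele reaches \code{minAlleleScore}, (b) total covering reads reach
#' \code{minDepth}, and (c) the reference base is not N. The allele call
#' score is a declared quality-sum statistic: the summed Phred quality of
#' reads supporting the candidate allele minus the summed Phred quality of
#' reads supporting every other non-reference allele. The call is made to
#' the single best-scoring non-reference allele; additional alleles do not
#' block the call (multi-allele evidence is handled later by the
#' allele-consistency screen). No indels are ever called.
#'
#' @param pileup Pileup data.frame from \code{\link{buildPileup}}.
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param minDepth Minimum covering reads (default 3).
#' @param minAlleleScore Minimum allele call score (default 10).
#' @return A candidate data.frame: \code{refId}, \code{pos} (1-based),
#'   \code{refAllele}, \code{altAllele}, \code{depth}, \code{alleleScore},
#'   \code{flankLeft}, \code{flankRight}.
#' @export
callSNPs <- function(pileup, refs, minDepth = 3L, minAlleleScore = 10) {
  stopifnot(is(refs, "ReferenceSet"))
  empty <- data.frame(refId = character(), pos = integer(),
                      refAllele = character(), altAllele = character(),
                      depth = integer(), alleleScore = numeric(),
                      flankLeft = integer(), flankRight = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(pileup)) return(empty)
  refCharsL <- strsplit(as.character(refSeqs(refs)), "", fixed = TRUE)
  names(refCharsL) <- names(refSeqs(refs))
  dt <- data.table(pileup)
  refBase <- vapply(seq_len(nrow(dt)), function(r)
    refCharsL[[dt$refId[r]]][dt$pos[r]], character(1L))
  dt[, "refBase" := refBase]
  depthTab <- dt[, list(depth = sum(count)), by = c("refId", "pos")]
  nonref <- dt[dt$base != dt$refBase & dt$refBase != "N"]
  if (!nrow(nonref)) return(empty)
  scored <- nonref[, {
    sc <- qualSum - (sum(qualSum) - qualSum)
    best <- which(sc == max(sc))
    best <- best[order(base[best])][1L]  # deterministic tie-break
    list(altAllele = base[best], alleleScore = sc[best],
         refAllele = refBase[1L])
  }, by = c("refId", "pos")]
  scored <- merge(scored, depthTab, by = c("refId", "pos"))
  keep <- scored$depth >= minDepth & scored$alleleScore >= minAlleleScore
  scored <- scored[keep]
  if (!nrow(scored)) return(empty)
  fl <- t(vapply(seq_len(nrow(scored)), function(r)
    flankLengths(refCharsL[[scored$refId[r]]], scored$pos[r]), integer(2L)))
  out <- data.frame(refId = scored$refId, pos = scored$pos,
                    refAllele = scored$refAllele, altAllele = scored$altAllele,
                    depth = scored$depth, alleleScore = scored$alleleScore,
                    flankLeft = fl[, 1L], flankRight = fl[, 2L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$refId, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write alignments as SAM
#'
#' Minimal SAM with ungapped CIGAR (full-length match) and the NM tag
#' carrying the mismatch count.
#'
#' @param alignments Alignment data.frame from \code{\link{alignShortReads}}.
#' @param refs A \code{\link{ReferenceSet-class}} (for the header).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentsSam <- function(alignments, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(refSeqs(refs)))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refSeqs(refs))[i],
                       Biostrings::width(refSeqs(refs))[i]), con)
  if (nrow(alignments)) {
    w <- nchar(alignments$alnSeq)
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    qual <- vapply(strsplit(alignments$alnQuals, ",", fixed = TRUE),
                   function(q) rawToChar(as.raw(as.integer(q) + 33L)),
                   character(1L))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       alignments$readId, flag, alignments$refId,
                       alignments$refStart, w, alignments$alnSeq, qual,
                       alignments$mismatchCount), con)
  }
  invisible(path)
}

#' Write / read SNP candidates as a VCF-like TSV
#'
#' Columns \code{CHROM} (reference id), \code{POS} (1-based), \code{REF},
#' \code{ALT}, \code{DEPTH}, \code{SCORE}, \code{FLANK_L}, \code{FLANK_R},
#' plus any per-stage flag columns present.
#'
#' @param candidates Candidate data.frame from \code{\link{callSNPs}}.
#' @param path Output path.
#' @return \code{path} (write) or the candidate data.frame (read).
#' @export
writeCandidatesTsv <- function(candidates, path) {
  core <- data.frame(CHROM = candidates$refId, POS = candidates$pos,
                     REF = candidates$refAllele, ALT = candidates$altAllele,
                     DEPTH = candidates$depth, SCORE = candidates$alleleScore,
                     FLANK_L = candidates$flankLeft,
                     FLANK_R = candidates$flankRight)
  extra <- setdiff(colnames(candidates),
                   c("refId", "pos", "refAllele", "altAllele", "depth",
                     "alleleScore", "flankLeft", "flankRight"))
  for (col in extra) core[[col]] <- candidates[[col]]
  utils::write.table(core, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidatesTsv
#' @export
readCandidatesTsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  # single-base alleles like "T" must never be parsed as logicals
  out <- data.frame(refId = as.character(x$CHROM), pos = x$POS,
                    refAllele = as.character(x$REF),
                    altAllele = as.character(x$ALT), depth = x$DEPTH,
                    alleleScore = x$SCORE, flankLeft = x$FLANK_L,
                    flankRight = x$FLANK_R, stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$refAllele <- ifelse(out$refAllele == "TRUE", "T", out$refAllele)
    out$altAllele <- ifelse(out$altAllele == "TRUE", "T", out$altAllele)
  }
  extra <- setdiff(colnames(x), c("CHROM", "POS", "REF", "ALT", "DEPTH",
                                  "SCORE", "FLANK_L", "FLANK_R"))
  for (col in extra) out[[col]] <- x[[col]]
  out
}

#' Write candidates as minimal VCF 4.2
#' @param candidates Candidate data.frame.
#' @param refs A \code{\link{ReferenceSet-class}} (contig headers).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCandidatesVcf <- function(candidates, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##INFO=<ID=SC,Number=1,Type=Float,Description=\"Allele call score\">"),
             con)
  for (i in seq_along(refSeqs(refs)))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(refSeqs(refs))[i],
                       Biostrings::width(refSeqs(refs))[i]), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(candidates))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;SC=%g",
                       candidates$refId, candidates$pos, candidates$refAllele,
                       candidates$altAllele, candidates$depth,
                       candidates$alleleScore), con)
  invisible(path)
}
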