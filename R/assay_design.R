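# Flanking-sequence extraction, a transparent designability heuristic, and
# the e-PCR style primer-pair specificity screen.

maxHomopolymerRun <- function(s) {
  if (!nchar(s)) return(0L)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

gcFraction <- function(s) {
  if (!nchar(s)) return(NA_real_)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Extract assay flanking sequences for candidate SNPs
#'
#' For each candidate, the flanking sequence on each side is extracted up to
#' \code{flank} bases, truncated at the reference end or at the first N.
#' A record is design-eligible only when both flanks provide at least
#' \code{flank} bases of clean (non-N) sequence; \code{designPass}
#' additionally requires that no other candidate SNP lies within
#' \code{flank} bp of the site.
#'
#' @param candidates Candidate data.frame (see \code{\link{callSNPs}}).
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param flank Required clean flank per side, bp (default 60).
#' @return The candidate data.frame with added columns
#'   \code{flankLeftSeq}, \code{flankRightSeq}, \code{flankLeftLen},
#'   \code{flankRightLen}, \code{eligible}, \code{nNeighbors},
#'   \code{designPass}.
#' @export
extractFlanks <- function(candidates, refs, flank = 60L) {
  stopifnot(is(refs, "ReferenceSet"))
  n <- nrow(candidates)
  refChars <- as.character(refSeqs(refs))
  ls <- character(n); rs <- character(n)
  for (r in seq_len(n)) {
    s <- refChars[[candidates$refId[r]]]
    pos <- candidates$pos[r]
    lStart <- max(1L, pos - flank)
    left <- substr(s, lStart, pos - 1L)
    # truncate at the nearest N on each side
    nPos <- gregexpr("N", left, fixed = TRUE)[[1L]]
    if (nPos[1L] != -1L) left <- substr(left, max(nPos) + 1L, nchar(left))
    right <- substr(s, pos + 1L, min(nchar(s), pos + flank))
    nPos <- gregexpr("N", right, fixed = TRUE)[[1L]]
    if (nPos[1L] != -1L) right <- substr(right, 1L, min(nPos) - 1L)
    ls[r] <- left; rs[r] <- right
  }
  candidates$flankLeftSeq <- ls
  candidates$flankRightSeq <- rs
  candidates$flankLeftLen <- nchar(ls)
  candidates$flankRightLen <- nchar(rs)
  candidates$eligible <- candidates$flankLeftLen >= flank &
    candidates$flankRightLen >= flank
  nn <- integer(n)
  for (r in seq_len(n)) {
    same <- candidates$refId == candidates$refId[r]
    nn[r] <- sum(same & abs(candidates$pos - candidates$pos[r]) <= flank) - 1L
  }
  candidates$nNeighbors <- nn
  candidates$designPass <- candidates$eligible & nn == 0L
  candidates
}

#' Transparent assay-designability score
#'
#' A deterministic score in [0, 1] standing in for a proprietary assay
#' design score; it combines, with declared weights: flank-length
#' sufficiency, absence of neighboring candidate SNPs within the flank
#' window, flank GC content within [0.2, 0.8], and absence of homopolymer
#' runs of 8 or more in the flanks. The score is 1.0 exactly when all four
#' criteria are fully satisfied; it is monotone non-increasing in the number
#' of neighboring SNPs and in homopolymer run length, and non-decreasing in
#' the minimum flank length. The conventional 0.4/0.6/0.8 cutpoints can be
#' applied to this proxy as configuration, not as claims of equivalence.
#'
#' @param records Output of \code{\link{extractFlanks}}.
#' @param flank Flank requirement used for the length component (bp).
#' @param weights Numeric length-4 weights (flank, neighbors, GC,
#'   homopolymer); normalized to sum to 1.
#' @return The records with a \code{designability} column.
#' @export
designabilityScore <- function(records, flank = 60L,
                               weights = c(flank = 0.4, neighbors = 0.3,
                                           gc = 0.15, homopolymer = 0.15)) {
  stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  n <- nrow(records)
  score <- numeric(n)
  for (r in seq_len(n)) {
    fl <- min(records$flankLeftLen[r], flank) / flank
    fr <- min(records$flankRightLen[r], flank) / flank
    flankComp <- (fl + fr) / 2
    neighborComp <- 1 / (1 + records$nNeighbors[r])
    gcs <- c(gcFraction(records$flankLeftSeq[r]),
             gcFraction(records$flankRightSeq[r]))
    gcComp <- if (anyNA(gcs)) 0 else mean(gcs >= 0.2 & gcs <= 0.8)
    run <- max(maxHomopolymerRun(records$flankLeftSeq[r]),
               maxHomopolymerRun(records$flankRightSeq[r]))
    hpComp <- if (run < 8L) 1 else max(0, 1 - 0.25 * (run - 7L))
    score[r] <- w[1L] * flankComp + w[2L] * neighborComp + w[3L] * gcComp +
      w[4L] * hpComp
  }
  records$designability <- score
  records
}

#' Naive flank-anchored primer pair for a candidate
#'
#' Primer picking thermodynamics is out of scope; this utility emits the
#' simplest convergent pair for the specificity screen: the outermost
#' \code{primerLen} bases of the left flank as the forward primer and the
#' reverse complement of the outermost \code{primerLen} bases of the right
#' flank as the reverse primer.
#'
#' @param record One row of \code{\link{extractFlanks}} output.
#' @param primerLen Primer length (default 20, must lie in [15, 30]).
#' @return A list: \code{left}, \code{right} (character primers).
#' @export
designPrimerPair <- function(record, primerLen = 20L) {
  stopifnot(primerLen >= 15L, primerLen <= 30L)
  if (nchar(record$flankLeftSeq) < primerLen ||
      nchar(record$flankRightSeq) < primerLen)
    stop("flanks shorter than the primer length")
  left <- substr(record$flankLeftSeq, 1L, primerLen)
  rf <- record$flankRightSeq
  right <- revcompChar(substr(rf, nchar(rf) - primerLen + 1L, nchar(rf)))
  list(left = left, right = right)
}

# All placements of 'primer' on the forward strand of 'refChar' with at
# most nMismatches substitutions and at most nGaps gaps (single-base
# insertion or deletion). Returns a data.frame (start, end) of 1-based
# spans on the reference.
primerPlacements <- function(primer, refChar, nMismatches, nGaps) {
  m <- nchar(primer)
  L <- nchar(refChar)
  if (L < m - nGaps) return(data.frame(start = integer(), end = integer()))
  p <- charToRaw(primer)
  s <- charToRaw(refChar)
  # per-offset mismatch vector helpers: mmAt[[j]][i] = primer[j] != ref[i+j-1]
  hits <- list()
  addHit <- function(start, end) hits[[length(hits) + 1L]] <<- c(start, end)
  # ungapped placements
  if (L >= m) {
    mmCount <- integer(L - m + 1L)
    for (j in seq_len(m))
      mmCount <- mmCount + as.integer(s[j:(L - m + j)] != p[j])
    for (st in which(mmCount <= nMismatches)) addHit(st, st + m - 1L)
  }
  if (nGaps >= 1L && m >= 2L) {
    # one deletion in the primer (primer spans m-1 reference bases):
    # primer base g is skipped, g in 1..m
    if (L >= m - 1L) {
      nStarts <- L - m + 2L
      pref <- matrix(0L, nrow = m + 1L, ncol = nStarts)  # mism. of p[1..j] ungapped
      for (j in seq_len(m))
        if (j <= m - 1L)
          pref[j + 1L, ] <- pref[j, ] + as.integer(s[j:(L - m + 1L + j)] != p[j])
      # suffix mism. of p[j..m] aligned shifted left by one (after deletion)
      suff <- matrix(0L, nrow = m + 2L, ncol = nStarts)
      for (j in m:2L)
        suff[j, ] <- suff[j + 1L, ] + as.integer(s[(j - 1L):(L - m + j)] != p[j])
      for (g in seq_len(m)) {
        tot <- pref[g, ] + suff[g + 1L, ]
        for (st in which(tot <= nMismatches)) addHit(st, st + m - 2L)
      }
    }
    # one insertion in the primer relative to the reference (primer spans
    # m+1 reference bases): reference base after position g is skipped
    if (L >= m + 1L) {
      nStarts <- L - m
      pref <- matrix(0L, nrow = m + 1L, ncol = nStarts)
      for (j in seq_len(m))
        pref[j + 1L, ] <- pref[j, ] + as.integer(s[j:(L - m - 1L + j)] != p[j])
      suff <- matrix(0L, nrow = m + 2L, ncol = nStarts)
      for (j in m:1L)
        suff[j, ] <- suff[j + 1L, ] + as.integer(s[(j + 1L):(L - m + j)] != p[j])
      for (g in 0L:m) {
        tot <- pref[g + 1L, ] + suff[g + 1L, ]
        for (st in which(tot <= nMismatches)) addHit(st, st + m)
      }
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  h <- unique(do.call(rbind, hits))
  data.frame(start = h[, 1L], end = h[, 2L])
}

#' e-PCR style primer-pair specificity screen
#'
#' Locates all convergent placements of a primer pair across the reference
#' set with bounded per-primer substitutions (\code{nMismatches}) and gaps
#' (\code{nGaps}): the forward primer on the plus strand, the reverse
#' primer's reverse complement downstream on the plus strand, with a
#' product size within \code{productRange} (+/- \code{margin}). The pair
#' passes iff exactly one such hit exists over all references; pairs
#' amplifying from more than one location are discarded.
#'
#' @param pair A list with \code{left} and \code{right} primers (see
#'   \code{\link{designPrimerPair}}); lengths must lie in [15, 30].
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param nMismatches Per-primer substitution budget (default 3).
#' @param nGaps Per-primer gap budget (default 1).
#' @param productRange Allowed product length range, bp (default c(80, 300)).
#' @param margin Extra slack on the product range, bp.
#' @return A list: \code{hits} (data.frame \code{refId}, \code{leftStart},
#'   \code{rightEnd}, \code{productLen}) and \code{pass} (logical).
#' @export
epcrScreen <- function(pair, refs, nMismatches = 3L, nGaps = 1L,
                       productRange = c(80L, 300L), margin = 0L) {
  stopifnot(is(refs, "ReferenceSet"))
  left <- toupper(pair$left); right <- toupper(pair$right)
  if (nchar(left) < 15L || nchar(left) > 30L ||
      nchar(right) < 15L || nchar(right) > 30L)
    stop("primer lengths must lie in [15, 30]")
  rightRc <- revcompChar(right)
  lo <- productRange[1L] - margin; hi <- productRange[2L] + margin
  refChars <- as.character(refSeqs(refs))
  # collapse overlapping placements (gapped variants of one annealing site)
  # into one locus, represented by the placement whose span is closest to
  # the ungapped primer length, then leftmost
  reduceLoci <- function(pl, m) {
    if (nrow(pl) <= 1L) return(pl)
    ir <- IRanges(pl$start, pl$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    rep <- vapply(S4Vectors::mcols(red)$revmap, function(ix) {
      span <- pl$end[ix] - pl$start[ix] + 1L
      ix[order(abs(span - m), pl$start[ix])][1L]
    }, integer(1L))
    pl[rep, , drop = FALSE]
  }
  hits <- list()
  for (i in seq_along(refChars)) {
    lp <- reduceLoci(primerPlacements(left, refChars[i], nMismatches, nGaps),
                     nchar(left))
    if (!nrow(lp)) next
    rp <- reduceLoci(primerPlacements(rightRc, refChars[i], nMismatches, nGaps),
                     nchar(rightRc))
    if (!nrow(rp)) next
    for (a in seq_len(nrow(lp))) for (b in seq_len(nrow(rp))) {
      if (rp$start[b] <= lp$end[a]) next  # must be convergent, non-overlapping
      prod <- rp$end[b] - lp$start[a] + 1L
      if (prod >= lo && prod <= hi)
        hits[[length(hits) + 1L]] <- data.frame(
          refId = names(refChars)[i], leftStart = lp$start[a],
          rightEnd = rp$end[b], productLen = prod, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(refId = character(), leftStart = integer(),
                          rightEnd = integer(), productLen = integer(),
                          stringsAsFactors = FALSE)
  list(hits = hits, pass = nrow(hits) == 1L)
}

#' Write the assay table
#'
#' TSV with one row per candidate: SNP id, alleles, designability, and the
#' combined flank column with the SNP written as \code{[X/Y]} between the
#' flanks.
#'
#' @param records Output of \code{\link{designabilityScore}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAssayTable <- function(records, path) {
  out <- data.frame(
    snp_id = sprintf("%s_%d", records$refId, records$pos),
    alleles = sprintf("%s/%s", records$refAllele, records$altAllele),
    designability = records$designability,
    design_pass = records$designPass,
    sequence = sprintf("%s[%s/%s]%s", records$flankLeftSeq,
                       records$refAllele, records$altAllele,
                       records$flankRightSeq))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
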