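# In-silico restriction digestion and two-tier size selection.

# Expand an IUPAC motif into a fixed-width regular expression character class.
iupacToRegex <- function(motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    ex <- map[[ch]]
    if (is.null(ex)) stop(sprintf("invalid IUPAC code '%s'", ch))
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1L)), collapse = "")
}

#' Find restriction cut sites on a sequence
#'
#' Returns the 0-based between-base cut positions produced by a palindromic
#' blunt cutter on a sequence. A cut at position p separates
#' \code{seq[1..p]} from \code{seq[(p+1)..]} (1-based reading). Because the
#' recognition motifs are palindromic, scanning the forward strand covers
#' both strands; overlapping motif occurrences are all reported.
#'
#' @param seq A DNA string (character or \code{DNAString}), uppercase.
#' @param enzyme A \code{\link{RestrictionEnzyme}}.
#' @return Sorted integer vector of distinct 0-based cut positions (possibly
#'   empty). Cuts at the extreme ends (position 0 or sequence length) are
#'   dropped: they do not separate any bases.
#' @examples
#' findCutSites("AAGGCCTT", RestrictionEnzyme("HaeIII", "GGCC", 2L))
#' @export
findCutSites <- function(seq, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  s <- as.character(seq)
  pat <- iupacToRegex(enzyme@recognition)
  # lookahead so overlapping motif occurrences are all found
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  cuts <- as.integer(m) - 1L + enzyme@cutOffset
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(s)]
}

# Fragment boundaries (1-based starts/ends) from a sorted 0-based cut vector.
cutsToIntervals <- function(cuts, len) {
  bounds <- c(0L, cuts, len)
  data.frame(start = bounds[-length(bounds)] + 1L, end = bounds[-1L])
}

#' Digest a sequence with a set of enzymes
#'
#' A complete-digest model: fragments are the maximal intervals between
#' consecutive cut positions (the union over all enzymes), including the
#' sequence ends. Blunt cutting loses no bases, so the fragments concatenate
#' back to the input exactly.
#'
#' @param seq A DNA string (character, \code{DNAString}, or
#'   \code{\link{GenomeSequence-class}}).
#' @param enzymes A list of \code{\link{RestrictionEnzyme}} objects.
#' @param sourceId Label recorded as the fragments' source; defaults to the
#'   genome id when \code{seq} is a \code{GenomeSequence}.
#' @param tier Tier label for the produced fragments (1 or 2).
#' @return A \code{\link{FragmentSet-class}}.
#' @examples
#' frags <- digestSeq("AAGGCCTT", tier1Enzymes())
#' as.character(fragmentSeqs(frags))
#' @export
digestSeq <- function(seq, enzymes, sourceId = NULL, tier = 1L,
                      parent = NA_character_) {
  if (is(seq, "GenomeSequence")) {
    if (is.null(sourceId)) sourceId <- genomeId(seq)
    seq <- seq@seq
  }
  if (is.null(sourceId)) sourceId <- "seq"
  if (!length(enzymes)) stop("at least one enzyme is required")
  s <- as.character(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) findCutSites(s, e)))))
  iv <- cutsToIntervals(as.integer(cuts), nchar(s))
  fragId <- sprintf("%s:%d-%d:t%d", sourceId, iv$start - 1L, iv$end, tier)
  seqs <- DNAStringSet(substring(s, iv$start, iv$end))
  FragmentSet(seqs, data.frame(
    fragId = fragId, sourceId = sourceId, start = iv$start, end = iv$end,
    tier = as.integer(tier), parent = parent,
    stringsAsFactors = FALSE))
}

#' Size-select fragments within an inclusive window
#'
#' Models gel excision of a length window: fragments whose lengths fall in
#' \code{[window[1], window[2]]} (both ends inclusive) are kept in input
#' order; all others are dropped.
#'
#' @param fragments A \code{\link{FragmentSet-class}}.
#' @param window Integer length-2 inclusive window in bp.
#' @return A \code{\link{FragmentSet-class}} subset of the input.
#' @export
sizeSelect <- function(fragments, window) {
  stopifnot(is(fragments, "FragmentSet"), length(window) == 2L,
            window[1L] <= window[2L])
  w <- fragmentWidths(fragments)
  fragments[w >= window[1L] & w <= window[2L]]
}

#' Second-tier digestion of size-selected fragments
#'
#' Re-digests tier-1 fragments with the second-tier enzyme set and
#' size-selects the products. Tier-2 fragments carry their parent fragment
#' id and coordinates on the original source sequence, nested within the
#' parent's interval.
#'
#' @param tier1 A \code{\link{FragmentSet-class}} of tier-1 fragments.
#' @param enzymes2 Second-tier enzyme list (non-empty).
#' @param window2 Inclusive tier-2 size window in bp.
#' @return A \code{\link{FragmentSet-class}} with \code{tier == 2}.
#' @export
secondTierDigest <- function(tier1, enzymes2, window2 = c(110L, 140L)) {
  stopifnot(is(tier1, "FragmentSet"))
  if (!length(enzymes2)) stop("the tier-2 enzyme list must be non-empty")
  if (length(tier1) && any(fragmentInfo(tier1)$tier != 1L))
    stop("'tier1' must contain tier-1 fragments")
  info1 <- fragmentInfo(tier1)
  fragChars <- as.character(fragmentSeqs(tier1))
  pieces <- lapply(seq_len(length(tier1)), function(i) {
    s <- fragChars[i]
    cuts <- sort(unique(unlist(lapply(enzymes2, function(e) findCutSites(s, e)))))
    iv <- cutsToIntervals(as.integer(cuts), nchar(s))
    # lift coordinates from the fragment to the original source
    iv$start <- iv$start + info1$start[i] - 1L
    iv$end <- iv$end + info1$start[i] - 1L
    w <- iv$end - iv$start + 1L
    keep <- w >= window2[1L] & w <= window2[2L]
    iv <- iv[keep, , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    data.frame(fragId = sprintf("%s:%d-%d:t2", info1$sourceId[i],
                                iv$start - 1L, iv$end),
               sourceId = info1$sourceId[i], start = iv$start, end = iv$end,
               tier = 2L, parent = info1$fragId[i],
               seq = substring(s, iv$start - info1$start[i] + 1L,
                               iv$end - info1$start[i] + 1L),
               stringsAsFactors = FALSE)
  })
  info <- do.call(rbind, pieces)
  if (is.null(info))
    return(FragmentSet(DNAStringSet(),
                       as.data.frame(info1[0, , drop = FALSE])))
  seqs <- DNAStringSet(info$seq)
  info$seq <- NULL
  FragmentSet(seqs, info)
}

#' Fragment-length diagnostic for enzyme choice
#'
#' The enzymes for each tier were chosen so that digestion produced no
#' visible banding in the selection window — banding indicates restriction
#' sites inside highly repetitive elements. This diagnostic tabulates
#' fragment lengths within a window and flags when the number of fragments
#' overlapping repeat-annotated intervals exceeds a count threshold.
#'
#' @param fragments A \code{\link{FragmentSet-class}}.
#' @param window Inclusive size window to inspect.
#' @param genome Optional annotated \code{\link{GenomeSequence-class}} the
#'   fragments came from (for the repeat overlap count).
#' @param maxRepeatCount Flag threshold for repeat-overlapping in-window fragments.
#' @return A list: \code{lengthTable} (table of in-window lengths),
#'   \code{nInWindow}, \code{nRepeatInWindow}, \code{bandingFlag}.
#' @export
fragmentLengthDiagnostic <- function(fragments, window, genome = NULL,
                                     maxRepeatCount = 25L) {
  w <- fragmentWidths(fragments)
  inWin <- w >= window[1L] & w <= window[2L]
  nRep <- 0L
  if (!is.null(genome) && length(genomeAnnotations(genome))) {
    rep_ann <- genomeAnnotations(genome)
    rep_ann <- rep_ann[rep_ann$class == "repeat"]
    if (length(rep_ann) && any(inWin)) {
      info <- fragmentInfo(fragments)[inWin, , drop = FALSE]
      fr <- GRanges(as.character(seqnames(rep_ann))[1L],
                    IRanges(info$start, info$end))
      nRep <- sum(IRanges::overlapsAny(fr, rep_ann))
    }
  }
  list(lengthTable = table(w[inWin]), nInWindow = sum(inWin),
       nRepeatInWindow = nRep, bandingFlag = nRep > maxRepeatCount)
}

#' Write fragments as FASTA plus BED of source coordinates
#' @param fragments A \code{\link{FragmentSet-class}}.
#' @param fastaPath,bedPath Output paths (\code{NULL} to skip the BED).
#' @return \code{fastaPath}, invisibly.
#' @export
writeFragments <- function(fragments, fastaPath, bedPath = NULL) {
  writeXStringSet(fragmentSeqs(fragments), fastaPath, width = 80L)
  if (!is.null(bedPath)) {
    info <- fragmentInfo(fragments)
    out <- data.frame(chrom = info$sourceId, start = info$start - 1L,
                      end = info$end, name = info$fragId)
    utils::write.table(out, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fastaPath)
}
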