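# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately avoid the code paths they check.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

revcompOracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force cut-site scan: test every offset of the motif against the
# sequence, character by character, through the IUPAC sets.
cutSitesOracle <- function(seq, motif, cutOffset) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  ml <- length(mchars)
  L <- length(chars)
  hits <- integer()
  for (p in seq_len(L - ml + 1L)) {
    ok <- TRUE
    for (j in seq_len(ml)) {
      if (!(chars[p + j - 1L] %in% IUPAC_SETS[[mchars[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p - 1L + cutOffset)
  }
  hits <- sort(unique(hits))
  hits[hits > 0L & hits < L]
}

# Exhaustive ungapped alignment: every (reference, offset, strand), Hamming
# distance computed with Biostrings::neditStartingAt (a different primitive
# than the seeded search under test).
alignOracle <- function(readStr, refs, maxMismatches = 2L) {
  refChars <- as.character(refSeqs(refs))
  w <- nchar(readStr)
  placements <- list()
  for (i in seq_along(refChars)) {
    L <- nchar(refChars[i])
    if (L < w) next
    subj <- Biostrings::DNAString(refChars[i])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") readStr else revcompOracle(readStr)
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(p), subj,
                                        starting.at = seq_len(L - w + 1L),
                                        with.indels = FALSE)
      for (st in which(mm <= maxMismatches))
        placements[[length(placements) + 1L]] <-
          data.frame(refId = names(refChars)[i], start = st, strand = strand,
                     mm = mm[st], stringsAsFactors = FALSE)
    }
  }
  if (!length(placements))
    return(list(status = "unmapped"))
  pl <- do.call(rbind, placements)
  best <- pl[pl$mm == min(pl$mm), , drop = FALSE]
  if (nrow(best) > 1L) list(status = "ambiguous")
  else list(status = "aligned", refId = best$refId, start = best$start,
            strand = best$strand, mm = best$mm)
}

# Naive enumeration of primer placements with <= nMismatches substitutions
# and <= nGaps single-base gaps (character-by-character, no vectorization).
primerPlacementsOracle <- function(primer, refChar, nMismatches, nGaps) {
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  s <- strsplit(refChar, "", fixed = TRUE)[[1L]]
  m <- length(p); L <- length(s)
  hits <- list()
  ham <- function(a, b) sum(a != b)
  # ungapped
  if (L >= m)
    for (st in seq_len(L - m + 1L))
      if (ham(p, s[st:(st + m - 1L)]) <= nMismatches)
        hits[[length(hits) + 1L]] <- c(st, st + m - 1L)
  if (nGaps >= 1L) {
    # one primer base skipped (span m-1)
    if (L >= m - 1L)
      for (st in seq_len(L - m + 2L))
        for (g in seq_len(m)) {
          sub <- 0L
          if (g > 1L) sub <- sub + ham(p[1:(g - 1L)], s[st:(st + g - 2L)])
          if (g < m) sub <- sub + ham(p[(g + 1L):m], s[(st + g - 1L):(st + m - 2L)])
          if (sub <= nMismatches) hits[[length(hits) + 1L]] <- c(st, st + m - 2L)
        }
    # one reference base skipped (span m+1)
    if (L >= m + 1L)
      for (st in seq_len(L - m)) {
        for (g in 0L:m) {
          sub <- 0L
          if (g >= 1L) sub <- sub + ham(p[1:g], s[st:(st + g - 1L)])
          if (g < m) sub <- sub + ham(p[(g + 1L):m], s[(st + g + 1L):(st + m)])
          if (sub <= nMismatches) hits[[length(hits) + 1L]] <- c(st, st + m)
        }
      }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  h <- unique(do.call(rbind, hits))
  data.frame(start = h[, 1L], end = h[, 2L])
}

# Fixture: a ReadSet built directly from explicit sequences.
makeReads <- function(seqs, quals = NULL, fragIds = NULL, strands = NULL,
                      offsets = NULL, prefix = "rd") {
  n <- length(seqs)
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(w) rep(35L, w))
  if (is.null(fragIds)) fragIds <- rep("frag", n)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(offsets)) offsets <- rep(0L, n)
  ReadSet(Biostrings::DNAStringSet(seqs), quals,
          data.frame(readId = sprintf("%s_%03d", prefix, seq_len(n)),
                     fragId = fragIds, strand = strands, offset = offsets,
                     stringsAsFactors = FALSE))
}

# Fixture: a ReferenceSet from bare sequences (full qualities, no provenance).
makeRefs <- function(seqs, nReads = NULL, quals = NULL) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("ref_%03d", seq_len(n))
  if (is.null(nReads)) nReads <- rep(2L, n)
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(w) rep(40L, w))
  ReferenceSet(Biostrings::DNAStringSet(seqs), nReads, quals)
}

# Fixture: a tier-1/tier-2 FragmentSet directly from sequences.
makeFragments <- function(seqs, tier = 1L, sourceId = "genomeT",
                          starts = NULL) {
  n <- length(seqs)
  w <- nchar(seqs)
  if (is.null(starts)) starts <- cumsum(c(1L, utils::head(w + 10L, -1L)))
  info <- data.frame(
    fragId = sprintf("%s:%d-%d:t%d", sourceId, starts - 1L, starts + w - 1L, tier),
    sourceId = sourceId, start = starts, end = starts + w - 1L,
    tier = as.integer(tier),
    parent = if (tier == 2L) sprintf("parent_%03d", seq_len(n)) else NA_character_,
    stringsAsFactors = FALSE)
  FragmentSet(Biostrings::DNAStringSet(seqs), info)
}
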