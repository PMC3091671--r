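# Long-read reference construction: greedy seed-and-extend clustering with
# per-column majority consensus, quality masking, reference filtering, and
# the shared-word exclusion-library screen.

# Internal mutable cluster record, coordinates are "absolute": the first
# (root) read occupies abs positions 1..len; later reads may extend the
# range to either side. counts is a 4 x ncol integer matrix (A,C,G,T rows),
# aligned to abs coords minC..maxC.
newCluster <- function(codes, quals, readIdx) {
  len <- length(codes)
  counts <- matrix(0L, nrow = 4L, ncol = len)
  counts[cbind(codes, seq_len(len))] <- 1L
  list(counts = counts, qual = quals, minC = 1L, maxC = len,
       cons = codes, members = readIdx,
       memberStart = 1L, memberOrient = "F")
}

clusterAddRead <- function(cl, codes, quals, o, readIdx, orient) {
  len <- length(codes)
  lo <- min(cl$minC, o); hi <- max(cl$maxC, o + len - 1L)
  padL <- cl$minC - lo; padR <- hi - cl$maxC
  if (padL > 0L || padR > 0L) {
    counts <- matrix(0L, nrow = 4L, ncol = hi - lo + 1L)
    counts[, (padL + 1L):(padL + ncol(cl$counts))] <- cl$counts
    cl$counts <- counts
    cl$qual <- c(rep(0L, padL), cl$qual, rep(0L, padR))
    cl$cons <- c(rep(0L, padL), cl$cons, rep(0L, padR))
    cl$minC <- lo; cl$maxC <- hi
  }
  idx <- (o - cl$minC + 1L):(o - cl$minC + len)
  cl$counts[cbind(codes, idx)] <- cl$counts[cbind(codes, idx)] + 1L
  cl$qual[idx] <- pmax(cl$qual[idx], quals)
  # refresh majority consensus on the touched columns; ties -> 0 (N)
  sub <- cl$counts[, idx, drop = FALSE]
  best <- max.col(t(sub), ties.method = "first")
  bestCnt <- sub[cbind(best, seq_along(idx))]
  tied <- colSums(sub == rep(bestCnt, each = 4L)) > 1L
  cl$cons[idx] <- ifelse(tied, 0L, best)
  cl$members <- c(cl$members, readIdx)
  cl$memberStart <- c(cl$memberStart, o)
  cl$memberOrient <- c(cl$memberOrient, orient)
  cl
}

#' Cluster long reads into a reference set
#'
#' A greedy seed-and-extend clustering that stands in, at contract level,
#' for a de novo assembler: reads are processed in order; each read is
#' matched against existing cluster consensi via shared exact k-mers
#' (k = \code{minOverlap}), in both orientations; if the best ungapped
#' overlap reaches \code{minOverlap} bases at identity >= \code{minIdentity}
#' the read joins that cluster (extending the consensus by per-column
#' majority, ambiguous/tied columns become N), otherwise it seeds a new
#' cluster. Clusters with one read are emitted as singletons. Per-column
#' quality is the maximum supporting read quality. When the reads carry
#' truth placements, per-column genome provenance is propagated from each
#' cluster's root read (exact for ungapped, indel-free reads).
#'
#' @param reads A \code{\link{ReadSet-class}} of long reads.
#' @param minIdentity Minimum ungapped overlap identity to merge (default 0.98).
#' @param minOverlap Minimum overlap length in bp, also the seed k-mer size
#'   (default 40).
#' @param fragments Optional tier-1 \code{\link{FragmentSet-class}} the reads
#'   were simulated from; enables genome provenance tracking.
#' @param seedStep Spacing of indexed k-mer start positions along each read.
#' @return A \code{\link{ReferenceSet-class}}.
#' @export
clusterLongReads <- function(reads, minIdentity = 0.98, minOverlap = 40L,
                             fragments = NULL, seedStep = 12L) {
  stopifnot(is(reads, "ReadSet"))
  n <- length(reads)
  if (!n) stop("'reads' must be non-empty")
  k <- as.integer(minOverlap)
  readStr <- as.character(readSeqs(reads))
  readRc <- vapply(readStr, revcompChar, character(1L), USE.NAMES = FALSE)
  qualsL <- readQuals(reads)
  idx <- new.env(hash = TRUE, parent = emptyenv())  # kmer -> matrix(cluster, absPos)
  clusters <- vector("list", n)
  nCl <- 0L

  encode <- function(s) match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)

  # query k-mers are sampled along the read; index k-mers cover every
  # position of each cluster's span, so any >= k overlap is discoverable
  # regardless of the offset between read and cluster
  queryStarts <- function(len) {
    if (len < k) return(integer())
    unique(c(seq(1L, len - k + 1L, by = seedStep), len - k + 1L))
  }

  indexKmers <- function(cid, s, firstAbs, from, to) {
    # index k-mers of oriented read string s (abs coord of base 1 =
    # firstAbs) whose spans intersect abs range [from, to]
    len <- nchar(s)
    pLo <- max(1L, from - firstAbs + 1L - (k - 1L))
    pHi <- min(len - k + 1L, to - firstAbs + 1L)
    if (pHi < pLo) return(invisible())
    starts <- pLo:pHi
    kmers <- substring(s, starts, starts + k - 1L)
    for (j in seq_along(kmers)) {
      prev <- idx[[kmers[j]]]
      idx[[kmers[j]]] <- rbind(prev, c(cid, firstAbs + starts[j] - 1L))
    }
    invisible()
  }

  for (i in seq_len(n)) {
    len <- nchar(readStr[i])
    best <- NULL
    for (orient in c("F", "R")) {
      s <- if (orient == "F") readStr[i] else readRc[i]
      starts <- queryStarts(len)
      if (!length(starts)) next
      kmers <- substring(s, starts, starts + k - 1L)
      cand <- list()
      for (j in seq_along(kmers)) {
        hits <- idx[[kmers[j]]]
        if (is.null(hits)) next
        for (r in seq_len(nrow(hits)))
          cand[[length(cand) + 1L]] <- c(hits[r, 1L], hits[r, 2L] - starts[j] + 1L)
      }
      if (!length(cand)) next
      cand <- unique(do.call(rbind, cand))
      codes <- encode(s)
      for (r in seq_len(nrow(cand))) {
        cid <- cand[r, 1L]; o <- cand[r, 2L]
        cl <- clusters[[cid]]
        lo <- max(o, cl$minC); hi <- min(o + len - 1L, cl$maxC)
        ov <- hi - lo + 1L
        if (ov < k) next
        consPart <- cl$cons[(lo - cl$minC + 1L):(hi - cl$minC + 1L)]
        readPart <- codes[(lo - o + 1L):(hi - o + 1L)]
        ident <- sum(consPart == readPart) / ov
        if (ident >= minIdentity &&
            (is.null(best) || ident > best$ident ||
             (ident == best$ident && ov > best$ov))) {
          best <- list(cid = cid, o = o, ident = ident, ov = ov,
                       orient = orient, codes = codes)
        }
      }
    }
    if (!is.null(best)) {
      cid <- best$cid
      oldMin <- clusters[[cid]]$minC; oldMax <- clusters[[cid]]$maxC
      q <- qualsL[[i]]
      if (best$orient == "R") q <- rev(q)
      clusters[[cid]] <- clusterAddRead(clusters[[cid]], best$codes,
                                        q, best$o, i, best$orient)
      s <- if (best$orient == "F") readStr[i] else readRc[i]
      # only k-mers reaching outside the previously indexed span are new
      if (best$o < oldMin)
        indexKmers(cid, s, best$o, best$o, oldMin - 1L)
      if (best$o + len - 1L > oldMax)
        indexKmers(cid, s, best$o, oldMax + 1L, best$o + len - 1L)
    } else {
      nCl <- nCl + 1L
      clusters[[nCl]] <- newCluster(encode(readStr[i]), qualsL[[i]], i)
      indexKmers(nCl, readStr[i], 1L, 1L, len)
    }
  }
  clusters <- clusters[seq_len(nCl)]

  info <- readInfo(reads)
  fragInfo <- if (!is.null(fragments)) fragmentInfo(fragments) else NULL
  seqs <- character(nCl); nReads <- integer(nCl)
  quals <- vector("list", nCl); prov <- vector("list", nCl)
  for (c in seq_len(nCl)) {
    cl <- clusters[[c]]
    chars <- c("N", DNA_BASES)[cl$cons + 1L]
    seqs[c] <- paste(chars, collapse = "")
    nReads[c] <- length(cl$members)
    quals[[c]] <- cl$qual
    if (!is.null(fragInfo)) {
      root <- cl$members[1L]
      fi <- match(info$fragId[root], fragInfo$fragId)
      if (!is.na(fi)) {
        fragStart <- fragInfo$start[fi]
        off <- info$offset[root]
        rl <- nchar(readStr[root])
        cols <- cl$minC:cl$maxC  # root read base index = abs coord
        if (info$strand[root] == "+") {
          prov[[c]] <- list(sourceId = fragInfo$sourceId[fi],
                            genomePos = fragStart + off + cols - 1L,
                            strand = "+")
        } else {
          prov[[c]] <- list(sourceId = fragInfo$sourceId[fi],
                            genomePos = fragStart + off + rl - cols,
                            strand = "-")
        }
      } else prov[c] <- list(NULL)
    }
  }
  names(seqs) <- sprintf("ref_%06d", seq_len(nCl))
  ReferenceSet(DNAStringSet(seqs), nReads, quals,
               if (!is.null(fragInfo)) prov else list())
}

#' Mask low-quality reference bases to N
#'
#' Every consensus base whose per-column Phred quality is strictly below the
#' threshold is changed to N (a base at exactly the threshold is retained).
#' Lengths are preserved.
#'
#' @param refs A \code{\link{ReferenceSet-class}} with per-column qualities.
#' @param threshold Phred threshold (default 20).
#' @return A \code{\link{ReferenceSet-class}} of the same shape.
#' @export
maskLowQuality <- function(refs, threshold = 20L) {
  stopifnot(is(refs, "ReferenceSet"))
  if (!length(refs@quals))
    stop("reference set carries no per-column qualities")
  if (any(lengths(refs@quals) != Biostrings::width(refs@seqs)))
    stop("quality vectors must match reference lengths")
  chars <- as.character(refs@seqs)
  masked <- vapply(seq_along(chars), function(i) {
    v <- strsplit(chars[i], "", fixed = TRUE)[[1L]]
    v[refs@quals[[i]] < threshold] <- "N"
    paste(v, collapse = "")
  }, character(1L))
  names(masked) <- names(refs@seqs)
  ReferenceSet(DNAStringSet(masked), refs@nReads, refs@quals, refs@provenance)
}

#' Filter references by length and N fraction
#'
#' A reference is kept iff its length is at least \code{minLen} bases and
#' the fraction of N bases does not exceed \code{maxNFraction}; everything
#' else is eliminated. Kept and eliminated partition the input.
#'
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param minLen Minimum kept length (default 61).
#' @param maxNFraction Maximum tolerated N fraction (default 0.75).
#' @return A list: \code{kept}, \code{eliminated} (both
#'   \code{ReferenceSet}s), and \code{counts} (nIn, nEliminated, nKept).
#' @export
filterReferences <- function(refs, minLen = 61L, maxNFraction = 0.75) {
  stopifnot(is(refs, "ReferenceSet"))
  w <- Biostrings::width(refs@seqs)
  nFrac <- Biostrings::letterFrequency(refs@seqs, "N")[, 1L] / w
  keep <- w >= minLen & nFrac <= maxNFraction
  list(kept = refs[which(keep)], eliminated = refs[which(!keep)],
       counts = c(nIn = length(refs), nEliminated = sum(!keep),
                  nKept = sum(keep)))
}

#' Screen references against an exclusion library
#'
#' Flags every reference that shares at least one exact word of
#' \code{wordSize} bases with any library sequence, on either strand — the
#' seed requirement of a word-size-30 megablast search, applied without
#' extension, which is conservative relative to seeded extension. N bases
#' never match, so masked positions break words.
#'
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param library A \code{DNAStringSet} (or character vector) of exclusion
#'   sequences (organellar, repeat, or contaminant).
#' @param wordSize Exact shared-word length (default 30).
#' @return A list: \code{kept}, \code{flagged} (both \code{ReferenceSet}s),
#'   and \code{counts}.
#' @export
screenLibrary <- function(refs, library, wordSize = 30L) {
  stopifnot(is(refs, "ReferenceSet"))
  library <- as(library, "DNAStringSet")
  if (!length(library))
    stop("screening requested with an empty library")
  flaggedIdx <- screenSeqsAgainstLibrary(refs@seqs, library, wordSize)
  keep <- !(seq_along(refs@seqs) %in% flaggedIdx)
  list(kept = refs[which(keep)], flagged = refs[which(!keep)],
       counts = c(nIn = length(refs), nFlagged = sum(!keep),
                  nKept = sum(keep)))
}

# Shared-word screen core: indices of 'seqs' sharing an exact word of
# 'wordSize' with any library sequence on either strand.
screenSeqsAgainstLibrary <- function(seqs, library, wordSize) {
  library <- as(library, "DNAStringSet")
  wide <- library[Biostrings::width(library) >= wordSize]
  if (!length(wide) || !length(seqs)) return(integer())
  words <- unique(unlist(lapply(seq_along(wide), function(i) {
    s <- as.character(wide[[i]])
    starts <- seq_len(nchar(s) - wordSize + 1L)
    c(substring(s, starts, starts + wordSize - 1L))
  })))
  words <- words[!grepl("[^ACGT]", words)]
  if (!length(words)) return(integer())
  ws <- DNAStringSet(words)
  dict <- unique(c(ws, Biostrings::reverseComplement(ws)))
  pd <- Biostrings::PDict(dict)
  hits <- Biostrings::vwhichPDict(pd, seqs)
  which(lengths(hits) > 0L)
}

#' Persist / load a ReferenceSet
#'
#' FASTA for the sequences plus a JSON sidecar carrying supporting-read
#' counts, per-column qualities and genome provenance, so stage outputs can
#' be reloaded by later pipeline stages.
#'
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param fastaPath FASTA path.
#' @param sidecarPath JSON sidecar path (default: \code{fastaPath} + \code{".json"}).
#' @return \code{fastaPath} (write) or a \code{ReferenceSet} (load).
#' @export
writeReferenceSet <- function(refs, fastaPath,
                              sidecarPath = paste0(fastaPath, ".json")) {
  writeXStringSet(refs@seqs, fastaPath, width = 80L)
  side <- list(nReads = refs@nReads, quals = refs@quals,
               provenance = refs@provenance)
  jsonlite::write_json(side, sidecarPath, auto_unbox = FALSE, digits = NA)
  invisible(fastaPath)
}

#' @rdname writeReferenceSet
#' @export
readReferenceSet <- function(fastaPath,
                             sidecarPath = paste0(fastaPath, ".json")) {
  seqs <- readDNAStringSet(fastaPath)
  side <- jsonlite::read_json(sidecarPath, simplifyVector = FALSE)
  prov <- side$provenance
  if (is.null(prov) || !length(prov)) prov <- list()
  else prov <- lapply(prov, function(p) {
    if (is.null(p) || !length(p)) NULL
    else list(sourceId = unlist(p$sourceId),
              genomePos = as.integer(unlist(p$genomePos)),
              strand = unlist(p$strand))
  })
  quals <- side$quals
  if (is.null(quals)) quals <- list()
  else quals <- lapply(quals, function(q) as.integer(unlist(q)))
  ReferenceSet(seqs, as.integer(unlist(side$nReads)), quals, prov)
}
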