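# Simulation of long (454-style) and short (GA-style) sequencing reads
# over digestion fragments, with each platform's characteristic error mode.

#' A set of simulated sequencing reads
#'
#' Reads with per-base Phred qualities and truth placement (source fragment,
#' strand, 0-based offset on the fragment) for downstream evaluation.
#'
#' @slot seqs \code{DNAStringSet}, named by read id.
#' @slot quals List of integer Phred vectors (0-41), one per read.
#' @slot info \code{DataFrame} with columns \code{readId}, \code{fragId},
#'   \code{strand} (read orientation relative to the fragment), \code{offset}
#'   (0-based start of the sampled window on the fragment).
#' @export
setClass("ReadSet",
  representation(seqs = "DNAStringSet", quals = "list", info = "DataFrame"))

setValidity("ReadSet", function(object) {
  msg <- character()
  if (length(object@quals) != length(object@seqs))
    msg <- c(msg, "one quality vector per read is required")
  else if (length(object@seqs) &&
           any(lengths(object@quals) != Biostrings::width(object@seqs)))
    msg <- c(msg, "quality vectors must match read lengths")
  if (length(object@quals) &&
      any(unlist(lapply(object@quals, function(q) any(q < 0L | q > 41L)))))
    msg <- c(msg, "Phred scores must lie in [0, 41]")
  if (nrow(object@info) != length(object@seqs))
    msg <- c(msg, "info rows must match number of reads")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReadSet-class Construct from sequences, qualities and info.
#' @param seqs,quals,info See slots.
#' @export
ReadSet <- function(seqs, quals, info) {
  seqs <- as(seqs, "DNAStringSet")
  info <- as.data.frame(info)
  rownames(info) <- NULL
  names(seqs) <- info$readId
  new("ReadSet", seqs = seqs, quals = quals, info = DataFrame(info))
}

#' @export
setMethod("show", "ReadSet", function(object) {
  n <- length(object@seqs)
  cat(sprintf("ReadSet: %d read(s)", n))
  if (n) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf(", lengths %d-%d bp", min(w), max(w)))
  }
  cat("\n")
})

#' @export
setMethod("length", "ReadSet", function(x) length(x@seqs))

#' @describeIn ReadSet-class Read sequences (\code{DNAStringSet}).
#' @param x A \code{ReadSet}.
#' @export
readSeqs <- function(x) x@seqs
#' @describeIn ReadSet-class Per-read integer Phred qualities (list).
#' @export
readQuals <- function(x) x@quals
#' @describeIn ReadSet-class Read truth-placement table (\code{DataFrame}).
#' @export
readInfo <- function(x) x@info

#' Subset a ReadSet
#' @param x A \code{ReadSet}.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadSet", seqs = x@seqs[i], quals = x@quals[i],
      info = x@info[i, , drop = FALSE])
})

revcompChar <- function(s) {
  # byte-level reverse complement (A/C/G/T/N alphabet); much cheaper than
  # round-tripping through XString objects in per-read loops
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
}

# Quality tiers for the two-tier error-aware quality model. Downstream
# thresholds only discriminate at Phred 20 (reference masking) and at the
# allele-score threshold 10, so a coarse model suffices: confident bases
# score well above 20, bases inside long homopolymer runs score above but
# near the mask limit, and bases where an error was introduced score below
# the thresholds that would let a lone erroneous read drive a call.
QUAL_HIGH <- 35L
QUAL_HOMOPOLYMER <- 28L
QUAL_ERROR <- 8L

# Apply homopolymer length miscalls to one read: each run of length >= 2
# independently gains or loses one base with probability 'rate'.
applyHomopolymerErrors <- function(chars, rate) {
  r <- rle(chars)
  eligible <- which(r$lengths >= 2L)
  quals <- rep(QUAL_HIGH, length(chars))
  runStarts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  long <- which(r$lengths >= 4L)
  for (k in long)
    quals[runStarts[k]:(runStarts[k] + r$lengths[k] - 1L)] <- QUAL_HOMOPOLYMER
  if (!length(eligible) || rate <= 0)
    return(list(chars = chars, quals = quals, nIndels = 0L))
  hit <- eligible[runif(length(eligible)) < rate]
  if (!length(hit))
    return(list(chars = chars, quals = quals, nIndels = 0L))
  grow <- runif(length(hit)) < 0.5
  lens <- r$lengths
  lens[hit] <- lens[hit] + ifelse(grow, 1L, -1L)
  out <- rep.int(r$values, lens)
  outQuals <- rep(QUAL_HIGH, length(out))
  outStarts <- cumsum(c(1L, lens))[seq_along(lens)]
  for (k in which(lens >= 4L))
    outQuals[outStarts[k]:(outStarts[k] + lens[k] - 1L)] <- QUAL_HOMOPOLYMER
  for (k in hit)
    if (lens[k] >= 1L)
      outQuals[outStarts[k]:(outStarts[k] + lens[k] - 1L)] <- QUAL_ERROR
  list(chars = out, quals = outQuals, nIndels = length(hit))
}

#' Simulate long reads over tier-1 fragments
#'
#' Emulates a long-read (454-style) run: reads are sampled from random
#' strands of the fragments, lengths drawn from a truncated normal (default
#' mean 230 bp, matching the platform's reported average) and capped at the
#' fragment length. The platform's characteristic error — miscalling the
#' number of bases in a homopolymer — is applied per homopolymer run of
#' length >= 2 at \code{homopolymerErrorRate}; affected runs receive low
#' per-base qualities and long runs receive reduced qualities.
#'
#' @param fragments Tier-1 \code{\link{FragmentSet-class}}.
#' @param coverageDepth Target mean per-base coverage per fragment.
#' @param homopolymerErrorRate Per-run indel probability.
#' @param seed Integer seed.
#' @param meanLen,sdLen Read-length distribution (truncated normal, bp).
#' @param idPrefix Prefix for read ids.
#' @return A \code{\link{ReadSet-class}}.
#' @export
simulateLongReads <- function(fragments, coverageDepth = 20,
                              homopolymerErrorRate = 0, seed = 1L,
                              meanLen = 230, sdLen = 40,
                              idPrefix = "lr") {
  stopifnot(is(fragments, "FragmentSet"), coverageDepth > 0)
  if (length(fragments) && any(fragmentInfo(fragments)$tier != 1L))
    stop("'fragments' must be tier-1 fragments")
  info <- fragmentInfo(fragments)
  fragChars <- as.character(fragmentSeqs(fragments))
  out <- withSeed(seed, {
    seqsL <- list(); qualsL <- list(); rows <- list(); n <- 0L
    for (i in seq_len(length(fragments))) {
      fl <- nchar(fragChars[i])
      nReads <- stats::rpois(1L, coverageDepth * fl / min(meanLen, fl))
      if (nReads < 1L) next
      lens <- pmin(fl, pmax(30L, as.integer(round(stats::rnorm(nReads, meanLen, sdLen)))))
      starts <- vapply(fl - lens, function(m) sample.int(m + 1L, 1L), integer(1L)) - 1L
      strands <- sample(c("+", "-"), nReads, replace = TRUE)
      for (j in seq_len(nReads)) {
        s <- substr(fragChars[i], starts[j] + 1L, starts[j] + lens[j])
        if (strands[j] == "-") s <- revcompChar(s)
        hp <- applyHomopolymerErrors(strsplit(s, "", fixed = TRUE)[[1L]],
                                     homopolymerErrorRate)
        n <- n + 1L
        seqsL[[n]] <- paste(hp$chars, collapse = "")
        qualsL[[n]] <- hp$quals
        rows[[n]] <- data.frame(
          readId = sprintf("%s_%06d", idPrefix, n), fragId = info$fragId[i],
          strand = strands[j], offset = starts[j], stringsAsFactors = FALSE)
      }
    }
    list(seqs = unlist(seqsL), quals = qualsL, info = do.call(rbind, rows))
  })
  if (is.null(out$info))
    return(ReadSet(DNAStringSet(), list(),
                   data.frame(readId = character(), fragId = character(),
                              strand = character(), offset = integer())))
  ReadSet(DNAStringSet(out$seqs), out$quals, out$info)
}

#' Simulate short end reads over tier-2 fragments
#'
#' Emulates short-read (GA-style) end sequencing: every read starts at a
#' fragment end (reads from the right end are reverse-complemented), with
#' lengths drawn uniformly from \code{lenRange} (default 36-42 bp) and
#' i.i.d. substitution errors at \code{substitutionRate}. Under the
#' two-tier quality model, erroneous bases receive low Phred scores.
#'
#' @param fragments Tier-2 \code{\link{FragmentSet-class}}.
#' @param readsPerFragmentEnd Reads sampled from each fragment end.
#' @param substitutionRate Per-base substitution probability.
#' @param seed Integer seed.
#' @param lenRange Integer length-2 inclusive read-length range (bp).
#' @param idPrefix Prefix for read ids.
#' @return A \code{\link{ReadSet-class}}.
#' @export
simulateShortReads <- function(fragments, readsPerFragmentEnd = 20L,
                               substitutionRate = 0, seed = 1L,
                               lenRange = c(36L, 42L), idPrefix = "sr") {
  stopifnot(is(fragments, "FragmentSet"), readsPerFragmentEnd >= 1L)
  if (length(fragments) && any(fragmentInfo(fragments)$tier != 2L))
    stop("'fragments' must be tier-2 fragments")
  info <- fragmentInfo(fragments)
  fragChars <- as.character(fragmentSeqs(fragments))
  out <- withSeed(seed, {
    seqsL <- list(); qualsL <- list(); rows <- list(); n <- 0L
    for (i in seq_len(length(fragments))) {
      fl <- nchar(fragChars[i])
      for (end in c("left", "right")) {
        for (j in seq_len(readsPerFragmentEnd)) {
          len <- min(fl, sample(lenRange[1L]:lenRange[2L], 1L))
          if (end == "left") {
            s <- substr(fragChars[i], 1L, len)
            offset <- 0L; strand <- "+"
          } else {
            s <- revcompChar(substr(fragChars[i], fl - len + 1L, fl))
            offset <- fl - len; strand <- "-"
          }
          chars <- strsplit(s, "", fixed = TRUE)[[1L]]
          quals <- rep(QUAL_HIGH, len)
          # both vectors are drawn whatever the rate, so runs that differ
          # only in substitutionRate share every sampled read window
          u <- runif(len)
          pick <- ceiling(runif(len) * 3)
          err <- which(u < substitutionRate)
          for (k in err) {
            chars[k] <- setdiff(DNA_BASES, chars[k])[pick[k]]
            quals[k] <- QUAL_ERROR
          }
          n <- n + 1L
          seqsL[[n]] <- paste(chars, collapse = "")
          qualsL[[n]] <- quals
          rows[[n]] <- data.frame(
            readId = sprintf("%s_%06d", idPrefix, n), fragId = info$fragId[i],
            strand = strand, offset = offset, stringsAsFactors = FALSE)
        }
      }
    }
    list(seqs = unlist(seqsL), quals = qualsL, info = do.call(rbind, rows))
  })
  if (is.null(out$info))
    return(ReadSet(DNAStringSet(), list(),
                   data.frame(readId = character(), fragId = character(),
                              strand = character(), offset = integer())))
  ReadSet(DNAStringSet(out$seqs), out$quals, out$info)
}

#' Write / read a ReadSet as FASTQ (Phred+33) with a truth sidecar TSV
#'
#' The sidecar maps read id to its truth placement (fragment, strand,
#' 0-based offset) so that persisted reads round-trip losslessly.
#'
#' @param reads A \code{\link{ReadSet-class}}.
#' @param fastqPath FASTQ output path.
#' @param sidecarPath Sidecar TSV path (default: \code{fastqPath} +
#'   \code{".truth.tsv"}).
#' @return \code{fastqPath} (write) or a \code{ReadSet} (read).
#' @export
writeReadsFastq <- function(reads, fastqPath,
                            sidecarPath = paste0(fastqPath, ".truth.tsv")) {
  qstr <- vapply(readQuals(reads),
                 function(q) rawToChar(as.raw(q + 33L)), character(1L))
  x <- Biostrings::QualityScaledDNAStringSet(readSeqs(reads),
                                             Biostrings::PhredQuality(qstr))
  Biostrings::writeQualityScaledXStringSet(x, fastqPath)
  utils::write.table(as.data.frame(readInfo(reads)), sidecarPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastqPath)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(fastqPath,
                           sidecarPath = paste0(fastqPath, ".truth.tsv")) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastqPath))
  quals <- lapply(as.character(Biostrings::quality(x)),
                  function(s) as.integer(charToRaw(s)) - 33L)
  names(quals) <- NULL
  info <- utils::read.table(sidecarPath, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "character", "integer"))
  ReadSet(DNAStringSet(x), quals, info)
}
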