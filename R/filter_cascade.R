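# The ordered five-stage false-positive filter cascade with per-stage
# bookkeeping: paralog self-mapping, allele-swap verification, repeat and
# contaminant library screens, and the allele-consistency screen.

siteKey <- function(df) paste(df$refId, df$pos, sep = "@")

#' Paralog filter via self-mapping
#'
#' Apparent SNPs caused by paralogous or homologous genome copies co-mapping
#' to one reference surface in the genotype-A self-calls as well: aligning
#' genotype A's own short reads back to the genotype-A reference and calling
#' SNPs with the same thresholds marks those sites. Any candidate whose
#' (reference, position) also receives a self-call is eliminated.
#'
#' @param candidates Candidate data.frame (from genotype-B reads).
#' @param selfCalls Candidate data.frame called from genotype-A reads
#'   against the same references (see \code{\link{callSNPs}}).
#' @return A list: \code{kept}, \code{eliminated} (data.frames).
#' @export
paralogFilter <- function(candidates, selfCalls) {
  hit <- siteKey(candidates) %in% siteKey(selfCalls)
  list(kept = candidates[!hit, , drop = FALSE],
       eliminated = candidates[hit, , drop = FALSE])
}

#' Build allele-swapped references
#'
#' For every candidate, the reference base at the SNP position is replaced
#' with the candidate's alternate allele. All candidate sites on one
#' reference are substituted simultaneously in one modified copy (sites are
#' sparse; co-substitution interference is negligible and can be measured
#' with \code{perSite = TRUE} on small inputs, which swaps one site at a
#' time and returns one modified reference set per candidate).
#'
#' @param candidates Candidate data.frame.
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param perSite If \code{TRUE}, return a list of single-site swaps
#'   (diagnostic mode) instead of one batched set.
#' @return A \code{ReferenceSet} (batched) or a list of them (per site).
#' @export
swapAlleles <- function(candidates, refs, perSite = FALSE) {
  stopifnot(is(refs, "ReferenceSet"))
  doSwap <- function(cands) {
    chars <- as.character(refSeqs(refs))
    for (r in seq_len(nrow(cands))) {
      id <- cands$refId[r]
      substr(chars[id], cands$pos[r], cands$pos[r]) <- cands$altAllele[r]
    }
    ReferenceSet(DNAStringSet(chars), refNReads(refs), refQuals(refs),
                 refProvenance(refs))
  }
  if (perSite)
    lapply(seq_len(nrow(candidates)),
           function(r) doSwap(candidates[r, , drop = FALSE]))
  else doSwap(candidates)
}

#' Allele-swap verification
#'
#' Reciprocal evidence check: the candidate's alternate allele is
#' substituted into the reference, genotype A's short reads are aligned to
#' the modified reference, and SNPs are called with the same thresholds. A
#' real SNP shows the original reference allele as a SNP call back against
#' the swapped base; a candidate without such a reciprocal call (for
#' example, one with no genotype-A coverage at the site) is eliminated.
#'
#' @param candidates Candidate data.frame.
#' @param readsA Genotype-A short reads (\code{\link{ReadSet-class}}).
#' @param refs The original \code{\link{ReferenceSet-class}}.
#' @param minDepth,minAlleleScore,maxMismatches Calling/alignment thresholds
#'   (same semantics as primary calling).
#' @return A list: \code{kept}, \code{eliminated}, and \code{swapCalls}
#'   (the calls made against the swapped reference).
#' @export
alleleSwapVerify <- function(candidates, readsA, refs, minDepth = 3L,
                             minAlleleScore = 10, maxMismatches = 2L) {
  if (!nrow(candidates))
    return(list(kept = candidates, eliminated = candidates,
                swapCalls = candidates))
  swapped <- swapAlleles(candidates, refs)
  aln <- alignShortReads(readsA, swapped, maxMismatches = maxMismatches)
  pu <- buildPileup(aln, swapped)
  calls <- callSNPs(pu, swapped, minDepth = minDepth,
                    minAlleleScore = minAlleleScore)
  # verified iff a call at the site recovers the original reference allele
  want <- paste(candidates$refId, candidates$pos, candidates$refAllele)
  got <- paste(calls$refId, calls$pos, calls$altAllele)
  ok <- want %in% got
  list(kept = candidates[ok, , drop = FALSE],
       eliminated = candidates[!ok, , drop = FALSE],
       swapCalls = calls)
}

#' Screen candidates against an exclusion library
#'
#' A candidate is eliminated iff the whole reference sequence it resides on
#' is flagged by the shared-word rule (exact word of \code{wordSize} bases
#' on either strand) against the given library — the same rule as
#' \code{\link{screenLibrary}}. Used once with the repeat library and once
#' with the bacterial contaminant library.
#'
#' @param candidates Candidate data.frame.
#' @param refs A \code{\link{ReferenceSet-class}}.
#' @param library Exclusion library (\code{DNAStringSet} or character);
#'   an empty library eliminates nothing.
#' @param wordSize Exact shared-word length (default 30).
#' @return A list: \code{kept}, \code{eliminated}.
#' @export
libraryScreenCandidates <- function(candidates, refs, library, wordSize = 30L) {
  library <- as(library, "DNAStringSet")
  if (!length(library) || !nrow(candidates))
    return(list(kept = candidates, eliminated = candidates[0, , drop = FALSE]))
  flaggedIdx <- screenSeqsAgainstLibrary(refSeqs(refs), library, wordSize)
  flaggedIds <- names(refSeqs(refs))[flaggedIdx]
  hit <- candidates$refId %in% flaggedIds
  list(kept = candidates[!hit, , drop = FALSE],
       eliminated = candidates[hit, , drop = FALSE])
}

#' Allele-consistency screen
#'
#' Requires unanimous support for the called alternate allele among the
#' genotype-B reads covering the site: a candidate is eliminated iff at
#' least one covering genotype-B read carries a base different from the
#' called alternate allele. By default (\code{strict = TRUE}) a genotype-B
#' read showing the reference allele also counts as "different"; with
#' \code{strict = FALSE} only third alleles eliminate.
#'
#' @param candidates Candidate data.frame.
#' @param pileupB Genotype-B pileup (\code{\link{buildPileup}}) at least
#'   covering the candidate sites.
#' @param strict Whether reference-allele reads violate consistency.
#' @return A list: \code{kept}, \code{eliminated}.
#' @export
alleleConsistencyScreen <- function(candidates, pileupB, strict = TRUE) {
  if (!nrow(candidates))
    return(list(kept = candidates, eliminated = candidates))
  key <- siteKey(candidates)
  pkey <- paste(pileupB$refId, pileupB$pos, sep = "@")
  bad <- logical(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    rows <- pileupB[pkey == key[r], , drop = FALSE]
    other <- rows$base != candidates$altAllele[r]
    if (!strict) other <- other & rows$base != candidates$refAllele[r]
    bad[r] <- any(other & rows$count > 0L)
  }
  list(kept = candidates[!bad, , drop = FALSE],
       eliminated = candidates[bad, , drop = FALSE])
}

#' Run the ordered false-positive filter cascade
#'
#' Executes the five stages in their fixed order — paralog filter,
#' allele-swap verification, repeat screen, contaminant screen,
#' allele-consistency screen — with full per-stage bookkeeping. The
#' contaminant screen runs at the end of the cascade, when the candidate
#' set is smallest. Individual stages can be disabled for ablation but the
#' order is fixed. Each filter is a pure subset operation: it never adds
#' candidates and never mutates alleles.
#'
#' @param candidates Primary candidate data.frame (genotype-B reads vs the
#'   genotype-A reference).
#' @param refs The genotype-A \code{\link{ReferenceSet-class}}.
#' @param readsA Genotype-A short reads (needed by the paralog and
#'   allele-swap stages).
#' @param pileupB Genotype-B pileup (needed by the consistency screen);
#'   pass the pileup used for calling.
#' @param repeatLibrary,contaminantLibrary Exclusion libraries
#'   (\code{DNAStringSet}; empty skips nothing out).
#' @param params A \code{\link{PipelineParams}}.
#' @param stages Character vector of enabled stages (subset of the five, in
#'   any order; execution order is fixed).
#' @param strictConsistency Passed to \code{\link{alleleConsistencyScreen}}.
#' @param selfCalls Optional precomputed genotype-A self-calls; computed
#'   from \code{readsA} when \code{NULL}.
#' @return A list: \code{candidates} (survivors, with a
#'   \code{stageExited} column recording where each input candidate left,
#'   \code{"pass"} for survivors), \code{report} (a
#'   \code{\link{FilterReport-class}}), and \code{stageSets} (list of the
#'   surviving set after each stage).
#' @export
runCascade <- function(candidates, refs, readsA = NULL, pileupB = NULL,
                       repeatLibrary = Biostrings::DNAStringSet(),
                       contaminantLibrary = Biostrings::DNAStringSet(),
                       params = PipelineParams(),
                       stages = c("paralog_filter", "allele_swap_verify",
                                  "repeat_screen", "contaminant_screen",
                                  "allele_consistency_screen"),
                       strictConsistency = TRUE, selfCalls = NULL) {
  allStages <- c("paralog_filter", "allele_swap_verify", "repeat_screen",
                 "contaminant_screen", "allele_consistency_screen")
  stopifnot(all(stages %in% allStages))
  needsA <- any(c("paralog_filter", "allele_swap_verify") %in% stages)
  if (needsA && is.null(readsA) && is.null(selfCalls))
    stop("stage 'paralog_filter'/'allele_swap_verify' requires genotype-A reads")
  if ("allele_consistency_screen" %in% stages && is.null(pileupB))
    stop("stage 'allele_consistency_screen' requires the genotype-B pileup")

  cur <- candidates
  exited <- rep("pass", nrow(candidates))
  names(exited) <- siteKey(candidates)
  rep_stage <- character(); rep_in <- integer(); rep_elim <- integer()
  stageSets <- list()
  selfCallsUsed <- selfCalls
  alnA <- NULL

  recordStage <- function(name, res) {
    rep_stage <<- c(rep_stage, name)
    rep_in <<- c(rep_in, nrow(cur))
    rep_elim <<- c(rep_elim, nrow(res$eliminated))
    if (nrow(res$eliminated))
      exited[siteKey(res$eliminated)] <<- name
    cur <<- res$kept
    stageSets[[name]] <<- res$kept
  }

  for (st in allStages[allStages %in% stages]) {
    res <- switch(st,
      paralog_filter = {
        if (is.null(selfCallsUsed)) {
          alnA <- alignShortReads(readsA, refs,
                                  maxMismatches = params@maxMismatches)
          puA <- buildPileup(alnA, refs)
          selfCallsUsed <- callSNPs(puA, refs, minDepth = params@minDepth,
                                    minAlleleScore = params@minAlleleScore)
        }
        paralogFilter(cur, selfCallsUsed)
      },
      allele_swap_verify = {
        out <- alleleSwapVerify(cur, readsA, refs,
                                minDepth = params@minDepth,
                                minAlleleScore = params@minAlleleScore,
                                maxMismatches = params@maxMismatches)
        out[c("kept", "eliminated")]
      },
      repeat_screen = libraryScreenCandidates(cur, refs, repeatLibrary,
                                              params@screenWordSize),
      contaminant_screen = libraryScreenCandidates(cur, refs,
                                                   contaminantLibrary,
                                                   params@screenWordSize),
      allele_consistency_screen = alleleConsistencyScreen(cur, pileupB,
                                                          strictConsistency))
    recordStage(st, res)
  }

  report <- FilterReport(rep_stage, rep_in, rep_elim)
  if (nrow(candidates))
    candidates$stageExited <- exited[siteKey(candidates)]
  if (nrow(cur))
    cur$stageExited <- "pass"
  list(candidates = cur, report = report, stageSets = stageSets,
       inputFlags = candidates, selfCalls = selfCallsUsed)
}

#' Write a FilterReport as JSON and as a readable table
#' @param report A \code{\link{FilterReport-class}}.
#' @param jsonPath JSON output path (\code{NULL} to skip).
#' @param tablePath Plain-text table path (\code{NULL} to skip).
#' @return The stage data.frame, invisibly.
#' @export
writeFilterReport <- function(report, jsonPath = NULL, tablePath = NULL) {
  st <- reportStages(report)
  if (!is.null(jsonPath))
    jsonlite::write_json(st, jsonPath, dataframe = "rows", digits = NA)
  if (!is.null(tablePath)) {
    con <- file(tablePath, "w")
    utils::write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(st)
}
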