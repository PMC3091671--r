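#' Pipeline thresholds and windows
#'
#' The single container for every numeric threshold the pipeline applies:
#' tier size-selection windows (inclusive on both ends), reference filtering
#' limits, quality masking, SNP-calling constraints, alignment mismatch
#' budget, screening word size, e-PCR placement limits, short-read length
#' range and the flanking-sequence requirement for assay design.
#'
#' Defaults follow the published mtRRL protocol: tier-1 selection 300-350 bp,
#' tier-2 110-140 bp, references dropped below 61 bases or above 75% N,
#' bases below Phred 20 masked to N, SNP calls require read depth >= 3 and
#' allele call score >= 10, alignment allows at most 2 mismatches, library
#' screens use an exact shared word of 30, e-PCR placement allows 3
#' mismatches and 1 gap, short reads span 36-42 bp, and assay design needs
#' 60 bp of clean flank on each side.
#'
#' @param tier1SizeWindow,tier2SizeWindow Integer length-2 inclusive windows (bp).
#' @param minRefLen Minimum reference length kept (bp).
#' @param maxNFraction Maximum tolerated N fraction in a reference.
#' @param qualityMaskThreshold Bases with Phred below this become N.
#' @param minDepth Minimum covering reads for a SNP call.
#' @param minAlleleScore Minimum allele call score for a SNP call.
#' @param maxMismatches Ungapped alignment mismatch budget per read.
#' @param screenWordSize Exact shared-word length for library screens.
#' @param epcrMismatches,epcrGaps Per-primer placement budgets for the e-PCR screen.
#' @param shortReadLenRange Integer length-2 range of short-read lengths (bp).
#' @param flankRequirement Clean flank needed on each side for assay design (bp).
#' @return A \code{PipelineParams} object.
#' @examples
#' PipelineParams()
#' @export
PipelineParams <- function(tier1SizeWindow = c(300L, 350L),
                           tier2SizeWindow = c(110L, 140L),
                           minRefLen = 61L,
                           maxNFraction = 0.75,
                           qualityMaskThreshold = 20L,
                           minDepth = 3L,
                           minAlleleScore = 10,
                           maxMismatches = 2L,
                           screenWordSize = 30L,
                           epcrMismatches = 3L,
                           epcrGaps = 1L,
                           shortReadLenRange = c(36L, 42L),
                           flankRequirement = 60L) {
  new("PipelineParams",
      tier1SizeWindow = as.integer(tier1SizeWindow),
      tier2SizeWindow = as.integer(tier2SizeWindow),
      minRefLen = as.integer(minRefLen),
      maxNFraction = as.numeric(maxNFraction),
      qualityMaskThreshold = as.integer(qualityMaskThreshold),
      minDepth = as.integer(minDepth),
      minAlleleScore = as.numeric(minAlleleScore),
      maxMismatches = as.integer(maxMismatches),
      screenWordSize = as.integer(screenWordSize),
      epcrMismatches = as.integer(epcrMismatches),
      epcrGaps = as.integer(epcrGaps),
      shortReadLenRange = as.integer(shortReadLenRange),
      flankRequirement = as.integer(flankRequirement))
}

#' @rdname PipelineParams
#' @export
setClass("PipelineParams",
  representation(tier1SizeWindow = "integer", tier2SizeWindow = "integer",
                 minRefLen = "integer", maxNFraction = "numeric",
                 qualityMaskThreshold = "integer", minDepth = "integer",
                 minAlleleScore = "numeric", maxMismatches = "integer",
                 screenWordSize = "integer", epcrMismatches = "integer",
                 epcrGaps = "integer", shortReadLenRange = "integer",
                 flankRequirement = "integer"))

setValidity("PipelineParams", function(object) {
  msg <- character()
  win_ok <- function(w) length(w) == 2L && !anyNA(w) && w[1L] <= w[2L] && w[1L] > 0L
  if (!win_ok(object@tier1SizeWindow)) msg <- c(msg, "tier1SizeWindow must be a non-empty positive window")
  if (!win_ok(object@tier2SizeWindow)) msg <- c(msg, "tier2SizeWindow must be a non-empty positive window")
  if (!win_ok(object@shortReadLenRange)) msg <- c(msg, "shortReadLenRange must be a non-empty positive window")
  pos <- c(minRefLen = object@minRefLen,
           qualityMaskThreshold = object@qualityMaskThreshold,
           minDepth = object@minDepth, minAlleleScore = object@minAlleleScore,
           maxMismatches = object@maxMismatches,
           screenWordSize = object@screenWordSize,
           flankRequirement = object@flankRequirement)
  if (anyNA(pos) || any(pos <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (is.na(object@maxNFraction) || object@maxNFraction < 0 || object@maxNFraction > 1)
    msg <- c(msg, "maxNFraction must lie in [0, 1]")
  if (object@epcrMismatches < 0L || object@epcrGaps < 0L)
    msg <- c(msg, "e-PCR budgets must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PipelineParams", function(object) {
  cat("PipelineParams:\n")
  cat(sprintf("  tier-1 window [%d, %d] bp; tier-2 window [%d, %d] bp\n",
              object@tier1SizeWindow[1L], object@tier1SizeWindow[2L],
              object@tier2SizeWindow[1L], object@tier2SizeWindow[2L]))
  cat(sprintf("  reference: min length %d, max N fraction %.2f, mask Phred < %d\n",
              object@minRefLen, object@maxNFraction, object@qualityMaskThreshold))
  cat(sprintf("  calling: depth >= %d, allele score >= %g, <= %d mismatches\n",
              object@minDepth, object@minAlleleScore, object@maxMismatches))
  cat(sprintf("  screens: word size %d; e-PCR N = %d, G = %d; flank %d bp\n",
              object@screenWordSize, object@epcrMismatches, object@epcrGaps,
              object@flankRequirement))
})
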