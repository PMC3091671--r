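# Truth-based evaluation of the pipeline: validation rate, recall over
# discoverable sites, and the validation/conversion-rate bookkeeping.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Map candidate sites to genome coordinates via reference provenance
#'
#' For synthetic data every reference column carries its genome position and
#' orientation; this resolves each candidate to (genome position, strand)
#' and orients its alleles to genome-forward.
#'
#' @param candidates Candidate data.frame.
#' @param refs A \code{\link{ReferenceSet-class}} with provenance.
#' @return The candidates with added columns \code{genomePos} (1-based,
#'   genotype-A coordinates; NA when unmappable), \code{genomeStrand},
#'   \code{refAlleleFwd}, \code{altAlleleFwd}.
#' @export
mapCandidatesToGenome <- function(candidates, refs) {
  stopifnot(is(refs, "ReferenceSet"))
  prov <- refProvenance(refs)
  if (!length(prov))
    stop("reference set carries no provenance")
  n <- nrow(candidates)
  gp <- rep(NA_integer_, n); gs <- rep(NA_character_, n)
  ra <- candidates$refAllele; aa <- candidates$altAllele
  idx <- match(candidates$refId, names(refSeqs(refs)))
  for (r in seq_len(n)) {
    p <- prov[[idx[r]]]
    if (is.null(p)) next
    gp[r] <- p$genomePos[candidates$pos[r]]
    gs[r] <- p$strand
    if (p$strand == "-") {
      ra[r] <- COMPLEMENT[[ra[r]]]
      aa[r] <- COMPLEMENT[[aa[r]]]
    }
  }
  candidates$genomePos <- gp
  candidates$genomeStrand <- gs
  candidates$refAlleleFwd <- ra
  candidates$altAlleleFwd <- aa
  candidates
}

#' Evaluate candidates against the planted truth
#'
#' A candidate is counted true iff it maps (via reference provenance) to a
#' planted \code{true_snp} position with both alleles matching truth
#' (orientation resolved through the provenance strand). Candidates on
#' references without provenance are excluded from the rates and counted
#' separately. Position-only matches (site right, alleles wrong) are
#' reported as a diagnostic. Candidates falling inside paralog-copy or
#' repeat annotation intervals without matching a true SNP are classified
#' \code{paralog_induced} / \code{repeat_region}.
#'
#' @param candidates Candidate data.frame.
#' @param truth Truth table (see \code{\link{deriveGenotype}}; 0-based
#'   positions).
#' @param refs A \code{\link{ReferenceSet-class}} with provenance.
#' @param discoverable Optional integer vector of 1-based genome positions
#'   considered discoverable; enables \code{recall}.
#' @param annotations Optional \code{GRanges} of planted-feature intervals
#'   for false-call classification.
#' @return A list of metrics: \code{nReported}, \code{nTrue},
#'   \code{validationRate} (NA when nothing reported), \code{recall} (when
#'   \code{discoverable} given), \code{nPositionOnly}, \code{nUnmappable},
#'   \code{nFalse}, \code{falseClasses} (table), and \code{mapped} (the
#'   annotated candidate data.frame).
#' @export
evaluateCandidates <- function(candidates, truth, refs, discoverable = NULL,
                               annotations = NULL) {
  mapped <- mapCandidatesToGenome(candidates, refs)
  unmappable <- is.na(mapped$genomePos)
  ev <- mapped[!unmappable, , drop = FALSE]
  truthPos1 <- truth$pos + 1L
  ti <- match(ev$genomePos, truthPos1)
  posMatch <- !is.na(ti)
  alleleMatch <- posMatch
  alleleMatch[posMatch] <- ev$refAlleleFwd[posMatch] == truth$alleleA[ti[posMatch]] &
    ev$altAlleleFwd[posMatch] == truth$alleleB[ti[posMatch]]
  isTrue <- alleleMatch
  cls <- rep("false_other", nrow(ev))
  cls[isTrue] <- "true_snp"
  cls[posMatch & !isTrue] <- "position_only"
  if (!is.null(annotations) && length(annotations) && nrow(ev)) {
    falseIdx <- which(!isTrue)
    if (length(falseIdx)) {
      q <- GRanges(as.character(seqnames(annotations))[1L],
                   IRanges(ev$genomePos[falseIdx], width = 1L))
      classMap <- c(repeat_region = "repeat", paralog_induced = "paralog-copy")
      for (lab in names(classMap)) {
        ov <- IRanges::overlapsAny(q, annotations[annotations$class == classMap[[lab]]])
        cls[falseIdx[ov & cls[falseIdx] == "false_other"]] <- lab
      }
    }
  }
  ev$truthClass <- cls
  mapped$truthClass <- rep(NA_character_, nrow(mapped))
  mapped$truthClass[!unmappable] <- cls
  nReported <- nrow(ev)
  nTrue <- sum(isTrue)
  recall <- NA_real_
  if (!is.null(discoverable))
    recall <- if (length(discoverable))
      length(intersect(ev$genomePos[isTrue], discoverable)) / length(discoverable)
    else NA_real_
  list(nReported = nReported, nTrue = nTrue,
       validationRate = if (nReported > 0L) nTrue / nReported else NA_real_,
       recall = recall,
       nPositionOnly = sum(posMatch & !isTrue),
       nUnmappable = sum(unmappable),
       nFalse = nReported - nTrue,
       falseClasses = table(cls[!isTrue]),
       mapped = mapped)
}

#' Discoverable planted SNP positions
#'
#' A planted SNP is operationally discoverable when the evidence the caller
#' and the reciprocal verification require exists: at least \code{minDepth}
#' uniquely placed genotype-B reads and at least \code{minDepth} uniquely
#' placed genotype-A reads cover the site on a retained, provenance-mapped
#' reference.
#'
#' @param truth Truth table (0-based positions).
#' @param refs Retained \code{\link{ReferenceSet-class}} with provenance.
#' @param pileupB,pileupA Pileups of genotype-B and genotype-A reads against
#'   \code{refs}.
#' @param minDepth Depth requirement (default 3).
#' @param annotations Optional \code{GRanges} of planted features; sites
#'   inside paralog-copy or repeat intervals are excluded as inherently
#'   ambiguous (reads from the duplicated loci are not separable by
#'   position).
#' @return Integer vector of 1-based genome positions.
#' @export
discoverableSites <- function(truth, refs, pileupB, pileupA, minDepth = 3L,
                              annotations = NULL) {
  prov <- refProvenance(refs)
  if (!length(prov)) stop("reference set carries no provenance")
  cover <- function(pu) {
    if (!nrow(pu)) return(integer())
    dt <- data.table(pu)
    agg <- dt[, list(depth = sum(count)), by = c("refId", "pos")]
    agg <- agg[agg$depth >= minDepth]
    idx <- match(agg$refId, names(refSeqs(refs)))
    out <- integer(nrow(agg))
    for (r in seq_len(nrow(agg))) {
      p <- prov[[idx[r]]]
      out[r] <- if (is.null(p)) NA_integer_ else p$genomePos[agg$pos[r]]
    }
    out[!is.na(out)]
  }
  covered <- intersect(cover(pileupB), cover(pileupA))
  out <- intersect(truth$pos + 1L, covered)
  if (!is.null(annotations) && length(annotations) && length(out)) {
    amb <- annotations[annotations$class %in% c("paralog-copy", "repeat")]
    if (length(amb)) {
      q <- GRanges(as.character(seqnames(annotations))[1L],
                   IRanges(out, width = 1L))
      out <- out[!IRanges::overlapsAny(q, amb)]
    }
  }
  out
}

#' Round half-up to a number of decimal places
#'
#' Printed percentages follow half-up rounding at the printed precision
#' (one decimal for validation rates, whole percents for conversion rates),
#' unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Validation-rate bookkeeping
#'
#' The fraction of reported candidates confirmed true, as a percentage at
#' one printed decimal (half-up).
#'
#' @param nTrue,nReported Confirmed and reported counts.
#' @return Percentage (one decimal).
#' @examples
#' validationRatePercent(93, 108)  # 86.1
#' @export
validationRatePercent <- function(nTrue, nReported) {
  if (nReported <= 0) stop("undefined: no candidates reported")
  roundHalfUp(100 * nTrue / nReported, 1L)
}

#' Conversion-rate decomposition
#'
#' The fraction of assays that work is approximately the product of the
#' validation rate (predicted SNPs that are real) and the conversion rate
#' (real SNPs that yield a working assay); given the working rate and the
#' validation rate this recovers the conversion rate.
#'
#' @param workingRate Working-assay fraction, in (0, 1].
#' @param validationRate Validation fraction, in (0, 1].
#' @return \code{workingRate / validationRate}.
#' @examples
#' rateDecomposition(0.79, 0.86)  # ~0.9186; 92 at whole-percent rounding
#' @export
rateDecomposition <- function(workingRate, validationRate) {
  stopifnot(workingRate > 0, workingRate <= 1)
  if (is.na(validationRate) || validationRate <= 0)
    stop("undefined: validation rate must be positive")
  stopifnot(validationRate <= 1)
  workingRate / validationRate
}

#' Write evaluation metrics as JSON and TSV
#' @param metrics List from \code{\link{evaluateCandidates}}.
#' @param jsonPath,tsvPath Output paths (\code{NULL} to skip).
#' @return The scalar metrics as a list, invisibly.
#' @export
writeEvalMetrics <- function(metrics, jsonPath = NULL, tsvPath = NULL) {
  scalars <- metrics[c("nReported", "nTrue", "validationRate", "recall",
                       "nPositionOnly", "nUnmappable", "nFalse")]
  if (!is.null(jsonPath))
    jsonlite::write_json(scalars, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvPath)) {
    df <- data.frame(metric = names(scalars),
                     value = unlist(lapply(scalars, function(v)
                       if (is.null(v) || length(v) == 0L) NA else v)))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(scalars)
}
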