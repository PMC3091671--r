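# End-to-end orchestration: validated configuration, per-stage derived
# seeds, the run-all driver, and artifact persistence.

#' Default pipeline configuration
#'
#' A validated named list holding every knob of the pipeline, grouped as:
#' synthetic-world parameters (genome length and GC, SNP rate, planted
#' complications), sequencing simulation (long-read coverage and error
#' model, short-read depth and substitution rate), reference construction
#' (clustering identity/overlap), the \code{\link{PipelineParams}}
#' thresholds, cascade stage toggles, assay-design options, and the master
#' seed from which each stage derives its own seed.
#'
#' Defaults define the package's reference synthetic study: a 1 Mb
#' genotype-A genome at GC 0.4 carrying 2 planted paralog duplications of
#' 5 kb at 2\% divergence, 3 copies of a 400 bp repeat unit, a 5 kb
#' organellar insertion and a 2 kb bacterial contaminant insertion; a
#' genotype B derived at SNP rate 0.005; long-read sampling at a depth
#' calibrated so that roughly one long read lands per captured fragment
#' (reproducing the published contig/singleton balance and the resulting
#' incomplete reference capture), and 20 short reads per tier-2 fragment
#' end for each genotype, error-free unless error rates are raised.
#'
#' @param ... Name-value overrides of any config entry (unknown names are
#'   rejected).
#' @return A config list (class \code{rrlConfig}).
#' @examples
#' cfg <- defaultConfig(genomeLength = 2e5, seed = 42)
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    genomeLength = 1000000L,
    gcFraction = 0.4,
    snpRate = 0.005,
    nParalogs = 2L,
    paralogLength = 5000L,
    paralogDivergence = 0.02,
    nRepeats = 3L,
    repeatUnitLength = 400L,
    organellarLength = 5000L,
    contaminantLength = 2000L,
    longCoverage = 0.7,
    homopolymerErrorRate = 0,
    longMeanLen = 230,
    longSdLen = 40,
    shortReadsPerEnd = 20L,
    substitutionRate = 0,
    clusterMinIdentity = 0.98,
    clusterMinOverlap = 40L,
    tier1SizeWindow = c(300L, 350L),
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
    flankRequirement = 60L,
    stages = c("paralog_filter", "allele_swap_verify", "repeat_screen",
               "contaminant_screen", "allele_consistency_screen"),
    strictConsistency = TRUE,
    runEpcr = TRUE,
    epcrSampleSize = 192L,
    writeSam = TRUE,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    cfg[names(over)] <- over
  }
  class(cfg) <- "rrlConfig"
  validateConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and out-of-range values before any stage runs.
#'
#' @param cfg A config list.
#' @return \code{cfg}, invisibly, or an error.
#' @export
validateConfig <- function(cfg) {
  proto <- local({x <- list(
    genomeLength = 0, gcFraction = 0, snpRate = 0, nParalogs = 0,
    paralogLength = 0, paralogDivergence = 0, nRepeats = 0,
    repeatUnitLength = 0, organellarLength = 0, contaminantLength = 0,
    longCoverage = 0, homopolymerErrorRate = 0, longMeanLen = 0,
    longSdLen = 0, shortReadsPerEnd = 0, substitutionRate = 0,
    clusterMinIdentity = 0, clusterMinOverlap = 0, tier1SizeWindow = 0,
    tier2SizeWindow = 0, minRefLen = 0, maxNFraction = 0,
    qualityMaskThreshold = 0, minDepth = 0, minAlleleScore = 0,
    maxMismatches = 0, screenWordSize = 0, epcrMismatches = 0,
    epcrGaps = 0, shortReadLenRange = 0, flankRequirement = 0,
    stages = 0, strictConsistency = 0, runEpcr = 0, epcrSampleSize = 0,
    writeSam = 0, seed = 0); names(x)})
  bad <- setdiff(names(cfg), proto)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  missing <- setdiff(proto, names(cfg))
  if (length(missing))
    stop(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")))
  if (cfg$genomeLength < 1) stop("genomeLength must be positive")
  if (cfg$snpRate < 0 || cfg$snpRate >= 1) stop("snpRate must lie in [0, 1)")
  if (cfg$paralogDivergence < 0 || cfg$paralogDivergence > 0.2)
    stop("paralogDivergence must lie in [0, 0.2]")
  pipelineParamsFromConfig(cfg)  # runs PipelineParams validity
  invisible(cfg)
}

#' Extract the PipelineParams from a config
#' @param cfg A config list.
#' @return A \code{\link{PipelineParams}}.
#' @export
pipelineParamsFromConfig <- function(cfg) {
  PipelineParams(
    tier1SizeWindow = cfg$tier1SizeWindow,
    tier2SizeWindow = cfg$tier2SizeWindow,
    minRefLen = cfg$minRefLen, maxNFraction = cfg$maxNFraction,
    qualityMaskThreshold = cfg$qualityMaskThreshold,
    minDepth = cfg$minDepth, minAlleleScore = cfg$minAlleleScore,
    maxMismatches = cfg$maxMismatches, screenWordSize = cfg$screenWordSize,
    epcrMismatches = cfg$epcrMismatches, epcrGaps = cfg$epcrGaps,
    shortReadLenRange = cfg$shortReadLenRange,
    flankRequirement = cfg$flankRequirement)
}

#' Write / read a configuration as YAML
#' @param cfg A config list.
#' @param path YAML path.
#' @return \code{path} (write) or a validated config (read).
#' @export
writeConfigYaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stages <- as.character(cfg$stages)
  class(cfg) <- "rrlConfig"
  validateConfig(cfg)
  cfg
}

logStage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[rrlSNP] ", fmt), ...))
}

#' Run the full pipeline on a synthetic two-genotype world
#'
#' Executes every stage in order: simulate the genomes (with planted truth),
#' digest both genotypes and size-select the two tiers, simulate long and
#' short reads, build and filter the genotype-A reference set, align
#' genotype-B short reads and call SNPs, run the five-stage filter cascade,
#' extract flanks and score assay designability (optionally screening a
#' random sample of primer pairs e-PCR style), and evaluate against the
#' planted truth. Rerunning with the same config is byte-identical.
#'
#' @param cfg Configuration from \code{\link{defaultConfig}}.
#' @param outdir Output directory for persisted artifacts (\code{NULL} to
#'   keep everything in memory only).
#' @param verbose Log per-stage progress and counts.
#' @return A list with every intermediate and result: genomes and truth,
#'   fragment sets, read sets, reference sets and filter counts, alignments
#'   and pileups, raw and final candidates, the cascade
#'   \code{\link{FilterReport-class}}, assay records, e-PCR summary, and
#'   evaluation metrics (\code{evalRaw}, \code{evalFinal}, recall over
#'   discoverable sites, paralog-elimination diagnostics).
#' @export
runPipeline <- function(cfg = defaultConfig(), outdir = NULL, verbose = TRUE) {
  validateConfig(cfg)
  params <- pipelineParamsFromConfig(cfg)
  t0 <- proc.time()[["elapsed"]]
  seeds <- vapply(c("genome", "complications", "derive", "organellar",
                    "contaminant", "longreads", "shortA", "shortB", "epcr"),
                  function(s) stageSeed(cfg$seed, s), integer(1L))

  logStage(verbose, "simulate: genome %d bp, snpRate %g, seed %d",
           cfg$genomeLength, cfg$snpRate, cfg$seed)
  g0 <- generateGenome(cfg$genomeLength, cfg$gcFraction, seeds[["genome"]],
                       id = "genomeA")
  orgSeq <- if (cfg$organellarLength > 0L)
    paste(withSeed(seeds[["organellar"]],
                   randomBases(cfg$organellarLength, 0.38)), collapse = "") else ""
  conSeq <- if (cfg$contaminantLength > 0L)
    paste(withSeed(seeds[["contaminant"]],
                   randomBases(cfg$contaminantLength, 0.55)), collapse = "") else ""
  planted <- plantComplications(
    g0, nParalogs = cfg$nParalogs, paralogLength = cfg$paralogLength,
    paralogDivergence = cfg$paralogDivergence, nRepeats = cfg$nRepeats,
    organellarSeq = orgSeq, contaminantSeq = conSeq,
    seed = seeds[["complications"]])
  genomeA <- planted$genome
  libs <- planted$libraries
  der <- deriveGenotype(genomeA, cfg$snpRate, seeds[["derive"]], id = "genomeB")
  genomeB <- der$genome
  truth <- der$truth
  logStage(verbose, "simulate: %d true SNPs planted, %d annotations",
           nrow(truth), length(genomeAnnotations(genomeA)))

  enz1 <- tier1Enzymes(); enz2 <- tier2Enzymes()
  tier1A <- sizeSelect(digestSeq(genomeA, enz1), params@tier1SizeWindow)
  tier1B <- sizeSelect(digestSeq(genomeB, enz1), params@tier1SizeWindow)
  tier2A <- secondTierDigest(tier1A, enz2, params@tier2SizeWindow)
  tier2B <- secondTierDigest(tier1B, enz2, params@tier2SizeWindow)
  logStage(verbose, "digest: tier1 A/B %d/%d, tier2 A/B %d/%d fragments",
           length(tier1A), length(tier1B), length(tier2A), length(tier2B))

  longReads <- simulateLongReads(tier1A, cfg$longCoverage,
                                 cfg$homopolymerErrorRate,
                                 seeds[["longreads"]], cfg$longMeanLen,
                                 cfg$longSdLen)
  readsA <- simulateShortReads(tier2A, cfg$shortReadsPerEnd,
                               cfg$substitutionRate, seeds[["shortA"]],
                               cfg$shortReadLenRange, idPrefix = "srA")
  readsB <- simulateShortReads(tier2B, cfg$shortReadsPerEnd,
                               cfg$substitutionRate, seeds[["shortB"]],
                               cfg$shortReadLenRange, idPrefix = "srB")
  logStage(verbose, "reads: %d long, %d short A, %d short B",
           length(longReads), length(readsA), length(readsB))

  refsRaw <- clusterLongReads(longReads, cfg$clusterMinIdentity,
                              cfg$clusterMinOverlap, fragments = tier1A)
  refsMasked <- maskLowQuality(refsRaw, params@qualityMaskThreshold)
  filt <- filterReferences(refsMasked, params@minRefLen, params@maxNFraction)
  scr <- if (length(libs$organellar))
    screenLibrary(filt$kept, libs$organellar, params@screenWordSize)
  else list(kept = filt$kept, flagged = filt$kept[integer()],
            counts = c(nIn = length(filt$kept), nFlagged = 0L,
                       nKept = length(filt$kept)))
  refs <- scr$kept
  logStage(verbose,
           "build-ref: %d raw (%d contigs), %d after len/N filter, %d after organellar screen",
           length(refsRaw), sum(refNReads(refsRaw) >= 2L),
           length(filt$kept), length(refs))

  alnB <- alignShortReads(readsB, refs, params@maxMismatches)
  pileupB <- buildPileup(alnB, refs)
  rawCandidates <- callSNPs(pileupB, refs, params@minDepth,
                            params@minAlleleScore)
  logStage(verbose, "align/call: %d B reads aligned (%d ambiguous), %d raw candidates",
           nrow(alnB), attr(alnB, "nAmbiguous"), nrow(rawCandidates))

  alnA <- alignShortReads(readsA, refs, params@maxMismatches)
  pileupA <- buildPileup(alnA, refs)
  selfCalls <- callSNPs(pileupA, refs, params@minDepth, params@minAlleleScore)
  cascade <- runCascade(rawCandidates, refs, readsA = readsA,
                        pileupB = pileupB,
                        repeatLibrary = libs$repeats,
                        contaminantLibrary = libs$contaminant,
                        params = params, stages = cfg$stages,
                        strictConsistency = cfg$strictConsistency,
                        selfCalls = selfCalls)
  finalCandidates <- cascade$candidates
  if (verbose) for (r in seq_len(nrow(reportStages(cascade$report))))
    logStage(TRUE, "cascade %-26s in %5d eliminated %5d out %5d",
             reportStages(cascade$report)$stage[r],
             reportStages(cascade$report)$nIn[r],
             reportStages(cascade$report)$nEliminated[r],
             reportStages(cascade$report)$nOut[r])

  assay <- extractFlanks(finalCandidates, refs, params@flankRequirement)
  assay <- designabilityScore(assay, params@flankRequirement)
  epcr <- NULL
  if (isTRUE(cfg$runEpcr)) {
    eligible <- which(assay$designPass &
                        assay$flankLeftLen >= 20L & assay$flankRightLen >= 20L)
    pick <- withSeed(seeds[["epcr"]], {
      if (length(eligible) > cfg$epcrSampleSize)
        sort(sample(eligible, cfg$epcrSampleSize)) else eligible
    })
    pass <- logical(length(pick)); nhits <- integer(length(pick))
    for (j in seq_along(pick)) {
      pp <- designPrimerPair(assay[pick[j], , drop = FALSE])
      res <- epcrScreen(pp, refs, params@epcrMismatches, params@epcrGaps)
      pass[j] <- res$pass; nhits[j] <- nrow(res$hits)
    }
    epcr <- data.frame(index = pick, refId = assay$refId[pick],
                       pos = assay$pos[pick], pass = pass, nHits = nhits)
    logStage(verbose, "design: %d/%d sampled primer pairs pass the e-PCR screen",
             sum(pass), length(pick))
  }

  ann <- genomeAnnotations(genomeA)
  discoverable <- discoverableSites(truth, refs, pileupB, pileupA,
                                    params@minDepth, annotations = ann)
  evalRaw <- evaluateCandidates(rawCandidates, truth, refs,
                                discoverable = discoverable,
                                annotations = ann)
  evalFinal <- evaluateCandidates(finalCandidates, truth, refs,
                                  discoverable = discoverable,
                                  annotations = ann)
  # diagnostic: how well do the two reciprocal stages remove paralog-induced
  # false calls that have genotype-A evidence at the site ("dually captured")
  paralogStats <- local({
    flags <- cascade$inputFlags
    if (!nrow(flags)) return(list(nParalogInduced = 0L, nEliminatedByPair = 0L,
                                  fractionEliminated = NA_real_))
    rawMapped <- evalRaw$mapped
    key <- paste(rawMapped$refId, rawMapped$pos)
    pin <- which(!is.na(rawMapped$truthClass) &
                   rawMapped$truthClass == "paralog_induced")
    if (!length(pin)) return(list(nParalogInduced = 0L, nEliminatedByPair = 0L,
                                  fractionEliminated = NA_real_))
    dtA <- data.table(pileupA)
    depthA <- dtA[, list(depth = sum(count)), by = c("refId", "pos")]
    dual <- paste(rawMapped$refId[pin], rawMapped$pos[pin]) %in%
      paste(depthA$refId[depthA$depth >= params@minDepth],
            depthA$pos[depthA$depth >= params@minDepth])
    pin <- pin[dual]
    if (!length(pin)) return(list(nParalogInduced = 0L, nEliminatedByPair = 0L,
                                  fractionEliminated = NA_real_))
    st <- flags$stageExited[match(key[pin], paste(flags$refId, flags$pos))]
    elim <- st %in% c("paralog_filter", "allele_swap_verify")
    list(nParalogInduced = length(pin), nEliminatedByPair = sum(elim),
         fractionEliminated = sum(elim) / length(pin))
  })
  logStage(verbose,
           "evaluate: raw VR %.3f, final VR %.3f, recall %.3f over %d discoverable sites (%.1fs)",
           ifelse(is.na(evalRaw$validationRate), NaN, evalRaw$validationRate),
           ifelse(is.na(evalFinal$validationRate), NaN, evalFinal$validationRate),
           ifelse(is.na(evalFinal$recall), NaN, evalFinal$recall),
           length(discoverable), proc.time()[["elapsed"]] - t0)

  result <- list(config = cfg, params = params,
                 genomeA = genomeA, genomeB = genomeB, truth = truth,
                 libraries = libs,
                 tier1A = tier1A, tier1B = tier1B,
                 tier2A = tier2A, tier2B = tier2B,
                 longReads = longReads, readsA = readsA, readsB = readsB,
                 refsRaw = refsRaw, refFilterCounts = filt$counts,
                 refScreenCounts = scr$counts, refs = refs,
                 alignmentsB = alnB, pileupB = pileupB,
                 alignmentsA = alnA, pileupA = pileupA,
                 selfCalls = selfCalls,
                 rawCandidates = rawCandidates, cascade = cascade,
                 report = cascade$report, finalCandidates = finalCandidates,
                 assay = assay, epcr = epcr,
                 discoverable = discoverable,
                 evalRaw = evalRaw, evalFinal = evalFinal,
                 paralogStats = paralogStats)
  if (!is.null(outdir)) persistPipeline(result, outdir)
  result
}

#' Persist pipeline artifacts in standard formats
#'
#' Writes genomes (FASTA), truth (TSV), annotations (BED), fragments
#' (FASTA+BED), reads (FASTQ + truth sidecars), references (FASTA + JSON
#' sidecar), alignments (SAM), candidates (TSV + VCF), the filter report
#' (JSON + table), assay records (TSV), evaluation metrics (JSON), and the
#' resolved configuration (YAML).
#'
#' @param result \code{\link{runPipeline}} output.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
persistPipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  writeConfigYaml(result$config, pth("config.yaml"))
  writeGenomeFasta(result$genomeA, pth("genomeA.fasta"))
  writeGenomeFasta(result$genomeB, pth("genomeB.fasta"))
  writeTruthTable(result$truth, pth("truth.tsv"))
  writeAnnotationsBed(result$genomeA, pth("annotations.bed"))
  writeFragments(result$tier1A, pth("tier1A.fasta"), pth("tier1A.bed"))
  writeFragments(result$tier2A, pth("tier2A.fasta"), pth("tier2A.bed"))
  writeFragments(result$tier2B, pth("tier2B.fasta"), pth("tier2B.bed"))
  writeReadsFastq(result$longReads, pth("long_reads.fastq"))
  writeReadsFastq(result$readsA, pth("shortA.fastq"))
  writeReadsFastq(result$readsB, pth("shortB.fastq"))
  writeReferenceSet(result$refs, pth("reference.fasta"))
  if (isTRUE(result$config$writeSam)) {
    writeAlignmentsSam(result$alignmentsB, result$refs, pth("alignB.sam"))
    writeAlignmentsSam(result$alignmentsA, result$refs, pth("alignA.sam"))
  }
  writeCandidatesTsv(result$rawCandidates, pth("candidates_raw.tsv"))
  writeCandidatesTsv(result$cascade$inputFlags, pth("candidates_flags.tsv"))
  writeCandidatesTsv(result$finalCandidates, pth("candidates_final.tsv"))
  writeCandidatesVcf(result$finalCandidates, result$refs,
                     pth("candidates_final.vcf"))
  writeFilterReport(result$report, pth("filter_report.json"),
                    pth("filter_report.tsv"))
  writeAssayTable(result$assay, pth("assay_table.tsv"))
  writeEvalMetrics(result$evalFinal, pth("metrics_final.json"))
  writeEvalMetrics(result$evalRaw, pth("metrics_raw.json"))
  invisible(outdir)
}

#' Render the filter report and evaluation metrics together
#'
#' @param report A \code{\link{FilterReport-class}}.
#' @param metrics Optional metrics list from \code{\link{evaluateCandidates}}.
#' @return Character vector of report lines (also printed).
#' @export
renderReport <- function(report, metrics = NULL) {
  st <- reportStages(report)
  lines <- c("Filter cascade:",
             sprintf("  %-28s %8s %12s %8s", "stage", "in", "eliminated", "out"))
  for (r in seq_len(nrow(st)))
    lines <- c(lines, sprintf("  %-28s %8d %12d %8d", st$stage[r], st$nIn[r],
                              st$nEliminated[r], st$nOut[r]))
  if (!is.null(metrics)) {
    lines <- c(lines, "Evaluation:",
               sprintf("  reported: %d, true: %d", metrics$nReported,
                       metrics$nTrue),
               sprintf("  validation rate: %s",
                       ifelse(is.na(metrics$validationRate), "undefined",
                              sprintf("%.3f", metrics$validationRate))),
               sprintf("  recall: %s",
                       ifelse(is.na(metrics$recall), "n/a",
                              sprintf("%.3f", metrics$recall))))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
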