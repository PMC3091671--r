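#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet readDNAStringSet
#'   reverseComplement width
#' @importFrom GenomicRanges GRanges start end
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames
NULL

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit stage seed from a master seed and a stage name.
stageSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

randomBases <- function(n, gcFraction) {
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

#' Generate a random genome sequence
#'
#' Draws an i.i.d. DNA sequence with a target GC fraction. This stands in,
#' at desk scale, for one inbred genotype's genome; downstream stages treat
#' it as a single haploid chromosome.
#'
#' @param length Genome length in bp (positive integer).
#' @param gcFraction Target GC content in [0, 1].
#' @param seed Integer seed; identical arguments give identical sequences.
#' @param id Sequence label.
#' @return A \code{\link{GenomeSequence-class}} object with no annotations.
#' @examples
#' g <- generateGenome(1000, gcFraction = 0.4, seed = 7)
#' genomeLength(g)
#' @export
generateGenome <- function(length, gcFraction = 0.4, seed = 1L, id = "genomeA") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("'length' must be a positive integer")
  if (gcFraction < 0 || gcFraction > 1)
    stop("'gcFraction' must lie in [0, 1]")
  bases <- withSeed(seed, randomBases(length, gcFraction))
  new("GenomeSequence", id = id,
      seq = DNAString(paste(bases, collapse = "")),
      annotations = GRanges())
}

#' Derive a second genotype differing by SNPs only
#'
#' Creates the second inbred genotype from the first by substituting single
#' bases at an i.i.d. per-position rate; no indels are introduced, so the
#' two genomes share one coordinate system (genotype-A coordinates). Each
#' substitution is recorded in a truth table with class \code{true_snp}.
#' Positions inside organellar or contaminant insertions are never mutated,
#' so planted SNPs and foreign-sequence insertions cannot overlap.
#'
#' @param base A \code{\link{GenomeSequence-class}} (genotype A), possibly
#'   carrying planted complications.
#' @param snpRate Per-position substitution probability in [0, 1).
#' @param seed Integer seed.
#' @param id Label for the derived genotype.
#' @return A list with elements \code{genome} (the derived
#'   \code{GenomeSequence}; annotations carried over) and \code{truth}
#'   (data.frame with columns \code{genomeId}, \code{pos} (0-based,
#'   genotype-A coordinates), \code{alleleA}, \code{alleleB}, \code{class}).
#' @examples
#' g <- generateGenome(5000, seed = 1)
#' d <- deriveGenotype(g, snpRate = 0.005, seed = 11)
#' nrow(d$truth)
#' @export
deriveGenotype <- function(base, snpRate = 0.005, seed = 1L, id = "genomeB") {
  stopifnot(is(base, "GenomeSequence"))
  if (snpRate < 0 || snpRate >= 1)
    stop("'snpRate' must lie in [0, 1)")
  L <- genomeLength(base)
  ann <- genomeAnnotations(base)
  excluded <- rep(FALSE, L)
  if (length(ann)) {
    foreign <- ann[ann$class %in% c("organellar", "contaminant")]
    for (k in seq_along(foreign))
      excluded[GenomicRanges::start(foreign)[k]:GenomicRanges::end(foreign)[k]] <- TRUE
  }
  bases <- strsplit(as.character(base@seq), "", fixed = TRUE)[[1L]]
  res <- withSeed(seed, {
    pos <- which(runif(L) < snpRate & !excluded)
    alt <- character(length(pos))
    if (length(pos)) {
      off <- sample.int(3L, length(pos), replace = TRUE)
      for (i in seq_along(pos))
        alt[i] <- setdiff(DNA_BASES, bases[pos[i]])[off[i]]
    }
    list(pos = pos, alt = alt)
  })
  derived <- bases
  derived[res$pos] <- res$alt
  truth <- data.frame(
    genomeId = rep(genomeId(base), length(res$pos)),
    pos = res$pos - 1L,
    alleleA = bases[res$pos],
    alleleB = res$alt,
    class = rep("true_snp", length(res$pos)),
    stringsAsFactors = FALSE)
  genome <- new("GenomeSequence", id = id,
                seq = DNAString(paste(derived, collapse = "")),
                annotations = ann)
  list(genome = genome, truth = truth)
}

# Insert 'insert' (character vector of bases) into 'bases' before 1-based
# position 'at', shifting annotation coordinates downstream of the point.
insertSegment <- function(bases, ann, insert, at, class, seqname = "genome") {
  L <- length(bases)
  stopifnot(at >= 1L, at <= L + 1L)
  newBases <- append(bases, insert, after = at - 1L)
  w <- length(insert)
  if (length(ann)) {
    s <- GenomicRanges::start(ann); e <- GenomicRanges::end(ann)
    shift <- s >= at
    s[shift] <- s[shift] + w
    e[e >= at & !shift] <- e[e >= at & !shift] + w  # insertion inside an interval grows it
    e[shift] <- e[shift] + w
    GenomicRanges::ranges(ann) <- IRanges(start = s, end = e)
  }
  newAnn <- GRanges(seqnames = if (length(ann)) as.character(GenomeInfoDb::seqnames(ann))[1L] else seqname,
                    ranges = IRanges(start = at, end = at + w - 1L), class = class)
  list(bases = newBases, ann = c(ann, newAnn))
}

#' Plant confounding features into a genome
#'
#' Adds the complications a reduced-representation SNP pipeline must defend
#' against: paralogous duplications (a copied segment mutated at a set
#' divergence; both the source segment and the new copy are annotated
#' \code{paralog-copy}), a dispersed repeat family (identical copies of one
#' repeat unit), an organellar insertion, and a bacterial contaminant
#' insertion. Every planted feature is recorded as a labeled annotation
#' interval.
#'
#' @param genome A \code{\link{GenomeSequence-class}}.
#' @param nParalogs Number of paralogous duplications to plant.
#' @param paralogLength Length of each duplicated segment (bp).
#' @param paralogDivergence Per-base substitution rate between copy and
#'   source, in [0, 0.2].
#' @param nRepeats Number of copies of the repeat unit to insert.
#' @param repeatUnit Repeat unit sequence (character); generated at random
#'   (400 bp) when \code{NULL} and \code{nRepeats > 0}.
#' @param organellarSeq,contaminantSeq DNA strings to insert whole (each
#'   annotated with its class), or \code{""} to skip.
#' @param seed Integer seed.
#' @return A list with \code{genome} (annotated \code{GenomeSequence}) and
#'   \code{libraries} (named list of \code{DNAStringSet}s: \code{repeats},
#'   \code{organellar}, \code{contaminant} — the exclusion libraries the
#'   screening stages use).
#' @examples
#' g <- generateGenome(20000, seed = 1)
#' p <- plantComplications(g, nParalogs = 1, paralogLength = 2000,
#'                         paralogDivergence = 0.02, seed = 5)
#' genomeAnnotations(p$genome)
#' @export
plantComplications <- function(genome, nParalogs = 0L, paralogLength = 5000L,
                               paralogDivergence = 0.02, nRepeats = 0L,
                               repeatUnit = NULL, organellarSeq = "",
                               contaminantSeq = "", seed = 1L) {
  stopifnot(is(genome, "GenomeSequence"))
  if (paralogDivergence < 0 || paralogDivergence > 0.2)
    stop("'paralogDivergence' must lie in [0, 0.2]")
  L0 <- genomeLength(genome)
  for (s in c(organellarSeq, contaminantSeq))
    if (nchar(s) > L0)
      stop("insertion longer than the genome")
  if (nParalogs > 0L && paralogLength > L0)
    stop("insertion longer than the genome")
  bases <- strsplit(as.character(genome@seq), "", fixed = TRUE)[[1L]]
  ann <- genomeAnnotations(genome)
  libs <- list(repeats = DNAStringSet(), organellar = DNAStringSet(),
               contaminant = DNAStringSet())

  withSeed(seed, {
    if (nParalogs > 0L) {
      for (i in seq_len(nParalogs)) {
        src <- sample.int(length(bases) - paralogLength + 1L, 1L)
        seg <- bases[src:(src + paralogLength - 1L)]
        nmut <- rbinom(1L, paralogLength, paralogDivergence)
        if (nmut > 0L) {
          at <- sample.int(paralogLength, nmut)
          for (j in at) seg[j] <- sample(setdiff(DNA_BASES, seg[j]), 1L)
        }
        ins <- sample.int(length(bases) + 1L, 1L)
        # annotate the source interval too: false calls can surface on
        # references derived from either member of the pair
        srcAnn <- GRanges(genomeId(genome),
                          IRanges(src, src + paralogLength - 1L),
                          class = "paralog-copy")
        ann <- c(ann, srcAnn)
        out <- insertSegment(bases, ann, seg, ins, "paralog-copy",
                             genomeId(genome))
        bases <- out$bases; ann <- out$ann
      }
    }
    if (nRepeats > 0L) {
      if (is.null(repeatUnit))
        repeatUnit <- paste(randomBases(400L, 0.4), collapse = "")
      unit <- strsplit(toupper(repeatUnit), "", fixed = TRUE)[[1L]]
      for (i in seq_len(nRepeats)) {
        ins <- sample.int(length(bases) + 1L, 1L)
        out <- insertSegment(bases, ann, unit, ins, "repeat", genomeId(genome))
        bases <- out$bases; ann <- out$ann
      }
      libs$repeats <- DNAStringSet(structure(toupper(repeatUnit),
                                              names = "repeat_unit_1"))
    }
    if (nzchar(organellarSeq)) {
      ins <- sample.int(length(bases) + 1L, 1L)
      out <- insertSegment(bases, ann,
                           strsplit(toupper(organellarSeq), "", fixed = TRUE)[[1L]],
                           ins, "organellar", genomeId(genome))
      bases <- out$bases; ann <- out$ann
      libs$organellar <- DNAStringSet(structure(toupper(organellarSeq),
                                                 names = "organellar_1"))
    }
    if (nzchar(contaminantSeq)) {
      ins <- sample.int(length(bases) + 1L, 1L)
      out <- insertSegment(bases, ann,
                           strsplit(toupper(contaminantSeq), "", fixed = TRUE)[[1L]],
                           ins, "contaminant", genomeId(genome))
      bases <- out$bases; ann <- out$ann
      libs$contaminant <- DNAStringSet(structure(toupper(contaminantSeq),
                                                  names = "contaminant_1"))
    }
    invisible(NULL)
  })

  g <- new("GenomeSequence", id = genomeId(genome),
           seq = DNAString(paste(bases, collapse = "")), annotations = ann)
  list(genome = g, libraries = libs)
}

#' Write a genome as FASTA (80-column wrap)
#' @param genome A \code{\link{GenomeSequence-class}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  x <- DNAStringSet(genome@seq)
  names(x) <- genomeId(genome)
  writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path (first record used).
#' @return A \code{\link{GenomeSequence-class}} without annotations.
#' @export
readGenomeFasta <- function(path) {
  x <- readDNAStringSet(path)
  new("GenomeSequence", id = names(x)[1L], seq = x[[1L]], annotations = GRanges())
}

#' Write / read the planted-variant truth table
#'
#' Tab-separated with header \code{genome_id, pos_1based, allele_a,
#' allele_b, class}; positions 1-based in the file, 0-based in memory.
#'
#' @param truth Truth data.frame as returned by \code{\link{deriveGenotype}}.
#' @param path Output path.
#' @return \code{path} (write) or the truth data.frame (read), invisibly for write.
#' @export
writeTruthTable <- function(truth, path) {
  out <- data.frame(genome_id = truth$genomeId, pos_1based = truth$pos + 1L,
                    allele_a = truth$alleleA, allele_b = truth$alleleB,
                    class = truth$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "character",
                                        "character", "character"))
  data.frame(genomeId = x$genome_id, pos = x$pos_1based - 1L,
             alleleA = x$allele_a, alleleB = x$allele_b, class = x$class,
             stringsAsFactors = FALSE)
}

#' Write genome annotations as BED (0-based half-open)
#' @param genome A \code{\link{GenomeSequence-class}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationsBed <- function(genome, path) {
  ann <- genomeAnnotations(genome)
  out <- data.frame(chrom = rep(genomeId(genome), length(ann)),
                    start = GenomicRanges::start(ann) - 1L,
                    end = GenomicRanges::end(ann),
                    name = if (length(ann)) ann$class else character())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
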