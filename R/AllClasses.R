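#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

ANNOTATION_CLASSES <- c("paralog-copy", "repeat", "organellar", "contaminant")
VARIANT_CLASSES <- c("true_snp", "paralog_induced", "repeat_region")
DNA_BASES <- c("A", "C", "G", "T")

#' Restriction enzyme with a blunt-end cut model
#'
#' A named recognition motif plus the 0-based offset within the motif at
#' which both strands are cut (blunt ends). Only palindromic motifs are
#' accepted: for a palindromic blunt cutter the reverse-strand scan is
#' redundant and cut positions are computed on the forward strand alone.
#'
#' @slot name Enzyme name, e.g. \code{"HaeIII"}.
#' @slot recognition Recognition motif (IUPAC DNA, length >= 4), which must
#'   equal its own reverse complement.
#' @slot cutOffset 0-based offset within the motif where the duplex is cut.
#'
#' @examples
#' RestrictionEnzyme("HaeIII", "GGCC", 2L)
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@recognition) != 1L || nchar(object@recognition) < 4L)
    msg <- c(msg, "'recognition' must be a single motif of length >= 4")
  if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
      object@cutOffset < 0L || object@cutOffset > nchar(object@recognition))
    msg <- c(msg, "'cutOffset' must lie in [0, nchar(recognition)]")
  rec <- toupper(object@recognition)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", rec))
    msg <- c(msg, "'recognition' must be IUPAC DNA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rec)))
  if (rc != rec)
    msg <- c(msg, sprintf("motif '%s' is not palindromic; only palindromic blunt cutters are supported", rec))
  if (length(msg)) msg else TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,recognition,cutOffset See slots.
#' @export
RestrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutOffset = as.integer(cutOffset))
}

#' @export
setMethod("show", "RestrictionEnzyme", function(object) {
  m <- object@recognition
  cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
              substr(m, 1, object@cutOffset),
              substr(m, object@cutOffset + 1L, nchar(m))))
})

#' @describeIn RestrictionEnzyme-class Enzyme name.
#' @param x A \code{RestrictionEnzyme}.
#' @export
enzymeName <- function(x) x@name
#' @describeIn RestrictionEnzyme-class Recognition motif.
#' @export
enzymeMotif <- function(x) x@recognition
#' @describeIn RestrictionEnzyme-class 0-based cut offset within the motif.
#' @export
enzymeCutOffset <- function(x) x@cutOffset

#' The tier-1 enzyme catalogue
#'
#' The three enzymes used for the first-tier digestion, with standard REBASE
#' recognition sequences: HaeIII (GG^CC), PsiI (TTA^TAA), SspI (AAT^ATT).
#'
#' @return A named list of \code{\link{RestrictionEnzyme}} objects.
#' @examples
#' tier1Enzymes()
#' @export
tier1Enzymes <- function() {
  list(HaeIII = RestrictionEnzyme("HaeIII", "GGCC", 2L),
       PsiI = RestrictionEnzyme("PsiI", "TTATAA", 3L),
       SspI = RestrictionEnzyme("SspI", "AATATT", 3L))
}

#' Default tier-2 enzyme catalogue
#'
#' The running text names only the tier-1 enzymes; the second-tier set is
#' configurable. The default reapplies the tier-1 enzymes and adds one
#' frequent 4-cutter (AluI, AG^CT) so that 110-140 bp products exist within
#' 300-350 bp parents.
#'
#' @return A named list of \code{\link{RestrictionEnzyme}} objects.
#' @export
tier2Enzymes <- function() {
  c(tier1Enzymes(), list(AluI = RestrictionEnzyme("AluI", "AGCT", 2L)))
}

#' A genome sequence with feature annotations
#'
#' A single haploid chromosome-scale sequence for one genotype, with labeled
#' intervals marking planted complications (paralog copies, repeat family
#' members, organellar insertion, contaminant insertion). Annotations are
#' stored as an \code{IRanges} with a class label, 0-based half-open
#' externally (converted to 1-based closed internally by \code{IRanges}).
#'
#' @slot id Sequence label.
#' @slot seq A \code{DNAString} over A/C/G/T.
#' @slot annotations A \code{GRanges} on this sequence with an \code{mcols}
#'   column \code{class} drawn from \code{paralog-copy}, \code{repeat},
#'   \code{organellar}, \code{contaminant}.
#' @export
setClass("GenomeSequence",
  representation(id = "character", seq = "DNAString", annotations = "GRanges"))

setValidity("GenomeSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must be non-empty")
  ann <- object@annotations
  if (length(ann)) {
    if (is.null(ann$class) || !all(ann$class %in% ANNOTATION_CLASSES))
      msg <- c(msg, "annotation 'class' labels must come from the fixed vocabulary")
    if (any(GenomicRanges::start(ann) < 1L) ||
        any(GenomicRanges::end(ann) > length(object@seq)))
      msg <- c(msg, "annotations must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GenomeSequence", function(object) {
  cat(sprintf("GenomeSequence '%s': %d bp, %d annotation(s)\n",
              object@id, length(object@seq), length(object@annotations)))
  if (length(object@annotations)) {
    tab <- table(object@annotations$class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @describeIn GenomeSequence-class Sequence label.
#' @param x A \code{GenomeSequence}.
#' @export
genomeId <- function(x) x@id
#' @describeIn GenomeSequence-class The \code{DNAString}.
#' @export
genomeSeq <- function(x) x@seq
#' @describeIn GenomeSequence-class Annotated intervals (\code{GRanges}).
#' @export
genomeAnnotations <- function(x) x@annotations
#' @describeIn GenomeSequence-class Sequence length in bp.
#' @export
genomeLength <- function(x) length(x@seq)

#' A set of digestion fragments
#'
#' Fragments produced by in-silico restriction digestion, each with
#' provenance coordinates on its source sequence (0-based half-open in all
#' written outputs, 1-based closed internally), a tier label, and for tier-2
#' fragments a reference to the tier-1 parent fragment.
#'
#' @slot seqs \code{DNAStringSet} of fragment sequences, named by fragment id.
#' @slot info \code{DataFrame} with columns \code{fragId}, \code{sourceId},
#'   \code{start}, \code{end} (1-based closed on the source), \code{tier}
#'   (1 or 2), \code{parent} (tier-1 fragment id or \code{NA}).
#' @export
setClass("FragmentSet",
  representation(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  req <- c("fragId", "sourceId", "start", "end", "tier", "parent")
  if (!all(req %in% colnames(object@info)))
    msg <- c(msg, sprintf("info must have columns %s", paste(req, collapse = ", ")))
  else {
    if (nrow(object@info) != length(object@seqs))
      msg <- c(msg, "info rows must match number of sequences")
    if (nrow(object@info)) {
      if (any(object@info$end - object@info$start + 1L !=
              Biostrings::width(object@seqs)))
        msg <- c(msg, "fragment widths must equal coordinate spans")
      if (!all(object@info$tier %in% c(1L, 2L)))
        msg <- c(msg, "tier must be 1 or 2")
      if (any(object@info$tier == 2L & is.na(object@info$parent)))
        msg <- c(msg, "tier-2 fragments must carry a parent fragment id")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FragmentSet-class Construct from sequences plus an info table.
#' @param seqs,info See slots.
#' @export
FragmentSet <- function(seqs, info) {
  seqs <- as(seqs, "DNAStringSet")
  names(seqs) <- info$fragId
  new("FragmentSet", seqs = seqs, info = DataFrame(info))
}

#' @export
setMethod("show", "FragmentSet", function(object) {
  n <- length(object@seqs)
  cat(sprintf("FragmentSet: %d fragment(s)", n))
  if (n) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf(", tier %s, widths %d-%d bp",
                paste(sort(unique(object@info$tier)), collapse = "/"),
                min(w), max(w)))
  }
  cat("\n")
})

#' @export
setMethod("length", "FragmentSet", function(x) length(x@seqs))

#' @describeIn FragmentSet-class Fragment sequences (\code{DNAStringSet}).
#' @param x A \code{FragmentSet}.
#' @export
fragmentSeqs <- function(x) x@seqs
#' @describeIn FragmentSet-class Fragment provenance table (\code{DataFrame}).
#' @export
fragmentInfo <- function(x) x@info
#' @describeIn FragmentSet-class Fragment lengths in bp.
#' @export
fragmentWidths <- function(x) Biostrings::width(x@seqs)

#' Subset a FragmentSet
#' @param x A \code{FragmentSet}.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "FragmentSet", function(x, i, j, ..., drop = TRUE) {
  new("FragmentSet", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

#' Long-read reference set (contigs and singletons)
#'
#' The coordinate system for all SNP calls: consensus sequences built from
#' clustered long reads. Bases may be N (quality-masked or ambiguous
#' consensus columns). A singleton is supported by exactly one read.
#'
#' @slot seqs \code{DNAStringSet} over A/C/G/T/N, named by reference id.
#' @slot nReads Integer vector: supporting long-read count per reference.
#' @slot quals List of integer Phred vectors, one per reference (column
#'   quality = max supporting read quality).
#' @slot provenance List (one element per reference) of per-column genome
#'   placements for synthetic truth tracking, or empty when unavailable.
#' @export
setClass("ReferenceSet",
  representation(seqs = "DNAStringSet", nReads = "integer", quals = "list",
                 provenance = "list"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(object@nReads) != length(object@seqs))
    msg <- c(msg, "nReads must have one entry per reference")
  if (length(object@quals) && length(object@quals) != length(object@seqs))
    msg <- c(msg, "quals must be empty or have one entry per reference")
  if (length(object@seqs) && any(Biostrings::width(object@seqs) < 1L))
    msg <- c(msg, "reference sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceSet-class Construct from sequences and read counts.
#' @param seqs,nReads,quals,provenance See slots.
#' @export
ReferenceSet <- function(seqs, nReads, quals = list(), provenance = list()) {
  seqs <- as(seqs, "DNAStringSet")
  new("ReferenceSet", seqs = seqs, nReads = as.integer(nReads),
      quals = quals, provenance = provenance)
}

#' @export
setMethod("show", "ReferenceSet", function(object) {
  n <- length(object@seqs)
  nc <- sum(object@nReads >= 2L)
  cat(sprintf("ReferenceSet: %d reference(s) (%d contig(s), %d singleton(s))\n",
              n, nc, n - nc))
})

#' @export
setMethod("length", "ReferenceSet", function(x) length(x@seqs))

#' @describeIn ReferenceSet-class Reference sequences (\code{DNAStringSet}).
#' @param x A \code{ReferenceSet}.
#' @export
refSeqs <- function(x) x@seqs
#' @describeIn ReferenceSet-class Supporting read count per reference.
#' @export
refNReads <- function(x) x@nReads
#' @describeIn ReferenceSet-class \code{"contig"} or \code{"singleton"} per reference.
#' @export
refKind <- function(x) ifelse(x@nReads >= 2L, "contig", "singleton")
#' @describeIn ReferenceSet-class Per-column Phred qualities (list of integer vectors).
#' @export
refQuals <- function(x) x@quals
#' @describeIn ReferenceSet-class Per-column genome provenance (list), if tracked.
#' @export
refProvenance <- function(x) x@provenance

#' Subset a ReferenceSet
#' @param x A \code{ReferenceSet}.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ReferenceSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("ReferenceSet", seqs = x@seqs[i], nReads = x@nReads[i],
      quals = if (length(x@quals)) x@quals[i] else list(),
      provenance = if (length(x@provenance)) x@provenance[i] else list())
})

#' Per-stage filter bookkeeping report
#'
#' An ordered record of the false-positive filter cascade: for each stage the
#' number of candidates entering, eliminated, and surviving. Validity
#' enforces the conservation rules: \code{nOut == nIn - nEliminated} at every
#' stage and \code{nIn} of stage k+1 equals \code{nOut} of stage k.
#'
#' @slot stages A \code{data.frame} with columns \code{stage}, \code{nIn},
#'   \code{nEliminated}, \code{nOut}.
#' @export
setClass("FilterReport", representation(stages = "data.frame"))

setValidity("FilterReport", function(object) {
  st <- object@stages
  msg <- character()
  req <- c("stage", "nIn", "nEliminated", "nOut")
  if (!all(req %in% colnames(st)))
    return(sprintf("stages must have columns %s", paste(req, collapse = ", ")))
  if (nrow(st)) {
    if (any(st$nOut != st$nIn - st$nEliminated))
      msg <- c(msg, "nOut must equal nIn - nEliminated at every stage")
    if (nrow(st) > 1L && any(st$nIn[-1L] != st$nOut[-nrow(st)]))
      msg <- c(msg, "nIn of each stage must equal nOut of the previous stage")
    if (any(st$nEliminated < 0L) || any(st$nOut < 0L))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FilterReport
#'
#' @param stage Character vector of stage names, in execution order.
#' @param nIn Integer vector of candidates entering each stage.
#' @param nEliminated Integer vector of candidates removed at each stage.
#' @return A \code{\link{FilterReport-class}} object; \code{nOut} is derived.
#' @examples
#' FilterReport(c("paralog_filter", "allele_swap_verify"),
#'              nIn = c(35784L, 34477L), nEliminated = c(1307L, 29312L))
#' @export
FilterReport <- function(stage, nIn, nEliminated) {
  nIn <- as.integer(nIn); nEliminated <- as.integer(nEliminated)
  new("FilterReport", stages = data.frame(
    stage = as.character(stage), nIn = nIn, nEliminated = nEliminated,
    nOut = nIn - nEliminated, stringsAsFactors = FALSE))
}

#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@stages, row.names = FALSE)
})

#' @describeIn FilterReport-class The per-stage table.
#' @param x A \code{FilterReport}.
#' @export
reportStages <- function(x) x@stages
#' @describeIn FilterReport-class Final surviving candidate count.
#' @export
reportFinalCount <- function(x) {
  st <- x@stages
  if (!nrow(st)) 0L else st$nOut[nrow(st)]
}
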