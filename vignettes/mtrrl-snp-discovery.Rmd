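---
title: "Reference-free SNP discovery from a multi-tier reduced representation library"
author: "rrlSNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free SNP discovery from a multi-tier reduced representation library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the design

For a species without a sequenced genome, short-read SNP discovery has no
coordinate system to align against. The multi-tier reduced representation
library (mtRRL) design solves this with two rounds of restriction digestion
and gel size selection. A first digest of genotype A with three blunt,
palindromic enzymes (HaeIII GG^CC, PsiI TTA^TAA, SspI AAT^ATT) is
size-selected to 300-350 bp and sequenced with a long-read platform; the
assembled contigs and singletons become the reference. The same 300-350 bp
fraction of both genotypes is digested again and the 110-140 bp products are
end-sequenced with a short-read platform (36-42 bp reads). Because every
tier-2 fragment nests inside a tier-1 fragment, the short reads land at many
positions within the long-read reference, and SNPs called near the middle of
a reference sequence come with enough flanking sequence to design a
genotyping assay.

`rrlSNP` implements this pipeline end to end, reference-free, on synthetic
two-genotype worlds with planted ground truth, so that every stage —
digestion, read simulation, reference construction, ungapped alignment,
SNP calling, the five-stage false-positive filter cascade, and assay
designability — can be measured against what was planted.

## Pipeline stages and their models

**Digestion** is modeled as complete (no partial digests, no star
activity): fragments are the maximal intervals between the union of cut
sites over all enzymes, and blunt cutting loses no bases, so the fragments
always concatenate back to the input. Only palindromic blunt cutters are
accepted; cut positions are computed on the forward strand, which covers
both strands for a palindrome. Size windows are inclusive on both ends —
gel excision is approximate and the boundary convention is stated rather
than inferred.

**Long-read simulation** draws read lengths from a truncated normal (mean
230 bp, matching the platform's reported average read length; the median is
not separately enforced) and samples reads per fragment as Poisson with
mean `coverageDepth * fragmentLength / meanReadLength`. The platform's
characteristic error is a homopolymer length miscall: each run of two or
more identical bases independently gains or loses one base with probability
`homopolymerErrorRate`. Qualities follow a two-tier model (high for
confident bases, reduced inside long runs, low where an error was applied):
downstream stages only discriminate at Phred 20 (reference masking) and at
the allele-score threshold, so a full quality profile would add nothing
testable.

**Short-read simulation** is end-anchored: sequencing-by-synthesis proceeds
from adapters ligated at fragment ends, so every read starts at a tier-2
fragment end (right-end reads reverse-complemented), with lengths uniform
on 36-42 bp and i.i.d. substitution errors. Erroneous bases receive Phred 8
— below both the masking and allele-score thresholds — so a lone erroneous
read cannot drive a call, while coincident errors at one position remain
possible, which is exactly the failure mode the allele-consistency screen
addresses.

**Reference construction** stands in for a de novo assembler at contract
level: greedy seed-and-extend clustering indexes every k-mer (k = 40, the
minimum overlap) of each cluster's span and joins a read to the cluster
with the best ungapped overlap at identity >= 0.98, in either orientation;
consensus is per-column majority with ties masked to N, per-column quality
is the maximum supporting read quality, and unmerged reads are emitted as
singletons. Masking then turns every base below Phred 20 into N (a base at
exactly 20 is kept), references shorter than 61 bases or more than 75% N
are eliminated, and references sharing an exact 30-base word (either
strand) with the organellar exclusion library are removed. The 30-mer
shared-word rule realizes the seed requirement of a word-size-30 megablast
search without extension or E-values: it is deterministic, testable, and
conservative relative to seeded extension, because any seeded alignment
must contain such a word.

**Alignment and calling.** Short reads are aligned ungapped over their full
length with a budget of 2 mismatches, and only reads with a *unique*
minimum-mismatch placement are used; ties are discarded as ambiguous, which
prevents reads from duplicated loci from inflating depth at either copy.
The search seeds each read with three disjoint exact 12-mers (any placement
within a 2-mismatch budget leaves at least one seed intact) and verifies
candidates by a full Hamming count; the test suite checks this against an
exhaustive scan over every reference, offset and strand. The allele call
score is a declared proxy for an opaque vendor statistic: the summed Phred
quality of reads supporting the best non-reference allele minus the summed
quality of all other non-reference alleles. A site is called when that
score reaches 10, at least 3 reads cover the site, and the reference base
is not N. The call is made to the single best-scoring alternate allele;
extra alleles do not block it, because multi-allele evidence is removed
later by the consistency screen. No indels are ever called.

**The filter cascade** runs in a fixed order with full per-stage
bookkeeping (`n_out = n_in - n_eliminated` at every stage, chained):

1. *Paralog filter*: genotype A's own short reads are aligned back to the
   genotype-A reference and SNPs are called with the same thresholds; any
   candidate site that also receives such a self-call is a paralog artifact
   and is removed.
2. *Allele-swap verification*: the candidate's alternate allele is
   substituted into the reference (all sites of one reference batched into
   one modified copy — sites are sparse, and a per-site diagnostic mode
   exists to measure co-substitution interference), genotype A's reads are
   re-aligned, and the candidate survives only if a call back to the
   original reference allele is made. This demands reciprocal evidence for
   both alleles at the locus.
3. *Repeat screen* and 4. *contaminant screen*: candidates on references
   flagged by the 30-mer shared-word rule against the repeat or bacterial
   library are removed; the contaminant screen runs at the end of the
   cascade, where the candidate set is smallest.
5. *Allele-consistency screen*: a candidate is removed if any genotype-B
   read covering the site carries a base other than the called alternate
   allele. By default a genotype-B read showing the *reference* allele also
   violates consistency (strict unanimity); the alternative reading — that
   only third alleles count — is available as `strict = FALSE`, but strict
   unanimity is the default because the screen exists to guarantee a single
   B allele before assay design.

Stages can be disabled individually for ablation but never reordered.

**Assay design** extracts up to 60 bp of flanking sequence per side
(truncated at reference ends and at the first N) and scores designability
with a transparent heuristic — flank-length sufficiency, absence of other
candidate SNPs within 60 bp, flank GC within [0.2, 0.8], no homopolymer run
of 8 or more — with declared weights (0.4/0.3/0.15/0.15). The score is 1.0
exactly when all criteria hold and is monotone in each component. It is
explicitly *not* equivalent to any proprietary assay-design score; the
conventional 0.4/0.6/0.8 cutpoints may be applied to it as configuration.
Primer picking thermodynamics is out of scope: the naive pair anchors 20-mers
at the outer flank ends, and the e-PCR style screen then locates every
convergent placement across the reference set with at most 3 substitutions
and 1 gap per primer and a product of 80-300 bp, collapsing gapped variants
of one annealing site into a single locus; a pair passes only if exactly
one product locus exists.

## The synthetic world: what it emulates, and what it does not

`generateGenome` draws an i.i.d. genome at a target GC (default 0.4, 1 Mb
at desk scale). `plantComplications` adds the confounders the cascade is
built to remove: paralogous duplications (a copied segment mutated at 2%
divergence; both members of each pair are annotated, since false calls can
surface on references from either), a dispersed repeat family, an
organellar insertion and a bacterial contaminant insertion — the inserted
sequences double as the exclusion libraries the screens use, mirroring how
real screens use curated chloroplast/repeat/bacterial databases.
`deriveGenotype` then creates the second inbred genotype by substituting
single bases at rate 0.005, never inside the foreign insertions, recording
every substitution in a truth table on shared (genotype-A) coordinates.
Both lines are haploid and homozygous; there is no indel variation, no
heterozygosity, no residual heterogeneity, and no realistic repeat
landscape. Consequently, passing tests demonstrate the pipeline's internal
correctness and its behavior against these planted confounders — not
performance on real chromatin, real repeat families, or diverged wild
accessions.

One calibration deserves emphasis. The published run assembled 160,036
reference sequences of which 92,696 (58%) were singletons; under a Poisson
sampling model the singleton fraction P(N=1 | N>=1) is 58% at roughly one
read per captured fragment, so the default long-read coverage is set to 0.7
(about one read per 300-350 bp fragment) rather than to a saturating depth.
This reproduces two properties of the real study that matter downstream:
most references are singletons, and the reference captures only part of the
tier-1 pool, so short reads from an uncaptured locus can cross-map onto a
captured homolog — the mechanism that creates paralog-induced false calls
and gives the self-mapping and allele-swap stages real work to do. Short
reads default to 20 per tier-2 fragment end for each genotype.

"Discoverable" sites — the denominator of recall — are planted SNPs covered
by at least `minDepth` uniquely placed reads of *both* genotypes on a
retained reference, excluding sites inside paralog or repeat annotations
(reads from duplicated loci are not separable by position, so such sites
are ambiguous by construction, and the unique-placement rule deliberately
discards their reads).

## Numerical choices and degenerate inputs

- Coordinates are 1-based closed inside the package (the R/Bioconductor
  convention); all written outputs are 1-based except BED, which is 0-based
  half-open as the format requires.
- Consensus ties mask to N; calls are never made at N reference bases.
- The caller breaks allele-score ties lexicographically, making output
  deterministic.
- Every stage derives its seed from the master seed by hashing the stage
  name, so any stage can be rerun in isolation and reruns are
  byte-identical. Error and error-free runs at the same seed share their
  sampled read windows (the error draw is consumed whatever the rate).
- Empty inputs (no fragments in a window, no candidates entering a stage)
  propagate as empty sets with zero-count reports, never as errors.
- The tier-2 enzyme identity is not fixed by the protocol text; the default
  reapplies the three tier-1 enzymes (their sites cannot occur inside tier-1
  fragments) plus one 4-cutter, AluI (AG^CT), so that 110-140 bp products
  exist inside 300-350 bp parents. The set is configuration, not a claim.

## Problem sizes in the tests

The default study is a 1 Mb genome; a run produces roughly 190 tier-1
fragments in the 300-350 bp window, 40-55 tier-2 fragments, some 200 long
reads and 2,000 short reads per genotype, and a handful of discoverable
SNPs, completing in well under a minute. The acceptance checks use 5 seeds
for truth recovery and cascade efficacy, 100 random 50 kb genomes for
digest reconstruction, and 1,000 random reads against ~20 kb of reference
for the aligner-oracle equivalence; the paralog-elimination property is
measured on a focused 80 kb scenario in which the reference deliberately
captures only one member of each duplicated pair, the configuration that
produces cross-mapped calls at a testable rate. The assay e-PCR screen is
exercised on constructed fixtures and runs over a sample of at most 192
candidates in the full pipeline, following the design-validation practice
of screening a random subset.

## Known limitations

- The clustering reference builder is greedy and order-dependent; at high
  long-read depth it can split one fragment across two overlapping contigs
  instead of merging them. At the calibrated depth this is immaterial
  (most references are singletons), but it is not an assembler.
- Homopolymer indels in long reads break the ungapped overlap model, so
  affected reads tend to become singletons, and provenance mapping assumes
  indel-free consensus columns; evaluation runs therefore default to
  homopolymer error 0.
- The allele call score, the designability heuristic and the shared-word
  screen are declared proxies: faithful to the thresholds and bookkeeping
  they feed, not to the internals of the tools they replace.
- Validation and recall are defined against planted truth on synthetic
  data; nothing here estimates wet-lab validation rates for real libraries.
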