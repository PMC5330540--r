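---
title: "Detecting selenocysteine tRNA genes with covariance models"
author: "secScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selenocysteine tRNA genes with covariance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secScan)
library(GenomicRanges)
library(S4Vectors)
```

## The problem

Selenocysteine (Sec) is inserted co-translationally at recoded UGA codons.
The Sec-specific tRNA (tRNA^Sec^, gene *selC*) is the keystone of the
pathway: a genome encodes selenoproteins essentially if and only if it
carries a functional tRNA^Sec^, which makes this single gene a reliable
marker of the Sec trait. tRNA^Sec^ is also the longest known tRNA
(90--101 nt) and folds unlike every other tRNA: the coaxial acceptor+T
stem (the "AT-stem") has 13 base pairs -- 9/4 in eukaryotes and archaea,
8/5 in bacteria -- instead of the canonical 12 (7/5); the D-stem is long
(6 bp, 7 bp in most archaea) with a short 4-nt D-loop; and the variable
arm is long. General-purpose tRNA finders are built around the canonical
cloverleaf and miss or misannotate this fold. secScan instead searches
with covariance models (profile stochastic context-free grammars) built
directly from structurally annotated tRNA^Sec^ alignments, one model per
domain of life.

## The model

A covariance model (CM) is a profile SCFG: a guide tree of nodes derived
deterministically from the consensus secondary structure (pair-match nodes
for consensus base pairs, left/right-match nodes for unpaired positions,
bifurcations for the multiloop), each expanded into match, delete, and
insert states. Emission and transition probabilities are estimated from the
seed alignment; scores are log~2~ odds (bits) against an iid null with
equal nucleotide frequencies, so a bit score compares the joint
sequence-and-structure likelihood with a background explanation of the same
length.

Parameter choices that matter:

* **Match columns.** A column is a match column when fewer than half of
  the seed rows are gaps. Minority-occupancy columns become insert states
  with genuine counts.
* **Emission pseudocount** (`pseudocount`, default 1): Laplace smoothing
  over the 4 singlet / 16 pair emission cells.
* **Transition pseudocount** (`transitionPseudocount`, default `1e-4`).
  Transitions see at most a handful of distinct outcomes per node, and a
  large pseudocount materially over-weights indel paths never observed in
  the seed: with +1 the generative model produced samples up to 16 nt
  shorter than any real tRNA^Sec^. The near-ML default keeps unseen paths
  parseable (about -20 bits per unseen transition) without distorting the
  family.
* **Null model**: uniform 0.25 per nucleotide; `N` emits at the null
  (0 bits) everywhere.
* **Sequence weighting**: none (uniform weights).
* **Intron accommodation** (`intronCap`): eukaryotic tRNA introns
  invariably interrupt the anticodon loop one base 3' of the anticodon.
  The insert state at that point (after position 37) has its
  self-transition floored at -0.1 bits during scoring, so a 14--60-nt
  intron costs a few bits rather than hundreds. This affects scoring only,
  never sampling.

Alignment is global in the model and local in the genome ("glocal"): there
are no local begins/ends inside the model, so every hit accounts for the
entire cloverleaf, and the arm-completeness filter then inspects what the
parse actually realized.

## Search

`scanGenome()` evaluates every start position on both strands with each
model using a banded CYK dynamic program (Rcpp). Per-state parse-length
bands are derived from the consensus span of each state's subtree: slack of
30 nt for deletions and 40 nt for insertions on the guide-tree path that
contains the intron point, 12 nt elsewhere. The maximum parse length is
the consensus length plus 30 (`windowPad`). The scan DP uses single
precision; reported candidates are re-aligned in double precision to attach
their traceback parse. Genomes are processed in overlapping chunks
(`chunkSize`, default 1000 nt, overlap one window) purely to bound memory;
results are independent of chunking.

Hits at or above the threshold *T* (default 40 bits) are kept;
`resolveOverlaps()` collapses same-strand overlapping hits to the single
best one (ties: longer interval, then eukaryota < bacteria < archaea, then
leftmost start), and the locus is labelled with the domain of the winning
model. Thresholding happens before overlap resolution.

## Annotation and filtering

For each resolved hit the parse gives, per arm, the consensus pairs
actually emitted as pairs, realized loop lengths, and insertions inside
stems (bulges). Downstream:

* **Anticodon**: the bases at tRNA positions 34--36; undefined if any is
  deleted. Candidates whose anticodon is not UCA (including undefined) must
  pass a stringent threshold of 55 bits -- rare genuine variants (e.g. the
  CUA anticodon reading UAG Sec codons) survive only with strong support.
* **Arm filter**: each stem must realize at least its consensus pair count
  minus 2 (V-stem at least 2), all five arms present. These minima are this
  package's declared defaults; they pass every clean sample from all three
  bundled models while removing the typical false positives (shorter or
  missing arms).
* **Discriminator (position 73)**: deliberately *not* a model column, so it
  never contributes to the score. It is located as the 14th genomic residue
  3' of the residue aligned to position 61 (the last T-loop position;
  13 AT-stem 3'-strand residues lie between), read from the genome in hit
  orientation and independent of how many acceptor pairs the parse
  realized. For 12-bp AT-stem (7/5) variants this fixed offset lands one
  base 3' of the structurally correct discriminator; such candidates are
  recognizable by their fold label. G73 is reported as a flag, as is a
  genomically encoded CCA tail (the three residues following the
  discriminator; expected in bacteria, absent in most eukaryotic and
  archaeal genes where CCA is added post-transcriptionally).
* **Fold label**: 9/4, 8/5, 7/5 or "other" from the realized acceptor and
  T-stem pair counts, with the AT-stem total alongside.
* **Introns**: an insertion of at least 8 nt (default; real eukaryotic tRNA
  introns are 14--60 nt) exactly one base 3' of the anticodon is reported
  as an intron and spliced out of the mature sequence. The mature sequence
  scores at least as well as the unspliced one on the same model.

`classifyCopy()` compares an additional gene copy to the genome's
top-scoring candidate: *identical* (exact match including 100 nt of
genomic flanks -- a signature of assembly duplication), otherwise per
consensus pair *compensatory* (both copies pair, both partner bases
differ), *disrupted* (pairing status differs, or a partner is deleted), or
*equivalent*; the overall call is disrupted before compensatory before
equivalent. The per-pair classes are symmetric in the two candidates.

## Model refinement

`iterativeAlign()` re-aligns training sequences to the current model,
induces the implied multiple alignment, and rebuilds, until the alignment
is literally unchanged. Two caveats are documented deliberately. First,
the recorded total bit score of the first iteration is computed under the
bootstrap model; if that model was trained on a much deeper seed, its
absolute bit level is not comparable to the rebuilt models (pseudocount
dilution scales with training depth), so monotonicity is only meaningful
among rebuilt iterates -- a decrease there triggers the oscillation path
and the best-scoring rebuilt iterate is returned. Second,
`foldSequence()` is a maximum-base-pair (Nussinov) folder with minimum
hairpin loop 3 and a deterministic 5'-most tie-break -- a structural
stand-in, not a thermodynamic model; an external folder can be plugged in
wherever a dot-bracket string is accepted.

Training-set filtering follows two rules: a structural plausibility score
of at least 0 bits on the bootstrap model, and a UCA anticodon.

## The benchmark harness

Because Sec is not universal, tRNA^Sec^ prediction admits a genome-level
benchmark that is impossible for other tRNAs: any prediction in a
Sec-devoid genome is a false positive and absence of predictions in a
selenoprotein-encoding genome is a false negative. `evaluateBenchmark()`
computes sensitivity (% of positive genomes with at least one prediction),
specificity (% of negative genomes with none) and mean predictions per
genome, to one decimal (half-up), from a neutral predictions table -- so
any external predictor's output can be scored the same way.

## The synthetic-data generator

`makeGenome()` builds iid-background genomes (configurable GC, default 0.5)
with planted items at recorded coordinates and strands, emitting truth
tables (0-based half-open, BED-style). Planted tRNA^Sec^ genes are sampled
from the bundled models (resampled until the anticodon is UCA -- a planted
functional gene), with the genomic trailer the models deliberately exclude:
the discriminator G and, for bacteria, a CCA tail. Canonical-tRNA decoys
(7/5 fold, 4-bp D-stem, 12-bp AT-stem, ~75 nt) come from a fourth bundled
model. Mutation modes generate the copy classes: `compensatory` rewrites an
intact pair to a different Watson-Crick/GU pair, `disruptive` breaks one.
Introns are iid sequence inserted exactly one base 3' of the anticodon.

The bundled seeds themselves are synthetic: 128 sequences per domain drawn
around a seeded random consensus with compensatory stem variation (6% per
pair), low loop variation (3%), fixed universally conserved anchors (G18,
G19, U33, UCA, U55, C61, C66) and a variable-length V-loop insert block
that gives sampled lengths the real 90--101-nt spread. They encode exactly
the published consensus topologies (eukaryota 9/4 with 6-bp D-stem,
90 consensus columns; bacteria 8/5 with 6-bp D-stem, 91; archaea 9/4 with
7-bp D-stem, 92). What passing tests on these fixtures shows is that the
*method* -- model building, scanning, annotation, filtering -- behaves as
specified on data with the family's architecture and conservation
structure; it does not certify performance on real genomes, whose
repeats, composition bias, pseudogenes and diverged family members the
iid generator does not emulate. Scores are this package's bits and are
internally consistent, but not numerically comparable to other CM
implementations (priors and weighting differ).

## Problem sizes used in the tests

The shipped test-suite runs the full pipeline on synthetic genomes of
1.5--6 kb (50 genomes in the recovery/rejection suite, generator seeds
1--50), a 50-kb signal-free negative control, exhaustive CYK-vs-oracle
enumeration on toy models up to length 10, and 100--200-replicate score
distributions. These sizes were chosen so the whole suite exercises every
claim at desk scale; all scale linearly in sequence length for larger
runs (the scanner processes a few hundred kilobases per minute per
model-strand on one core).

## Known limitations

* Local/truncated hits are not modelled: a gene split across contig ends
  is missed or truncated.
* No E-values; thresholds are in bits.
* The discriminator rule assumes the 13-bp AT-stem; 7/5 variants need the
  fold-label flag and manual review.
* The ORF screen (`orfScreen()`) assumes prokaryotic single-exon CDS
  annotations and uses local protein alignment against user-supplied
  homologues (BLOSUM62, affine gaps 11/1, score minimum 40; U scores as C);
  it ranks readthrough candidates by TGA/Cys support and does not examine
  SECIS elements.
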