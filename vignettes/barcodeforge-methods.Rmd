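---
title: "Methods: specimen barcoding and metabarcoding annotation with barcodeforge"
author: "barcodeforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specimen barcoding and metabarcoding annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeforge)
```

# The problem

Species-level metabarcoding of zooplankton is limited less by sequencing
than by reference databases. Public COI collections are thin and
geographically biased for rotifers, cladocerans and copepods, and their
intraspecific divergences are often large enough that a community read has
no hit above any sensible identity cutoff. The remedy is an *indigenous*
database: one COI barcode per locally collected, morphologically identified
specimen. Producing those barcodes one specimen at a time by Sanger
sequencing fails frequently for organisms this small; amplifying every
specimen separately, pooling the amplicons, and sequencing the pool on a
high-throughput instrument is far more efficient — but shifts the burden to
software, which must recover exactly one correct barcode per specimen out
of a read soup that also contains sequencing error, co-amplified bacterial
COI (endosymbionts such as *Wolbachia*, or gut content), PCR chimeras, and
occasionally pseudogene-like fragments.

`barcodeforge` is that software, plus the downstream half: auditing the
resulting database with genetic distances and trees, and annotating
community metabarcoding OTUs against it.

# One identity definition everywhere

Every similarity decision in the package — read clustering, chimera parent
scoring, amino-acid panel classification, OTU assignment — uses a single
definition: global (Needleman–Wunsch) alignment with match +1, mismatch −1,
gap open −2, gap extension −1; identity is matches divided by aligned
columns after terminal gap columns are stripped, and "alignment length" is
that column count. Stripping terminal gaps keeps ragged ends (incomplete
trimming, shorter references) from diluting identity, without rewarding
tiny overlaps: an assignment additionally requires a minimum alignment
length. The aligner is compiled (Gotoh's three-state recurrence); for
equal-length pairs the gap-free comparison is used as a fast path in the
clustering join decision, accepting when ungapped identity already clears
both the threshold and 90%, and rejecting without the full alignment when
it falls more than 20 points below the threshold. At those similarities the
gap-free alignment is the score optimum, so the fast path changes no
decisions for substitution-dominated reads; data with long compensating
indels would need the full alignment everywhere, which the gray zone still
receives.

# Pre-treatment

Stages run in a fixed order: quality → primer → length → dereplication →
chimera detection. The order itself is a package decision (the upstream
tools this replaces do not document theirs); putting dereplication before
chimera detection is required by the abundance-skew model, and quality
first avoids paying primer-matching costs on hopeless reads.

* **Quality** (`quality_filter`): discard a read iff its expected error
  count $\sum_i 10^{-q_i/10}$ exceeds 1.0 or its mean Phred score is below
  20. Both thresholds are package defaults, configurable in
  `filter_params()`; whole-read accept/reject only, no quality trimming.
* **Primers** (`locate_and_trim_primers`): the degenerate forward primer is
  sought at the 5′ end of the read and of its reverse complement, anchored
  with a ±2 bp slack window (amplicons are primer-flanked by construction,
  so a free-floating search only invites false matches). A position matches
  iff the IUPAC sets of read and primer symbol intersect — necessary
  because the primers are heavily degenerate. The orientation with fewer
  mismatches wins; more than 2 mismatches in both orientations rejects the
  read. The reverse-primer complement is trimmed from the 3′ end when found
  within the same tolerance, but its absence is not a rejection (short
  reads may simply not reach it).
* **Length** (`length_filter`): reads shorter than 200 bp are removed,
  boundary inclusive (exactly 200 bp is kept).
* **Dereplication** (`dereplicate`): exact string identity; abundance ties
  break lexicographically so every downstream stage is deterministic.

## Chimera detection

`detect_chimeras` implements the core of the de-novo two-parent model: a
query is chimeric if some single-crossover concatenation of two more
abundant sequences explains it better than any single parent. Parameters
and their reasons:

* *Abundance skew ≥ 2×*: a chimera arises after its parents during PCR, so
  it should be rarer; candidate parents must be at least twice the query's
  abundance.
* *Gain ≥ 1 percentage point* over the best single parent, with each parent
  contributing ≥ 30 matching positions — a crossover too close to an end is
  indistinguishable from sequencing noise.
* *Model identity ≥ 97%*: the two-parent model must explain the query up to
  sequencing error (the same 97% used as the clustering radius). Without
  this, the "best crossover of the best parent pair" gains a few points
  over the best single parent for *any* unrelated query — a co-amplified
  bacterial read at 27% identity to the specimen's parents, or a rare
  species' read scored against other species' parents in a pooled
  community — and the false-positive rate explodes. Real chimeras sit at
  ~100% minus the error rate.
* *Candidate cap*: only the 8 most abundant eligible parents are scanned
  per query; the pair scan is quadratic in candidates, and genuine parents
  are by assumption abundant.

The detector reports the best parent pair and the midpoint of the optimal
crossover plateau (the true crossover is only localizable between the
flanking parent differences). A known blind spot, shared with the model
itself: if the exact sequence of one parent never reaches abundance 2 in
the read set (e.g. scarce contaminant templates under high error rates),
chimeras involving it cannot be called. In the recovery pipeline this is
benign — such chimeras form low-abundance clusters that fail the coding
screen or the panel, and never outrank the true barcode.

# Specimen recovery

Within one specimen, uniques are clustered greedily in abundance order at
97% identity — wide enough to absorb ~1% sequencing error around the true
barcode, narrow enough to keep contaminants (>5% divergent) and other
species apart. The cluster representative is the *centroid*, the most
abundant exact read, not a column-wise consensus: with per-base error ~1%
and realistic depth, the error-free read is the modal sequence, and a
centroid can never be an alignment artifact.

Each cluster centroid passes a **coding screen**: translate in the three
forward frames (reads are already primer-oriented) under the invertebrate
mitochondrial code (table 5, where TGA is Trp and AGA/AGG are Ser — under
the standard code a genuine COI fragment would show spurious stops), and
require some frame with no internal stop codon. Nuclear-mitochondrial
pseudogenes and frameshifted artifacts typically fail this. The stop-free
translation is then **classified** by global amino-acid alignment against a
small labeled panel (`target_COI` translations plus `bacterial_COI`
decoys): the cluster takes the best hit's label if identity ≥ 60%, else
`unknown`. COI amino acids are strongly conserved within the animals, so
60% separates "some metazoan COI" from bacterial COI and junk without
requiring a close relative in the panel.

The recovered barcode is the centroid of the most abundant stop-free
`target_COI` cluster; `support` is that cluster's share of the specimen's
retained reads. If a non-target cluster is larger, recovery still succeeds
but the record is flagged `contaminant-majority`; with no qualifying
cluster a failure record carries the per-cluster diagnostics.

# Distances, discrimination, trees

K2P distances are computed from transition/transversion proportions with
*pairwise deletion*: positions where either sequence has a gap or non-ACGT
symbol are excluded pair by pair, preserving signal on ragged barcodes
(complete deletion would discard whole columns for one bad sequence).
Unequal-length pairs are globally aligned first; a multiple alignment is
deliberately avoided — same-marker amplicons gain nothing from it. When
1 − 2P − Q or 1 − 2Q is non-positive the pair is *saturated*: the distance
is undefined, matrix builders record it as such, and summaries exclude and
count it.

Intraspecific divergence reports both the mean and the maximum of all
conspecific pairwise K2P values (which summary a survey reports is often
unstated; both are cheap). The discrimination audit flags a species pair as
unresolved when the minimum interspecific distance does not exceed the
larger of the two species' maximum intraspecific distances — the absence of
a barcode gap, with shared identical barcodes as the limiting case.

Neighbor-joining follows the Saitou–Nei Q-criterion with deterministic
tie-breaking (first minimal pair in column-major order); on additive
matrices the reconstruction is exact, which the tests verify against
simulated trees, and the implementation is cross-checked against an
independent one. Negative branch-length estimates (possible on non-additive
input) are clamped to zero with the total deficit attached to the tree.
Bootstrap support resamples alignment columns with replacement, rebuilds
K2P + NJ per replicate, and scores each internal edge by the percentage of
completed replicates containing the same bipartition; replicates in which
any pair saturates are skipped and excluded from the denominator. The
bootstrap requires equal-length input and refuses otherwise (no silent
internal alignment). Trees are `ape` `phylo` objects; Newick output writes
branch lengths to 6 decimals with supports as internal node labels.

# OTU clustering and assignment

Community uniques, pooled across samples with per-sample counts, are
clustered greedily at a 97% radius in abundance order. Uniques below
abundance 2 never seed an OTU but still map onto existing ones —
singletons are overwhelmingly error reads, and letting them seed inflates
richness; chimera-flagged uniques are dropped entirely. Both parameters
follow the conventions of the pipeline this re-implements and are
configurable.

Assignment is best-hit by identity (ties: longer alignment, then
lexicographic reference id) with the operational species-level rule:
identity strictly greater than 95% *and* alignment length strictly greater
than 100 bp. Boundary cases — exactly 95.0% identity, exactly 100 aligned
bases — are not assigned. An OTU that misses the rule keeps its best hit
but is reported unassigned at species rank. The two-database comparison
classes every OTU as species-assigned by both databases, one, or neither,
and records species agreement within the "both" class.

# Concordance reporting

Species are binned by detection frequency: abundant (> 1/2 of samples),
moderate (> 1/3), rare (the rest). The two bounds are strict and leave
exactly 1/3 ambiguous between the published "> 1/3" and "< 1/3"; it is
assigned to *rare*. Species names are matched after whitespace and case
normalization, with an optional synonym map — misspellings across
morphology tables and sequence headers are a real hazard. The per-sample
species-count concordance is ordinary least squares of metabarcoding counts
on morphology counts, with R² the squared Pearson correlation and the
two-sided t-test on the slope.

# The synthetic-data generator

The generator produces every fixture the pipeline needs, as a pure
function of its configuration and seed:

* **Barcodes** are built codon-by-codon from the non-stop codons of
  table 5, default length 313 bp (the fragment the primer pair brackets).
  Species radiate from a common ancestor and are rejection-sampled until
  all pairwise K2P distances reach the configured floor (default 0.10);
  conspecific specimen variants are placed so pairwise intraspecific
  divergence lands near its target (default 0.02). Mutations are
  transition-biased 50/50 and never introduce an internal frame-0 stop.
* **Specimen read sets** flank the barcode with the degenerate primers
  (each degenerate position instantiated uniformly from its IUPAC set, as
  in a synthesized oligo pool), apply uniform per-base substitution error
  (default 1%), emit half the reads reverse-complemented, and add two
  contaminant classes: whole reads from bacterial-like coding decoys
  (default 10%) and single-crossover chimeras of the barcode and a decoy
  (default 5%). The crossover is drawn uniformly over the central 25–75%
  of the insert so each parent contributes a resolvable anchor segment;
  crossovers hard against an end are biologically possible but
  operationally indistinguishable from point noise, and modeling them
  would only blur ground truth. Qualities are constant Q30 unless an error
  profile is supplied.
* **Communities** draw a per-species occupancy frequency uniformly on
  [0.15, 0.95], Bernoulli presence per sample, symmetric-Dirichlet
  relative abundances among present species, and multinomial read counts
  (default 12 samples × 600 reads). The presence truth table doubles as
  the synthetic morphology survey for the concordance module.

The error model is substitution-only by default, which keeps truth
alignment trivial; `homopolymer_indel_rate` optionally adds one-base
expansions/contractions of homopolymer runs (the dominant indel mode of
semiconductor chemistries) for harder fixtures. What the generator does
*not* emulate — and therefore what passing tests do not demonstrate about
field data: realistic flowgram noise, PCR abundance bias and copy-number
variation, primer-template mismatch dropout, multi-individual wells, and
real taxonomic misidentification. The simulated regime is the
intended operating envelope of the method, not a stress model of its
instrument.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one core while still
exercising every failure mode: 200 simulated specimens (20 species × 10) at
100–1000 reads each for recovery; 100 random 4–12-taxon trees for NJ
exactness; 10-species × 12-sample communities at 600 reads per sample for
the end-to-end check; 1000 bootstrap replicates by default (tests use
50–200). Scores in the aligner are integers, so alignment results carry no
floating-point ambiguity; distance ties in clustering, assignment and NJ
all have documented deterministic tie-breaks; every stochastic function
requires an explicit seed and restores the RNG state afterwards.

# Known limitations

* Recovery assumes one individual per well; mixed wells yield either a
  flagged recovery or a failure record, not a deconvolution.
* The stop-codon screen catches frame-shifted pseudogenes but not
  stop-free ones; those require the divergence audits to surface.
* The chimera detector cannot call chimeras whose parent sequence never
  reaches the abundance floor in the read set (see above).
* Saturated K2P pairs propagate as exclusions, not imputations; a database
  divergent enough to saturate routinely needs a different distance model
  than the one this package implements.
* Bootstrap support requires equal-length barcodes; mixed-length databases
  must be trimmed or aligned externally first.
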