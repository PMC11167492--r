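---
title: "Predicting TF binding motifs from protein-DNA complex structures"
author: "StructMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF binding motifs from protein-DNA complex structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StructMotif)
```

## The problem

The binding preference of a transcription factor (TF) is usually
summarized as a position weight matrix (PWM): per-position nucleotide
probabilities over its binding site. Measuring PWMs experimentally
(protein-binding microarrays, SELEX variants, ChIP methods) is
laborious, and a substantial fraction of eukaryotic TFs still has no
measured motif. When the structure of a TF bound to DNA is available
(or can be modelled), the physics of the interface constrains which DNA
sequences the protein can read out. StructMotif turns that constraint
into a predictor: it learns knowledge-based statistical potentials from
the contacts observed in TF-DNA structures, optionally enriched with
high-throughput protein-binding-microarray (PBM) data, and scores every
candidate binding sequence of a complex to derive a PWM. Downstream it
provides the machinery such a predictor needs to be evaluated and used:
motif-motif comparison with an empirical null, rank-based benchmarks,
a nearest-neighbor baseline, exact-p-value PWM scanning along DNA, and
a binned majority-vote binding-site caller for ensembles of predicted
motifs.

## The contact model

A contact joins one amino acid with one *dinucleotide step*: two
contiguous nucleotides of the leading strand together with their
complementary bases. Its distance is measured from the residue's
C&beta; atom to the unweighted mean of the nitrogen-base atoms of those
four nucleotides. Each contact carries five categorical environment
features:

* residue hydrophobicity class (nonpolar = {A,V,L,I,M,F,W,C,G,P},
  polar = the rest),
* secondary structure (helix / strand / coil),
* solvent exposure (buried / exposed, relative accessibility above a
  0.25 cutoff by default),
* the DNA groove (major / minor) of the base atom nearest to the
  C&beta;, and
* the strand side (leading / complementary) of that nearest atom.

Crossing the five features gives 2 x 3 x 2 x 2 x 2 = 48 environment
classes, and with 20 amino acids and 16 dinucleotides the potential
contact space holds 16 x 20 x 48 = 15 360 cells. The *contact
abundance score* log10(15360 / observed distinct triples) tracks how
much of this space a training set covers. The five-way factorization
is the minimal one consistent with the 48-class / 15 360-cell
bookkeeping used throughout, and the classifier is a single function
(`envClassId`) so an alternative factorization can be swapped in.

Structural annotations that pipelines in this field usually delegate
to external binaries (DSSP for secondary structure and accessibility)
are implemented in-package so everything runs self-contained:
secondary structure comes from backbone dihedrals (helix for
&phi; in [-120,-30], &psi; in [-80,-5]; strand for extended &phi;/&psi;
with minimum run lengths 3 and 2, mirroring the usual collapse of the
eight DSSP states onto three), and solvent accessibility from a
Shrake-Rupley rolling-probe construction (92 sphere points, 1.4 A
probe) normalized by Gly-X-Gly maxima. Glycine gets a virtual C&beta;
from ideal tetrahedral backbone geometry. The relative-accessibility
cutoff and the dihedral windows are exposed as arguments because no
single standard value fixes them.

## From counts to potentials

Counts are binned by distance at 1 A resolution up to a radius of 15,
22 or 30 A, either as intervals (x-1 < d <= x) or cumulatively
(d <= x; the cumulative count at x equals the interval bins summed to
x, which is asserted as an invariant). The score of a cell
(a = amino acid, b = dinucleotide, e = environment; bin x) is the
negative log odds of its pseudocounted frequency within the bin against
the product of the amino-acid marginal and the (dinucleotide,
environment) marginal, with pseudocount kappa = 0.1 and the class-space
size K = 15 360 backing the denominator. Lower scores are more
favorable. Knowledge-based split potentials form a whole family of
closely related functional forms; the log-odds form here is
deliberately kept behind one builder function so alternates can be
swapped without touching the downstream contract, which only consumes
the Z-transform.

That Z-transform compares the score of the observed amino acid against
all 20 substitutions at the same (dinucleotide, environment, bin):
Z = (S(a) - mean) / sd with the population standard deviation, and
Z = 0 when the substitutions do not differ. Summing per-contact
Z-scores over an interface gives the complex score used everywhere
downstream (the ES3DC-style raw sum is also reported). A property
worth knowing: when counts exist only in a single (b, e, x) cell, the
amino-acid marginal exactly cancels the cell counts and the potential
is flat there — discrimination requires counts spread over more than
one cell, which any realistic training table has.

Sparse distance profiles can be completed with a polynomial smoother
("Taylor" option): for each (a, b, e) profile, unobserved bins lying
between observed ones are imputed from a degree <= 2 polynomial fit of
log counts versus distance, the degree chosen by BIC, with observed
bins never overwritten. Redundancy among training TFs is controlled by
greedy filtering on contact fingerprints (the sets of nonzero cells):
TFs are visited in order of descending total contacts and dropped when
their fraction of identical contacts with an already-kept TF — the
intersection over the smaller fingerprint — exceeds 0.70
(family-specific) or 0.40 (general), the low ends of the 70-80% and
40-50% working ranges these potentials are built with.

PBM data extend the structural counts: 8-mers with E-score > 0.45 are
positives, < 0.37 negatives, the band between is discarded. Positive
8-mers are placed on the template binding site by their best ungapped
alignment against the TF's PWM (both strands; placements below the
median log-likelihood of random 8-mers are rejected — the median
floor is this package's own choice of noise gate, since unfiltered
placements would inject arbitrary dinucleotides). The template's
contacts are then re-emitted with substituted dinucleotides, and
transferred onto homologous TFs through a global protein alignment
(BLOSUM62, gap open 10 / extend 0.5); homologs with an alignment gap
inside the interface are rejected outright.

## Predicting a PWM

The binding site of a complex spans the contacted dinucleotide steps;
its length L in nucleotides is the contacted span plus one (a site of
L nucleotides has L-1 steps, so a one-step site enumerates 16
sequences). Every candidate sequence is scored by the summed
per-contact Z with its dinucleotides substituted step by step. Because
that score decomposes over adjacent steps, the search space is a chain
of 16-state nodes with overlap-consistency edges, and an exact top-K
dynamic programming (`dp_topk`) makes heuristic search unnecessary;
with K = 4^L it provably reproduces exhaustive
enumeration, which the test suite asserts on random potentials up to
L = 8. Scores are min-max normalized with 1 = best (if every sequence
ties, all are assigned 1 so that threshold selection stays meaningful);
sequences at or above a threshold in [0.7, 1] are selected, and the
PWM is their per-position base frequency with a 0.01 pseudocount per
cell.

Six parameters are tuned per TF family by grid search: binning
(interval/cumulative), smoothing (on/off), contacts database
(structures only / PBM-extended), scope (family/general), radius
(15/22/30 A) and the selection threshold (0.70..1.00 step 0.01) —
1488 grid points, selected by (i) most significant predictions,
(ii) best mean similarity score among counts within 1 of the maximum,
(iii) lowest threshold. The shipped per-family defaults are in
`inst/extdata/family_params.yaml` and are returned by
`familyDefaults()`.

## Comparison, ranking, scanning

Two PWMs are compared by their optimal ungapped alignment over all
offsets with at least 4 overlapping columns and both orientations,
column similarity being the Pearson correlation of probability
4-vectors. The p-value is empirical: the fraction of random motifs of
the query's width — columns resampled from a Dirichlet fitted to the
target database by moments — that align at least as well, with the
+1/(n+1) correction; the similarity score is -log10(p). This replaces
the exact null of the TOMTOM comparison tool with a resampled null
carrying the same contract; p-values are checked for approximate
uniformity under the null (Kolmogorov-Smirnov distance below 0.15 at
the test's null sample sizes).

Prediction quality is evaluated by ranking the true motif among all
database motifs: normalized score = 100 (M - rank + 1) / M, null when
the true-motif comparison is not significant at 0.05. The
*rank-enrichment* rule aggregates an ensemble of predicted PWMs by
majority vote: each prediction contributes its top-10 significant
matches, the motif selected most often wins (ties by higher mean
similarity, then lexical id), and a true motif absent from every top
list voids coverage. The nearest-neighbor baseline assigns the motif
of the most sequence-similar TF, with identity bins centered on
15..95% in 10% steps (the 95% bin holds relatives at 90-100%).

Scanning uses log2 odds against the background with an exact p-value:
the discrete distribution of PWM scores under the background is built
by dynamic programming with the score range discretized into 1000
steps, so p-values agree with brute-force enumeration of all words to
within the discretization (asserted for widths <= 6; the observed
maximum absolute error is about 0.016). N bases contribute zero
log-odds. For binding-site calling over a 420-nt window, the window
is cut into 21 bins of 20 nt (bin b covers positions
[20(b-1)+1, 20b]; bin 11 = 201-220 holds the central site); each PWM
of an ensemble contributes once, in the bin overlapping most of its
best hit (ties to the lower bin), bins achieving the maximal count are
the positive calls, and a positive middle bin is the one true
positive. ROC curves over a p-value sweep are averaged across
experiments with standard error sd/sqrt(N).

## What the synthetic data emulate — and what they do not

The fixture generator builds everything the tests consume:

* **Toy complexes** — an ideal B-form duplex (rise 3.4 A, twist 36
  degrees) with simplified nucleotides whose base atoms carry the
  canonical major/minor groove partition, plus protein residues placed
  so each planted contact's C&beta;-centroid distance is exact to
  0.01 A, and optional ideal helical/extended segments for the
  secondary-structure contract. Geometry satisfies the contact
  definition; it is not physically realistic (no sterics, no base
  pairing energetics, simplified backbone).
* **Planted-preference tables** — every extracted contact contributes
  counts for all 16 dinucleotides, with the dinucleotide dictated by a
  planted consensus enriched 5-fold. A potential trained on such a
  table must rank the planted dinucleotide best at every step, and the
  closed-loop test (complex -> table -> potential -> scored sequences
  -> PWM) must recover the planted consensus exactly.
* **A synthetic TF family** for the 8-mer benchmark: 12 TFs sharing
  one planted preference, contacting the same eight positions through
  the same amino acid per step but at TF-specific distances, so
  fingerprints differ while the pooled potential carries the family
  signal. Positives are the consensus and four single-base mutants;
  negatives are drawn at ratio 1/100 with G+C matched to the
  positives; 10 repeats, 5-fold cross-validation over TFs with the
  0.70 redundancy rule between train and test. Because summed
  Z-scores of different TFs are on different scales, ROC/PR areas are
  computed per test TF and averaged — pooling raw scores across TFs
  would measure calibration rather than discrimination.
* **PBM tables** with planted positives (E in (0.455, 0.50)),
  negatives (E in (-0.50, 0.36)) and an optional discarded band, so
  the E-score filter recovers the partition exactly.
* **Motif databases** with Dirichlet-sampled columns and an optional
  embedded motif.

Passing these tests shows the machinery is self-consistent and
recovers planted signal under its own model assumptions. It does not
show performance on real structures: real interfaces have correlated
contacts, non-B DNA, crystallographic noise and family idiosyncrasies
that the fixtures deliberately omit; benchmarking against the real
repositories (structure and motif databases, PBM collections,
ChIP-exo compendia) requires downloads and is out of scope here.

## Numerical choices and problem sizes

* Pseudocount kappa = 0.1; PWM cell pseudocount 0.01; placement floor
  from 10 000 sampled 8-mers under a fixed internal seed.
* dp_topk tie-break: sequences ordered by score, then alphabetically,
  making the ranking fully deterministic and identical to exhaustive
  enumeration's ordering.
* Motif-comparison ties: smaller |offset|, then the + orientation.
  Constant PWM columns correlate 0 with everything.
* Degenerate inputs: an all-tie score set normalizes to all-1; an
  empty contact list scores 0; an empty selection raises "threshold
  too high"; empty tables refuse to build a potential.
* Test-suite problem sizes are chosen for a laptop-scale run: oracle
  equivalences use sites up to L = 8 (65 536 sequences) and scanner
  widths up to 6 (4096 words); the benchmark family holds 12 TFs with
  505 scored 8-mers per TF and repeat. The acceptance script repeats
  the same computations at the same sizes from a fresh seed.

## Known limitations

* The potential's functional form is one member of the family of
  split knowledge-based potentials; the Z-transform contract is what
  is tested, and the form is swappable behind the builder.
* Homology modelling of TF structures, DNA conformation modelling and
  macro-complex assembly are out of scope; contacts are transferred
  symbolically for PBM extension.
* The comparison null is resampled, not exact; its p-values are
  calibrated only approximately (see the uniformity test).
* The secondary-structure assigner is dihedral-based and intentionally
  simple; it matches DSSP's three-state collapse on ideal geometry but
  will differ on distorted real chains.
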