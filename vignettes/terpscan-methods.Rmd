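---
title: "terpscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{terpscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the profile model and its scoring, the decision procedure, the
statistics, what the synthetic generator does and does not emulate, and
the choices made where the design was genuinely open.

## The classification problem

Terpene synthase (TPS) sub-families — mono-, di- and sesquiterpene
synthases, or the homology clades TPSa–TPSg — share a common terpene
fold and extensive sequence homology. A single sub-family profile HMM
is therefore a near-perfect *detector* (it finds essentially every true
member) but a poor *classifier*: it also scores members of sibling
sub-families well enough to pass any sensible significance threshold.
terpscan's core procedure is to scan a query with every profile of a
bank in parallel and assign the sub-family of the highest-scoring
profile. The assignment premise is that the self profile outscores the
eleven non-self profiles; on the package's synthetic conditions the
self-versus-best-other margin is hundreds of bits, so the argmax is
stable.

Three schemes are scanned independently (a query legitimately receives
both a function-based and a gene-family call): FB with six profiles
(MonoD, MonoM, DiD, DiM, SesD, SesM), GB with six (TPSa, TPSb, TPSc,
TPSd, TPSe_f, TPSg) and PT with one — thirteen profiles in the default
configuration.

## Profile construction

**Match columns.** A column of the family alignment becomes a match
state iff its gap fraction is strictly below `gap_threshold`
(default 0.5). Deterministic; an error is raised if nothing survives.

**Henikoff position-based weights.** In each match column with $r$
distinct residue types, a row holding a residue shared by $s$ rows
receives $1/(rs)$; gaps contribute nothing, all-gap columns are skipped
(avoids 0/0), and per-row sums are normalised to the row count so the
effective number of sequences is conserved. This down-weights redundant
rows; duplicating a row never increases anyone else's share.

**Emissions and transitions.** Match emissions are weighted residue
counts with an additive (Laplace) pseudocount, default 1.0:
$e_j(a) = (c_j(a) + \kappa)/(C_j + 20\kappa)$. Dirichlet-mixture priors
would be sharper but are harder to verify by hand; additive smoothing is
simple, strictly positive and configurable. Insert states emit the
background. M→{M,I,D}, I→{M,I} and D→{M,D} transitions are estimated
from the weighted observed events with the same pseudocount; the
non-standard D→I and I→D events are not part of the state graph and are
skipped. The background is the weighted pooled residue frequency of the
alignment, smoothed identically.

## Scoring

Scores are local ("Smith–Waterman-like") single-hit Viterbi bit scores:
$S = \log_2 [P(\text{path}, x \mid \text{profile}) / P(x \mid
\text{background})]$, with uniform entry into any match state (cost
$\log_2(1/L)$), free exit from any match state, and flanking residues
cancelling against the null. Multi-hit (J-state) parsing and
forward/posterior decoding are out of scope: family assignment needs a
single best local alignment, and the single-hit model keeps the
exhaustive path-enumeration oracle used in the tests tractable.
Ambiguity codes X/B/Z emit the background (log-odds 0), so they neither
help nor hurt a hit. Ties on bit score are broken by lexicographic
family name — documented, deterministic, and exercised by the tests.

The dynamic program is implemented in C++ (Rcpp). One numerical detail:
the unreachable-cell sentinel is a large finite value (−10^300) rather
than IEEE −Inf, because infinity propagation in the inner loop costs an
order of magnitude in throughput; the two are equivalent for every
reachable path.

**E-values.** Each profile is calibrated by scoring `n_samples = 200`
i.i.d. background sequences of length 350 (seed 42 by default, recorded
in the profile file) and fitting a Gumbel law by maximum likelihood
($\lambda$ via the profile-likelihood root, $\mu$ in closed form). Then
$E = n \, (1 - \exp(-\exp(-\lambda (S - \mu))))$, with $n$ the scanned
set size (database-size semantics). Protein-path reporting uses a
permissive E ≤ 10 (assignment itself is argmax among reported hits);
the EST path applies the stricter filter E ≤ 0.01, Bonferroni-scaled by
the number of candidate peptides of the query. A 350-residue
calibration length is conservative for the short ORF fragments of the
EST path — shorter random sequences score lower, so their true
false-positive rate is below the nominal one.

## EST handling

Nucleotide input is translated in all six frames (standard genetic code
by default, configurable by NCBI table number; N-containing codons
become X), each frame is split at stop codons, and segments of at least
50 aa are scanned. Fifty residues is far below the shortest genuine
TPS (~550 aa), so no true hit is lost, while stop-broken random
translations rarely reach the threshold. Coordinates of the winning
peptide (frame, amino-acid offset) are reported.

## Diterpene-synthase motif classes

Class I catalysis (ionization) is marked by the aspartate-rich DDxxD/E
motif or the NSE/DTE consensus (N,D) D (L,I,V) x (S,T) x x x E; class II
(protonation-initiated cyclization) by DxDD. Presence of class I
evidence only → ClassI; class II only → ClassII; both → Bifunctional;
neither → Noncanonical. Bifunctional takes precedence so the four
classes partition the sequence space. All (possibly overlapping)
occurrences are reported; classification uses presence only. `X` never
satisfies a constrained position — a conservative rule that prevents
low-quality translations from generating spurious class I calls. The
whole sequence is scanned (no domain-architecture constraint is
applied).

## Benchmarking

Sensitivity is TP/(TP+FN). "Accuracy" is implemented as the positive
predictive value TP/(TP+FP): only this reading explains accuracy rising
to ~100% when argmax assignment eliminates cross-family false
positives while sensitivity stays at 100%. In `single` mode every
profile independently calls any sequence passing E ≤ 0.01; in
`combined` mode each sequence is assigned exactly its argmax family
(provided the top hit passes). The stratified splitter holds out
`ceiling(0.1 n)` per family, disjoint and deterministic given the seed.

## The synthetic generator

The generator produces the statistical structure the classifier
assumes, not biological sequences:

* a single deterministic *fold backbone* shared by the 12 TPS families
  (PT has its own) — this is what makes single-profile mode imprecise,
  as in real TPS data;
* three family-specific 24-residue conserved blocks per family
  (substitution rate 0.02) — what the argmax keys on;
* class signature motifs embedded near the C-terminal end: both class I
  and class II at fidelity 1 for the diterpene-length families (DiD,
  DiM), DxDD only for TPSc (CPS-like), aspartate-rich only for TPSe_f
  (KSL-like), and an aspartate-rich motif at fidelity 0.9 elsewhere
  (PT none);
* lengths drawn once per family from the family-biology ranges
  (DiTPS 850–900, MonoTPS 600–650, SesTPS 550–580, PT 300–400 aa), so
  members form a valid un-gapped alignment and no aligner is needed
  (a single draw per family is the deliberate resolution of "uniform
  lengths" versus "un-gapped alignment");
* divergence 0.25 outside blocks, substituted residues redrawn from
  typical globular-protein background frequencies excluding the
  consensus residue (the realised rate is exact); the background
  frequencies also drive negatives and calibration, so motif false
  positives occur at realistic rates;
* negatives are pure-background sequences added to the test set only.

Default divergence 0.25 places the benchmark in the regime where
single-profile mode produces abundant cross-family false positives
while argmax mode stays perfect — both regimes the benchmark module
must demonstrate. What the generator does **not** emulate: phylogenetic
correlation (no tree-based evolution), indel processes within families,
codon-usage bias in EST encodings, and realistic negative sets of
*related* non-TPS enzymes. Passing tests therefore show the decision
procedure is correct under the assumed structure, not that real-genome
accuracy equals the synthetic one.

## Genomic clustering

Loci use 0-based half-open coordinates everywhere; GFF3 is converted at
the boundary (one convention prevents off-by-one drift). Two family
genes join a cluster when they share a chromosome, their start-to-start
distance is ≤ 100 kb and, when a gene universe is supplied, at most 5
non-family genes intervene; clusters are maximal runs of size ≥ 2.
Neither knob has a canonical published value; both are exposed and
recorded in the output. Start-to-start distance is robust to annotation
length noise.

Significance: the observed nearest-neighbour start distances are
compared with distances pooled from 100 uniform random placements of
the same per-chromosome counts, by a one-sided Welch t-test on
$\log_{10}(d+1)$. The log scale matters: nearest-neighbour distances
are near-exponential with a heavy tail, and on the raw scale the mean
difference is variance-dominated (the test has little power even on
strongly clustered genomes); after the log transform both samples are
near-symmetric and the test is well calibrated (uniform genomes exceed
p = 0.01 in ≈ 98% of runs) and powerful (strongly clustered genomes
reach p < 0.01 essentially always). Default α = 0.01 — the 99%
confidence level. The test sizes used throughout (5 × 30-Mb
chromosomes, 60 genes, 100 placements) are the package defaults.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full default
conditions: 13 families × 30 sequences, 10% held out, 200-sample
calibration per profile, 100 random-EST controls, 70 simulated genomes.
Every stochastic step takes an explicit seed; generation, calibration,
splitting and placement restore the caller's RNG state, and fixed
internal seeds make the default family specifications (backbone and
block peptides) identical in every session, which is what makes banks
reproducible across machines.

## Known limitations

* Single-hit local alignment only: a query containing two family
  domains reports the better one.
* Additive pseudocounts flatten emission estimates for very small
  families; 10+ rows are recommended.
* The Gumbel fit uses 200 calibration samples by default; E-values
  below ~1e-3 are extrapolations of the fitted tail.
* The cluster rule ignores strand and intergenic orientation, and the
  significance test conditions on per-chromosome gene counts.
* The four-way motif classes are presence tests; they do not validate
  the structural context of a motif hit.
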