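---
title: "famforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famforge re-implements, as one tested toolkit, the computational workflow
used for genome-wide characterization of plant gene families such as the
F-box superfamily: discover the family in a proteome by iterative profile
search, characterize its conserved domain and C-terminal architectures,
analyze duplicate-gene evolution (tandem placement, Ka/Ks selection),
pair orthologs across species, screen expression patterns, and score
disease phenotypes. This vignette records the models, the tunable
parameters, and the design decisions taken where the published workflow
left the design open.

## 1. Family discovery by iterative profile search

**Model.** A family is found by scanning every protein with a
position-specific scoring matrix (PSSM) built from a seed-domain
alignment, then iterating PSI-BLAST-style: hits below the inclusion
E-value contribute their matched segments to a rebuilt PSSM, and the
proteome is rescanned until membership stops growing or `max_iter` (10,
the published setting) is reached. Membership is monotone by
construction: a protein once included is never dropped, which also makes
convergence within `max_iter` well-defined.

**PSSM.** Column log-odds are `log2((f + w·bg) / ((1 + w)·bg))` with `f`
the observed non-gap residue frequency, `bg` a fixed Robinson–Robinson
background shipped with the package, and `w` a fixed pseudocount weight
(default 0.5). Scores are stored in bits; `-Inf` (unseen residue at
`w = 0`) is capped at -8 bits — equivalently -16 half-bits — which keeps
the dynamic programming finite without affecting optima in practice.
Columns that are majority-gap (> 50%) are dropped. The X wildcard scores
0 everywhere.

**Alignment engines.** All scanning uses exhaustive affine-gap dynamic
programming (Rcpp): Smith–Waterman for sequence pairs, a profile variant
for PSSM-to-sequence scans (gap penalties 5.5/0.5 bits, mirroring the
BLOSUM62 11/1 half-bit convention). There are no word-hit heuristics;
at desk scale exhaustive DP is fast and exactly testable against
brute-force oracles.

**E-values.** Because profile scores are gapped, Karlin–Altschul theory
does not apply directly; instead each profile is calibrated empirically:
200 background sequences of length 400 are scored, a Gumbel law is
fitted by moments (`lambda = pi/(sd·sqrt 6)`, `mu = mean − gamma/lambda`),
and `E = db_size · (n/L0) · exp(−lambda·(S − mu))` — algebraically the
familiar `K·m·n·exp(−lambda·S)`. The calibration null uses a fixed
internal seed so scans are deterministic. With the published thresholds
(`evalue = inclusion = 1e-2`) false positives on a 500-protein background
are rare (the expectation is ~0.01 per scan), which is what keeps
iterative expansion from hijacking.

**What the synthetic world establishes.** The generator plants mutated
copies of a known domain consensus at recorded offsets; divergence tiers
(e.g. 0.8 → 0.6 → 0.35 identity, each tier derived from a member of the
previous one, as in a real family radiation) create members invisible to
the seed scan but reachable through iteration — the property the
published workflow exploits when PSI-BLAST finds ~26% more members than
a single HMM pass. A green test shows the engine recovers planted
structure (recall and precision ≥ 0.9 at these divergences); it does not
certify sensitivity on real Pfam-scale families, profile-HMM local/glocal
subtleties, or compositional bias corrections, none of which are modeled.

## 2. Redundancy removal and duplicate genes

CD-HIT-style greedy clustering: sequences processed longest-first (ties
broken lexicographically by id, so results are input-order independent),
each joining the first cluster whose representative identity meets the
threshold — 0.8 for domain-segment redundancy removal, 0.9 for
duplicate-gene grouping, both inclusive at the boundary. Identity is
identical aligned residues over the shorter sequence length from a
global alignment (the CD-HIT convention). Clusters of size ≥ 2 are
duplicate groups; the duplicate fraction is reported as a percentage
rounded to two decimals (61 of 389 → 15.68).

Tandem classification follows the 200-kb rule: a pair is tandem iff both
genes share a chromosome and their start coordinates lie at most
`max_gap = 200000` bp apart (inclusive). The anchor point (starts rather
than midpoints or inter-gene gap) is a package decision — the rule's
published form names no anchor — and the synthetic generator plants
pairs at exactly 200,000 and 200,001 bp so the boundary is always
exercised.

## 3. Ka/Ks (Nei–Gojobori 1986)

Site counts: per codon and position, the fraction of the three possible
changes that are synonymous; mutations creating stop codons count as
nonsynonymous (the original NG86 convention — this is what makes the
three-codon worked example give `S = 5/3`, `N = 22/3`). `S` and `N`
average the two sequences. Difference counts weight all shortest
mutational pathways equally, excluding pathways through stop codons
(falling back to unrestricted pathways only if every pathway is
blocked). Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)p)` yields Ka
and Ks. Flags: `undefined` for 0/0 (identical sequences) or `p ≥ 3/4`;
`infinite` for `Ks = 0, Ka > 0`; flagged pairs are excluded from summary
means. Codon alignments are obtained by back-translating a global
protein alignment; gapped codon columns are excluded; one terminal stop
codon is tolerated and stripped.

The synthetic duplicate generator evolves one copy of each pair by
accept/reject point mutation: uniform site and nucleotide proposals,
stop codons rejected, nonsynonymous changes accepted with relative
probability omega (for omega > 1, synonymous changes accepted with
probability 1/omega). This is deliberately not a full M0 codon model:
truth omega is approximate but controllable, and NG86's uniform-
substitution assumption matches the proposal process, so estimator
recovery (omega ∈ {0.2, 1, 2} within ±0.15·omega + 0.05) is a fair test
of the counting, not of phylogenetic realism.

## 4. Alignment, conserved sites, architectures

Progressive alignment uses a 3-mer-distance UPGMA guide tree and
profile–profile Needleman–Wunsch with mean-of-pairs BLOSUM62 column
scores; gaps are linear at the residue–gap pair score (-8), which makes
each merge exactly optimal for the cross sum-of-pairs term. On 3-sequence
toys the result is within 5% of the exhaustive 3-way optimum.

Conserved sites report, per column, the two most abundant non-gap
residues (ties alphabetical). The percentage denominator is the *total*
row count including rows gapped at the column — the only convention that
reproduces 293/389 = 75.32%. Cross-species overlap — never operationally
defined in the published analysis, and flagged here as not reproducible —
is defined as: columns where the top-2 residue sets of all species share
at least one residue, over columns conserved in at least one species.
Residue positions are reported in alignment-column coordinates (1-based),
since the published residue numbering convention is unstated.

C-terminal architecture annotation scans the region downstream of the
family domain with each model profile in a user-supplied (or synthetic)
library; hits at `E ≤ 1e-2` are resolved greedily by score, then leftmost
position, then name, into a non-overlapping set, giving labels like
`F-box+Kelch` — or `FBXU` exactly when no hit survives. The census counts
a protein once per distinct domain type.

## 5. Expression screening

Normalization is median-of-ratios: geometric-mean pseudo-reference over
samples, per-sample size factor = median ratio over genes positive in
every sample. One subtlety is recorded in the tests: scaling one of `m`
samples by `c` multiplies the *entire* normalized matrix by the nuisance
factor `c^(1/m)` — this is intrinsic to every geometric-mean-reference
estimator (DESeq2 included), so the scale-invariance test asserts exact
equality up to that factor, plus exact invariance of size-factor ratios
among unscaled samples.

Clustering is agglomerative complete linkage on Euclidean distances, cut
into exactly `k` clusters (default 10, the published cluster count).
Rows are z-scored on `log2(x+1)` first (disable with `scale_rows =
FALSE`), because the published analysis clusters expression *patterns* —
shape, not magnitude. Per-cluster mean profiles are the "expression
model" of each cluster. Expression breadth uses three parameters the
published analysis left unstated, exposed as arguments rather than
claims: expressed threshold 1 normalized count, ubiquitous fraction 1.0,
and tau ≥ 0.85 for tissue specificity (`tau = sum(1 − x/max x)/(n−1)`);
a gene expressed everywhere but with tau above the cutoff is called
tissue-specific, not ubiquitous, since tau is the specificity statistic.
The published category counts (229 + 118 + 64 = 411 over 389 genes)
overlap or contain a discrepancy and are not reproduced; categories here
are disjoint with an explicit `intermediate` remainder.

qPCR fold changes follow 2^(−ΔΔCt) with replicate-mean Ct values,
reference-gene normalization per condition and a calibrator condition;
fold changes are invariant to shifting all Ct values.

**Synthetic counts.** Cluster archetypes are log-normal profiles
`2^(base + amplitude·z)` with `base ~ U(5, 7)` (log2 counts) and
`amplitude = 1` by default. The pattern matrix is projected (alternating
row-mean and per-sample column-median centering) so that the per-sample
median over clusters is zero: in that world "a typical gene is not
sample-biased", which is precisely the assumption median-of-ratios
needs; without it the size-factor criterion is unattainable no matter
how many genes are generated (the median sits in a density gap between
archetype atoms). The size-factor validation scenario therefore uses
many per-gene profiles (`k = n_genes`) at amplitude 0.5 — a continuous
ratio density — while cluster-recovery scenarios use `k = 10` shared
archetypes with a separation target that relaxes geometrically when `k`
patterns cannot be packed into the sample dimension. Dispersion is the
NB overdispersion (`var = mu + disp·mu²`), default 0.1; 0 gives
noise-free rounded means. The generator does not emulate library-size-
correlated composition bias, zero inflation, or gene length effects, so
green tests say nothing about those.

## 6. Phenotype scores

Morbidity = 100 · (plants with grade ≥ 1)/total. Disease index =
100 · Σ(grade · n_grade)/(4 · total): the denominator uses the scale
maximum 4, not the observed maximum, so an all-grade-4 table scores
exactly 100 — the only reading consistent with standard usage. Both are
monotone in any single plant's grade, invariant under duplicating the
table, and bounded in [0, 100].

## 7. Determinism and numerics

All generator randomness flows from one integer seed through named
sub-streams (a 31-bit hash of seed and stream name), so adding a
generator never perturbs existing streams; identical spec + seed gives
byte-identical output files. Tie-breaks are specified everywhere:
lexicographic ids after the primary key in scans and clustering,
smallest-index merges in agglomeration (ties have probability zero for
continuous data), alphabetical residue order at conserved-site count
ties, first-id wins for reciprocal-best-hit ties. Internal coordinates
are 0-based half-open throughout; GFF3 (1-based inclusive) and MSA
columns (1-based) are converted only at the boundary.

## 8. Known limitations

No profile-HMM forward/backward (the seed scan stands in for the HMM
stage); no BLAST word heuristics (desk-scale exhaustive DP only); no
synteny-block detection (inter-species collinearity is reduced to
reciprocal-best-hit counting); no tree inference; no read alignment or
quantification (counts are assumed given); the codon evolution process
is accept/reject, not a continuous-time codon model; Gumbel calibration
by moments is accurate in the tail only to the extent 200 shuffles
constrain it, which the inclusion threshold 1e-2 tolerates comfortably.
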