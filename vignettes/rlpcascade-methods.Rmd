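---
title: "The rlpcascade method: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rlpcascade method: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant receptor-like proteins (RLPs) share the single-pass membrane-receptor
architecture of receptor-like kinases (RLKs) — a signal peptide, an
N-terminal ectodomain, one transmembrane (TM) helix — but lack the conserved
cytoplasmic kinase domain. Because the kinase domain is exactly what
alignment-based searches key on, RLPs evade homology-driven genome surveys.
`rlpcascade` addresses this with a composition-based cascade: sequences are
described by residue-frequency encodings of their whole chain and of their
N- and C-terminal halves, and pushed through three classification stages
gated by membrane topology:

1. **RLP vs non-RLP (NRLP)** — is this a receptor-shaped protein at all?
2. **RLP vs RLK** — does it lack the kinase module?
3. **Subfamily** — which ectodomain family does it belong to?

The premise, inherited from the biology, is that RLP subfamilies carry the
same ectodomain signals as their RLK counterparts, so classifiers trained on
kinase-truncated RLK constructs transfer to RLPs.

## Feature encodings

Six fixed-dimension frequency encodings are computed per sequence:
amino acid composition (20), the same split over N/C-terminal halves (40),
dipeptide (400) and tripeptide (8000) overlapping k-mer frequencies, and the
frequency of side-chain chemical property groups, whole-sequence (9) and
split (18). K-mers slide with stride 1 and the denominator counts valid
windows only; `X` residues (and windows containing them) are excluded from
numerator and denominator alike, so unknown residues never bias a
composition. The N-terminal half receives the extra residue at odd lengths —
"equal or nearly equal" needs one fixed, testable rule.

The property-group table deserves a note: the literature names eight
property classes for nine features without printing the grouping itself.
The package ships an explicit default — positively/negatively charged, polar
uncharged, aromatic, nonpolar aliphatic, hydrophobic, large volume, large
mass, and the conformationally special residues {C, G, P} — chosen so the
dimensionality is exactly 9 with standard biochemical groupings. Groups may
overlap (e.g. F is aromatic, hydrophobic, large), so the 9-vector need not
sum to one. The whole table is an argument (`default_property_groups()`),
not a constant.

## Topology gating

Training positives must carry a signal peptide and exactly one TM segment —
the receptor architecture. At prediction time the rule is deliberately
asymmetric: **TM absence vetoes** an RLP call (a receptor cannot lack its
membrane anchor), but **SP absence does not** — known RLPs with unannotated
or absent signal peptides are still classified, only with lower decision
confidence.

Topology comes from external annotations (TSV re-expression of dedicated
predictor output) when supplied; absence of segments in an external
annotation is treated as information, never re-predicted. Otherwise built-in
hydropathy heuristics apply: a TM segment is a maximal region whose 19-residue
Kyte–Doolittle window mean exceeds 1.6, merged across gaps under 5 residues
and kept at ≥ 15 residues; a signal peptide is an 8-residue hydrophobic
window inside the first 30 positions ending before residue 35, with the
cleavage site at the first small residue (A/G/S) after it. These are
deliberately simple, deterministic stand-ins — production users should
supply real predictor output via `read_annotations()`; the heuristics keep
the cascade runnable with zero external binaries. All four thresholds are
config keys (`topology.window`, `topology.threshold`, `topology.min_tm_len`,
`topology.merge_gap`).

## Training-set design

Stage-1 positives are RLK sequences truncated immediately before the kinase
domain (ectodomain + TM + juxtamembrane). The negative pool is split into
three disjoint random subsets, each paired with the same positives — more
negatives are covered without inflating any single set. Stage 2 opposes the
truncated constructs to the full-length RLKs, so the discriminating signal
is precisely the kinase module. Stage 3 labels the constructs by subfamily
and draws ten datasets in which any class above 500 members is independently
down-sampled to 500. Crossing with the six encodings yields 18 + 6 + 60
training sets.

Redundancy removal is greedy longest-first clustering at 0.85 global-alignment
identity (matches / alignment columns; match 1, mismatch 0, gap open −10,
extend −1) — the exact-alignment equivalent of CD-HIT-style filtering, which
is idempotent and deterministic. In `train_cascade()` it is opt-in
(`redundancy_threshold = NULL` by default) because the synthetic generator
emits mutually non-redundant sequences and all-pairs alignment is an O(n²)
cost a default run does not need.

Class imbalance is handled by SMOTE: each minority class is raised to the
majority count with synthetic rows `x + u (x_nn − x)` interpolated toward
one of k = 5 nearest minority neighbors, original rows untouched. SMOTE is
applied after fold assignment and only to training folds — balancing before
splitting would leak interpolated copies of validation rows into training.

## Member models and selection

The registry holds eight member algorithms: AdaBoost (SAMME over depth-1
stumps), a Platt-calibrated discriminant classifier, gradient boosting,
k-nearest neighbors, linear and quadratic discriminant analysis,
cross-validated ridge logistic regression, and a small feed-forward network
(one hidden layer; no architecture is canonical for this problem, so size is
config). Constant feature columns are dropped before every fit; the
discriminant family additionally drops columns with zero pooled within-class
variance, and QDA reduces to a full-rank column subset because frequency
encodings carry exact linear dependencies (rows sum to one).

Per training set, every algorithm in the configured roster is
cross-validated and a champion is selected by MCC, ties broken by accuracy
and then fixed registry order. Two deliberate defaults:

* `select_folds = 3` for champion selection (ranking needs far fewer folds
  than unbiased estimation); `cross_validate()` itself defaults to the
  canonical 10 folds.
* the default roster is `lda` + `knn`, and encodings wider than 1000
  features use only neighbor-based members (`highdim_algorithms = "knn"`).
  At p ≫ n the discriminant and linear fits are rank-degenerate and
  expensive, while distance-based classification is exactly what k-mer
  encodings support well — consistent with neighbor methods dominating the
  high-dimensional encodings in this problem family. The full registry is
  one config key away.

Metrics are the standard confusion-matrix suite (ACC, F1, FDR, MCC,
precision, sensitivity, specificity), computed one-vs-rest and
macro-averaged for multiclass sets (`metrics.average = "micro"` pools counts
instead). Zero denominators yield 0 with a warning rather than NaN.

## Conjugate Bayesian ensemble

Member votes are combined by exact conjugacy rather than by majority:

* **Binary stages.** The n member votes are Bernoulli trials with success
  probability π; with a Beta(α₀, β₀) prior the posterior is
  Beta(α₀ + x, β₀ + n − x) and the reported stage probability is its mean
  (α₀ + x)/(α₀ + β₀ + n). Defaults α₀ = β₀ = 1 (uniform).
* **Subfamily stage.** The per-class vote totals are one multinomial draw;
  with a Dirichlet(1, …, 1) prior the posterior mean for class i is
  (1 + xᵢ)/(k + n).

The posteriors are available in closed form, so MCMC would add Monte-Carlo
noise without information; the test suite nevertheless checks the closed
forms against an independent random-walk Metropolis sampler run at 10,000
iterations with 2,000 burn-in, to 0.01.

The final rule: NRLP if the TM is absent or either binary stage posterior
falls below its cutoff (0.6); otherwise Undefined if the best subfamily
posterior mean is below its cutoff (0.7); otherwise the argmax subfamily.
Note an arithmetic consequence of the Dirichlet smoothing: with k = 16
classes the best posterior mean can only reach c₃ = 0.7 when the ensemble
has at least 34 members and at least ⌈0.7(k + n) − 1⌉ of them agree — with
the full 60-member stage-3 ensemble that is 53 concordant votes. Smaller
ensembles should lower `cutoffs.c3` accordingly; all three cutoffs are
config keys.

The scalar "decision probability" reported per sequence is the mean of a
Beta(½ + Σwᵢvᵢ, ½ + Σwᵢ(1 − vᵢ)) posterior over the five evidence bits
(SP, TM, stage-1 pass, stage-2 pass, subfamily pass) with unit weights. This
functional form is implementation-defined: it is monotone in every piece of
positive evidence and reproduces the qualitative ordering (≈ 0.92 with all
evidence, ≈ 0.75 with TM but no SP, low values as stages fail), and the
categorical classification never depends on it.

## The synthetic generator

`build_benchmark()` emulates the corpus structure the cascade assumes, with
one generative profile per subfamily: a residue distribution with a single
signature residue at frequency 0.3 over a uniform background, plus a short
class motif implanted with 10% per-position substitution. Signature residues
are the 16 canonical residues that are not strongly hydrophobic, so an
ectodomain never mimics a TM helix. Receptors are assembled as
SP block + ectodomain + 21-residue hydrophobic TM + (for RLKs) juxtamembrane
linker and a fixed 250-residue kinase-like consensus carrying canonical
kinase motifs at 10% substitution; RLPs get a short (≤ 30 residue) polar
tail instead. Non-receptor classes are globular (no SP/TM), secreted (SP
only), polytopic (3 TM), and uniform-random decoys.

Defaults: 20 receptors per subfamily per architecture — the smallest size at
which every named subfamily clears the scheme's default grouping threshold
(`min_members = 20`) — and non-receptor groups sized so the negative pool
supports three receptor-sized disjoint splits. Generation is a pure function
of (parameters, seed).

What the generator does *not* emulate: homology and indel evolution,
repeat-structured ectodomains (LRR periodicity), compositional drift across
species, or annotation noise. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and that the cascade recovers
known-by-construction signal — not that real proteomes are this separable.
With `signal = 0` all profiles collapse onto the same background and
subfamily separability vanishes, which the suite uses as a negative control
alongside label permutation.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; conversion happens only at
  slicing boundaries.
* Duplicate FASTA ids, illegal residues, inverted intervals, and
  single-member minority classes are hard errors; sequences too short to
  featurize at prediction time become NRLP rows with a warning (a sequence
  shorter than a k-mer window is a decoy by any reasonable definition).
* k-NN vote ties are resolved under a pinned RNG state (restored
  afterwards), so prediction is pure: identical inputs give byte-identical
  reports.
* Champion selection tie-breaks are total (MCC, then ACC, then registry
  order), making training deterministic given the seed.
* Fold assignment deals shuffled class members round-robin, so per-fold
  class counts differ by at most one.

## Problem sizes

The default synthetic conditions train 84 member models (18 + 6 + 60) on a
1,600-sequence corpus (640 receptors, 960 non-receptors) in a few minutes on
one core; the test suite uses a 10-per-class corpus and a three-encoding
bundle for the behavioral checks, and the full default conditions for the
random-sequence control.

## Known limitations

* The subfamily stage reports `Undefined` more often than a human annotator
  would like whenever the member ensemble is small or the class count high —
  a direct consequence of the (correct) Dirichlet smoothing; see the cutoff
  discussion above.
* The topology heuristics are hydropathy-only: they miss sequence-context
  signals real predictors model (positively charged n-regions, helix
  breakers) and will both over- and under-call TM segments on real
  proteomes. They exist to make the cascade self-contained, not to replace
  dedicated predictors.
* Training metrics on synthetic corpora are optimistic relative to real
  data by construction; the generator's separability dial controls the
  difficulty but not the realism.
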