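---
title: "Matrix relevance learning for early folding residues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix relevance learning for early folding residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvqfold)
```

## The classification model

`lvqfold` implements Generalized Matrix Learning Vector Quantization for a
two-class, heavily imbalanced problem: early folding residues (EFR, the
positive minority, ~15% of residues) versus late folding residues (LFR).
The model consists of K prototypes in standardized feature space, each
carrying a class label, and a linear mapping $\Omega \in \mathbb{R}^{M
\times D}$. Distances are measured after mapping,

$$d'(v, w) = \lVert \Omega (v - w) \rVert^2 = (v-w)^\top \Lambda (v-w),
\qquad \Lambda = \Omega^\top \Omega,$$

and a point takes the label of its nearest prototype. With one prototype
per class and a fixed (identity) mapping this is a linear classifier; with
matrix learning enabled the model additionally learns which features, and
which feature combinations, matter for the class distinction. $\Lambda$ is
the Classification Correlation Matrix (CCM): its diagonal is a per-feature
influence score and its off-diagonal entries score discriminative feature
pairings. Because $\Omega$ is renormalized to $\mathrm{trace}(\Lambda) = 1$
after every epoch, influences are nonnegative and sum to one, making
rankings comparable across runs.

### The soft objective

The classifier score of a labeled point is
$\mu(v) = (d^+ - d^-)/(d^+ + d^-) \in [-1, 1]$, negative exactly when the
point is correctly classified. The cited literature does not print the
transfer function, so the package uses the standard logistic form
$f_\sigma(x) = 1/(1 + e^{-\sigma x})$, and defines the *soft correctness*
$c(v) = f_\sigma(-\mu(v))$, which approaches the 0/1 correctness indicator
as $\sigma \to \infty$. Accumulating $c$ and $1-c$ into soft TP/FN (for
positives) and TN/FP (for negatives) gives a soft confusion matrix whose
marginals are exact by construction. Four objectives are computed from it:

| kind | definition | parameters (default) |
|------|-----------|----------------------|
| `CA` | $(tp + tn)/n$ | — |
| `WCA` | $w_+\, tp/n_+ + w_-\, tn/n_-$ | $w = (0.75, 0.25)$ |
| `F_BETA` | $(1+\beta^2)\,tp\,/\,((1+\beta^2)tp + \beta^2 fn + fp)$ | $\beta = 1$ |
| `PR_WEIGHTED` | $\gamma\, PR + (1-\gamma)\, RE$ | $\gamma = 0.5$ |

The weighted-accuracy weight of 0.75 sits on the positive-class recall
term: on imbalanced data this is the lever that trades precision for
recall. Undefined ratios (empty denominators) are defined as 0 and logged.

### Training

Training is gradient ascent on the chosen objective. Per epoch, a fraction
`data_ratio` of the training points is drawn without replacement, the exact
gradient of the objective with respect to all prototypes and $\Omega$ is
accumulated over that subset by the chain rule through $c(v)$, $\mu(v)$ and
$d'$, and one step is taken. Batch accumulation (rather than per-sample
updates) was chosen because weighted accuracy and $F_\beta$ are global
functionals of the confusion matrix with no clean per-sample decomposition;
plain accuracy decomposes, but using one update rule for all four
objectives keeps their comparison meaningful. The correctly-labeled nearest
prototype of each sampled point is attracted, the other-class nearest
prototype repulsed — the classic LVQ picture.

Defaults mirror the reference configuration of the residue study: 150
epochs, 1 prototype per class, data ratio 0.75, $\sigma$ annealed over
$[1, 50]$, unit base learning rates, $M = D$. Choices the source
material leaves open, fixed here once:

* **$\sigma$ annealing** is linear in the epoch index across
  `sigma_interval`. Low early $\sigma$ gives smooth, far-reaching
  gradients; high late $\sigma$ sharpens the objective toward the hard
  counts.
* **Learning rates** decay linearly to zero, $\eta_t = \eta_0 (1 -
  (t-1)/T)$. Whether the original implementation decays rates is unstated;
  decay bounds the late-training steps under the base rate of 1.0 and makes
  runs reproducible in practice.
* **Initialization**: prototypes start at their class mean plus seeded
  Gaussian jitter (sd 0.05 per standardized feature); $\Omega$ starts as a
  trace-normalized (truncated) identity. This is deterministic per seed and
  class-informed, avoiding empty-prototype pathologies.
* **Trace renormalization** happens after every epoch (not every update),
  which suffices to keep $\Lambda$'s scale fixed and its diagonal
  interpretable.
* **Tie-breaking**: equidistant prototypes resolve to the lowest prototype
  index; a prediction score of exactly 0.5 resolves to LATE, the majority
  class.
* **Standardization** (z-score with population sd) is fitted inside
  `gmlvq_train` and stored in the model; zero-variance features get divisor
  1 with a warning. In cross-validation this automatically restricts the
  standardization to the training split of each fold — a deliberate
  strictness that avoids information leakage.

A property worth knowing when reading trained models: the ascent
equilibrium of the soft objective does not sit exactly at the class means.
Boundary points carry the gradient weight $c(1-c)$, so prototypes settle
slightly boundary-ward — in standardized space the displacement is ~0.1
for well-separated classes. Tests therefore assert prototype positions in
standardized space, the space the model is defined in.

## The feature pipeline

The pipeline reproduces a 27-feature per-residue table. Energy-profile
columns (`e`, `ePred`) are consumed as external inputs — their computation
is a separate algorithm outside this package's scope; missing values are
imputed with the column mean and logged. Secondary structure comes from a
DSSP file (8-state collapsed to H/E/C), a plain annotation string, or a
dihedral-based fallback (helix: $\varphi \in [-80, -40]$, $\psi \in [-65,
-5]$ for at least 4 consecutive residues; strand: $\varphi \in [-150,
-90]$, $\psi \in [90, 180]$ for at least 2). `SecSize` counts the full run
containing the residue (the residue itself included — "number of neighbors
sharing the state" is ambiguous and the run length is the reproducible
reading). The loop fraction uses a 9-residue window normalized by the
positions actually present, so chain ends are not penalized.

Contacts come either from an external tab-separated contact list (the
fidelity path, standing in for a dedicated interaction profiler) or from a
simplified geometric detector: hydrogen bonds as N/O–N/O heavy-atom pairs
within 3.5 Å from non-adjacent residues (covalently adjacent pairs are
excluded because peptide-bond geometry would otherwise produce spurious
bonds), hydrophobic contacts as side-chain C–C pairs within 4.0 Å between
apolar residues. Detection is heavy-atom only; crystal structures rarely
carry hydrogens. Four graph representations are built (all contacts,
hydrogen bonds only, hydrophobic only, Cα distance ≤ 8 Å inclusive), each
including covalent edges between sequence-adjacent residues. Betweenness
(fractional credit across multiple shortest paths, normalized by
$n(n-1)/2$), closeness (inverse mean path length, over reachable nodes
only in disconnected graphs) and clustering coefficients are computed per
representation through igraph and verified in the test suite against an
exhaustive shortest-path enumeration oracle on hundreds of small random
graphs. Contact *counts* exclude covalent edges and split by kind,
backbone flag and sequence locality (local < 6 positions apart, long-range
> 5; cross-chain contacts count as long-range since sequence separation is
undefined across chains). The distinct neighborhood count merges a
residue's long-range partners into regions wherever consecutive partners
are ≤ 5 positions apart and counts the regions, over same-chain partners.

Solvent accessibility uses the Shrake–Rupley algorithm with a
deterministic golden-spiral point set (960 points; the 960 vs 3840
difference is below 2% on test fixtures), probe 1.4 Å, and van der Waals
radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å. Relative values divide by
theoretical extended-tripeptide maxima per amino acid; a different
reference table can be passed in. Note that these maxima are defined for a
residue flanked by glycines — a fully isolated residue computes RASA well
above 1, which is expected, and values above 1.2 trigger a logged warning.

Window averaging (±4 positions, truncated at termini, residue included)
runs before labeling; prolines participate in all structural computations
and in their neighbors' windows, and only their own labeled rows are
dropped (the underlying exchange experiment cannot annotate proline).

## The synthetic data generator

`gaussian_dataset` emulates the *statistical shape* of the residue dataset:
3266-row scale, 14.8% positive fraction (positives count =
`round(n * p)`), 27 columns named like the real table, a small informative
subset separated by a mean shift $\pm\delta/2$, optional within-class
correlations, Gaussian noise. It deliberately does **not** emulate spatial
autocorrelation along the sequence, the discrete/zero-inflated nature of
contact counts, or between-protein heterogeneity — so green tests on
synthetic data demonstrate the correctness of the estimator and pipeline
mechanics, not the attainable performance on real residues. `toy_structure`
generates ideal helices and strands from standard backbone internal
coordinates and a two-cluster Cα topology that guarantees long-range
contacts, which is what the structure pipeline tests run on.

## Problem sizes used in tests

The test and acceptance workloads were sized to what the properties need:
descriptor oracles on 200 random graphs of ≤ 7 nodes; parameter recovery
at n = 2000, D = 5; the imbalance comparison at n = 600, 5% positives,
over 10 seeds with 60 epochs; cross-validation demonstrations at
n = 120–1000. These sizes keep every property comfortably measurable.

## Known limitations

* The geometric contact detector is intentionally simple; ingesting a real
  interaction profiler's output is the higher-fidelity path and the two
  can disagree (e.g. no angular criteria for hydrogen bonds).
* The dihedral secondary-structure fallback handles ideal geometries well
  but is not a DSSP replacement (no hydrogen-bond pattern analysis).
* Closeness in strongly disconnected graphs (e.g. sparse hydrogen-bond
  graphs) averages over reachable nodes only; other conventions exist and
  yield different absolute values.
* Real-data performance claims require the original experimental
  annotations; the package ships only generators, not the dataset.
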