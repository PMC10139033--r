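---
title: "Decision analytics for a multi-stage virtual-screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision analytics for a multi-stage virtual-screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelscreen)
```

# The problem

Hierarchical virtual screening reduces a large compound library to a short
list of testable hits through a funnel of increasingly expensive stages:
a fingerprint-based QSAR regression, structure- and ligand-based rescoring,
consensus ranking, negative design (removal of assay-interference and
promiscuity liabilities), and finally molecular-dynamics stability
assessment of the survivors. The scientific content of such a campaign is
not the individual docking engines or force fields — those are external
tools — but the *decision machinery* around them: the statistics that
admit or reject a QSAR model, the enrichment analytics that validate a
scoring protocol, the normalisation that makes protocols commensurable,
the exclusion rules, and the trajectory descriptors that certify binding
stability. `funnelscreen` implements that machinery as a tested package,
exercised end to end on synthetic data whose ground truth is known by
construction.

# QSAR curation and features

Activity records arrive as IC50 values with qualifiers (`eq`, `gt`, `lt`).
Curation collapses exact duplicates per compound to their median (even
counts: mean of the central pair) and retains a qualified record only when
its inequality pins the compound's activity class at the 1000 nM boundary:
`> 2000 nM` is unambiguously inactive-class and is kept (contributing the
bound as its working value), while `> 500 nM` could fall on either side
and is dropped. This is the only reading under which the qualifier rule
acts as a filter, and it makes curation idempotent. Activities are
converted as `pIC50 = 9 - log10(IC50 [nM])`.

The train/test split uses `ceiling(n * fraction)` for the test size: at
n = 103 and a 10% fraction this reproduces the conventional 92/11
partition (plain rounding would give 93/10).

Feature selection is correlation-based (CFS): a subset S of fingerprint
bits scores

$$M(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}}$$

with $k = |S|$, $\bar r_{cf}$ the mean absolute Pearson (point-biserial)
correlation between member bits and activity, and $\bar r_{ff}$ the mean
absolute pairwise correlation among members — rewarding relevance and
penalising redundancy. Search is best-first from the empty set: the best
unexpanded subset is popped and all single-bit additions evaluated;
termination after five consecutive non-improving expansions (the
conventional default). We use Pearson correlation throughout rather than
the symmetric-uncertainty variant some toolkits substitute internally;
Pearson is the measure in the original CFS formulation for numeric
responses and keeps the exhaustive oracle (against which the search is
tested on up to 12 features) unambiguous. Zero-variance bits are excluded
before the search. Selection is performed on the training set only; the
full-set variant is available but not the default.

# The regression harness

Learners enter through a two-method interface (`fit(x, y)`,
`predict(model, x)`), so cross-validation, external validation and model
ranking are agnostic to the learner. Adapters are provided for the common
families (random forest, support-vector regression, Gaussian-process RBF,
boosting, multilayer perceptron, k-NN), but the test suite deliberately
exercises only dependency-free reference models — the mean baseline,
ordinary least squares and 1-nearest-neighbour — because the package's
claims concern the harness and the statistics, not any learner's
internals. Hyperparameters default to the adapter library's defaults.
Model ranking sorts by cross-validated Q² descending, breaking ties by
MAE ascending and then model name, so it is fully deterministic.

# Validation statistics and decision rules

`regression_metrics()` computes, from an observed/predicted pair with
training-set provenance: the determination coefficient Q²/R², the
regression-through-origin slopes k and k′, the RTO determination
coefficients R₀² and R′₀², the concordance correlation coefficient, the
external functions Q²F1/Q²F2/Q²F3, the r²m pair and their mean, and MAE.
Three numerical conventions matter:

* **R′₀² denominator.** We use predicted-side deviations
  $\sum(\hat Y - \bar{\hat Y})^2$, exactly as the printed formula states,
  although some literature variants use observed-side deviations.
* **r²m under the root.** $R^2 - R_0^2$ can be numerically negative for
  near-perfect fits, where the printed formula is undefined; we take the
  absolute value under the square root and set `rm2_abs_flag` on the
  report, following common QSAR practice.
* **Q²F2 for CV-kind sets.** With no external set, the whole-set mean is
  substituted and the report is annotated with its provenance.

The Golbraikh–Tropsha rule requires Q² > 0.5, external R² > 0.6, at least
one relative RTO gap below 0.1, at least one RTO slope in [0.85, 1.15],
and |R₀² − R′₀²| < 0.3; the concordance-based rule requires CCC ≥ 0.85,
each Q²Fn ≥ 0.70 and mean r²m ≥ 0.65. Both return a per-criterion table
plus the conjunction, and both degrade gracefully (explicit failure, no
division by zero) when R² ≤ 0.

Threshold classification dichotomises observed activity at pIC50 ≥ 6 —
the active/inactive convention for this target class — and scores the
ROC AUC of the predictions by the Mann–Whitney midrank formulation, which
is exact under ties (unlike trapezoidal integration over a stepped ROC).
Note that a pIC50 of 6 corresponds to IC50 = 1 µM; descriptions of this
threshold as "1 nM" occasionally appear in the literature and are
inconsistent with the logarithmic definition, so the package implements
the pIC50 form.

# Screening analytics

All ranking operations work on a `score_table` that records each
protocol's direction (`lower_better` for docking energies,
`higher_better` for similarity scores); scores are oriented before any
ranking, so an AUC above 0.5 always means real discrimination. The
enrichment factor at fraction f uses the top $\lceil fN \rceil$ compounds
— the most common of the several EF conventions in use — and breaks score
ties lexicographically by compound id for determinism; EF(1) = 1
identically, and EF is bounded by min(1/f, N/actives). Z-normalised
consensus standardises each protocol over the screened set, negates
lower-is-better z-scores so larger is uniformly better, and sums; the
ranking is therefore invariant under any positive affine transform of a
protocol's raw scores, which is the property that makes scores from
different engines commensurable. Benchmark thresholding keeps compounds
scoring equal-or-better than a reference value (e.g. a known inhibitor's
−9.0 kcal/mol docking score), and hit-list intersection reports all
pairwise sizes for Venn-style accounting.

Cognate-pose RMSD is computed **without** superposition — both poses
share the receptor frame, so rigid displacement is part of the docking
error — over heavy atoms, with no graph-automorphism symmetry
correction (a documented limitation: symmetric ligands can score
pessimistically). The pass threshold defaults to 2.0 Å.

Published EF values for some protocols (e.g. a zero EF alongside an AUC
near 0.77) are hard to reconcile with any standard EF definition, and the
generating convention is typically unstated; the package implements the
standard definition above and makes no attempt to match such values.

# Negative design

The exclusion stage is a local rule engine over four rule kinds:
substructure alerts (SMARTS, matched through OpenBabel when structures
are supplied), physicochemical property windows (MW, cLogP, H-bond
donors/acceptors, rotatable bonds — fully config-driven, defaulting to a
standard drug-likeness profile), annotation thresholds (promiscuity
pScore ≥ 300 fails, the inclusive comparison mattering at the boundary),
and annotation flags (predicted aggregators fail). Aggregation and
promiscuity arrive as *annotations* rather than being predicted: the
web-server models that produce them are external services, and consuming
their outputs as data preserves the decision logic while keeping the
package self-contained. The shipped substructure table is a compact
curated subset of the published pan-assay-interference (PAINS) families
A/B/C; a complete catalogue can be supplied in the same tab-separated
format. Verdicts are per-compound and order-invariant, a compound with an
unparsable structure is marked not-evaluable rather than dropped, and
not-evaluable fails only in strict mode. Removing a rule can never shrink
the survivor set.

# Trajectory stability analytics

The trajectory container is frames × atoms × 3 with explicit per-atom
metadata (residue, element, mass, backbone flag, protein/ligand/solvent
chain tag) and explicit hydrogens throughout — no hydrogen inference
anywhere. Superposition is the Kabsch SVD construction with the
determinant correction that excludes reflections.

* **RMSD series** fits every frame to the reference (frame 0 by default —
  stability is measured relative to the initial structure) over the
  protein backbone, then measures over the backbone, the ligand, or a
  binding-site selection.
* **Binding site** = protein residues with any heavy atom within 5.0 Å
  (inclusive) of any ligand heavy atom in frame 0, reported as those
  residues' backbone atoms. This contact convention stands in for the
  pocket-detection services used in practice.
* **Rg** is mass-weighted by default; **RMSF** superposes to the iterated
  mean structure (two passes) and aggregates per residue.
* **Hydrogen bonds**: a candidate donor/H/acceptor triple is satisfied in
  a frame when the donor-heavy-atom···acceptor distance is ≤ 3.0 Å and
  the D–H···A angle (vertex at H) is ≥ 135°, both inclusive. The distance
  is donor-to-acceptor, not H-to-acceptor — consistent with a 3.0 Å
  cutoff magnitude; conventions differ across tools and this one is
  documented rather than inferred. Occupancy below 20% drops a bond from
  the headline table but not from the full output; average distances are
  over satisfying frames only.
* **PCA** removes global motion by the same two-pass mean-structure
  superposition, diagonalises the Cartesian (unweighted) 3N covariance,
  and clamps round-off-negative eigenvalues at zero; the eigenvalue sum
  equals the covariance trace to 1e−8 relative.
* **FEL**: Boltzmann inversion of the 2-D frame histogram over PC1/PC2,
  $G = -k_BT\ln(n/n_{max})$, at 300 K (the usual production-run
  thermostat setting; $k_BT \approx 0.596$ kcal/mol) with a kJ/mol
  switch. Empty bins get the maximum finite G plus an offset and are
  flagged; basins are counted as 8-neighbourhood local minima below a
  configurable depth (default 1 kcal/mol).

# What the generators emulate — and what they do not

`gen_qsar_dataset()` plants a linear bit→activity signal: uninformative
bits are Bernoulli with per-bit prevalence drawn once from U(0.05, 0.5)
(the sparsity profile of real structural fingerprints), informative bits
carry additive weights, and the noiseless signal is affinely rescaled to
span pIC50 4.398–7.721 — the activity range of the curated 103-compound
dataset the defaults mirror — before Gaussian noise of sd 0.3 pIC50 units
is added. Rescaling the signal only keeps `noise_sd` in stated units. The
noise level and the bit–activity structure of real data are unknown
(nothing equivalent is reported for the real datasets), so these defaults
are conventions chosen once, not estimates: real fingerprints have
correlated bits, nonlinear structure–activity relationships and
heteroscedastic assay noise, none of which the generator produces.
Passing tests therefore demonstrate correctness of the analytics under a
known linear ground truth, not predictive performance on real chemistry.

`gen_score_set()` draws Gaussian scores per class, for which the ROC AUC
has the closed form $\Phi(\Delta\mu/\sqrt{\sigma_a^2+\sigma_i^2})$ — the
anchor for enrichment validation. `gen_trajectory()` composes per-atom
isotropic Gaussian fluctuation with rigid-body motion (rotation about the
template centroid, which keeps Rg invariant by construction, plus
per-frame translation) and overrides scheduled hydrogen-bond geometry
exactly: conforming frames place the acceptor 2.7 Å from the donor along
the donor–H direction (D–H···A = 180°), non-conforming frames at 5.0 Å,
in exactly `round(fraction * n_frames)` frames. The atom template carries
reference coordinates explicitly; the built-in template is a small
pseudo-system (a few backbone residues plus a four-atom ligand) with no
claim to stereochemical realism. Real trajectories have anisotropic,
correlated fluctuations and conformational transitions; the generator's
role is to make every analytic's expected value computable.

# Numerical and design choices

* Seeds are explicit in every spec object; identical spec + seed is
  bitwise reproducible.
* Score ties in rankings break lexicographically by compound id.
* The RMSF benchmark against $\sigma\sqrt 3$ is run without superposition
  when no rigid motion is present: fitting a small N-atom system removes
  roughly 6/(3N) of the variance (the rigid-body degrees of freedom),
  which for the built-in template exceeds the 2% test band. With rigid
  motion present, fitting is enabled and the same bias affects both sides
  of the comparison equally.
* The planted collective mode used to validate PCA assigns each atom its
  own fixed direction: a mode in which all atoms share one direction is a
  pure translation and would be removed by superposition.
* The Boltzmann-gap check on the FEL uses the nearest-integer counts to a
  ratio of e (1000 and 368), asserting the identity
  $\Delta G = -k_BT\ln(n_1/n_2)$ at machine precision; an exact ratio of
  e is not representable with integer bin counts.
* Problem sizes in the tests and the acceptance script — 103 and 500
  compounds, 1024 bits, 2000–5000 frames, 5000-compound score tables —
  were chosen as the smallest scales at which the statistical assertions
  have comfortable margins.

# Known limitations

* With an 11-compound external set (the 92/11 convention), external R²
  and the downstream decision rules have large sampling variance: on
  synthetic data at noise sd 0.3 the Golbraikh–Tropsha and concordance
  rules can fail at one seed and pass at another. The analysis drivers
  report whatever the seed produces; the correctness of the decision
  machinery itself is established by the metric-oracle and
  worked-decision tests, not by asserting PASS on small external sets.
* No docking, shape matching, force-field energetics, MM/GBSA, or
  toxicity prediction: scores and annotations always arrive as tables.
* Cognate RMSD has no symmetry correction; the PAINS table is a subset;
  the CFS search is best-first, exact only where the exhaustive oracle
  can certify it (≤ 12 features in the tests).
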