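---
title: "Fold classification of predicted protein models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold classification of predicted protein models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Template-free structure prediction pipelines emit hundreds to thousands of
candidate models ("decoys") per target sequence, and for many targets every
one of them is wrong. Two decisions must be made downstream: which model to
select, and whether the selected model can be trusted at all. `rfqa`
addresses both by estimating, for each model, the probability that it is in
the correct fold — conventionally, a TM-score of at least 0.5 against the
(unknown) native structure — and by binning that estimate into four
confidence tiers: high (score > 0.5), medium (0.3, 0.5], low (0.1, 0.3],
and failed (<= 0.1). Boundary values belong to the lower tier.

The estimator is a random forest over 58 features per model. Its defaults,
500 trees with 7 candidate features per split, no class reweighting, and no
feature normalisation (tree ensembles are scale-free), are the
configuration of the published protocol this package re-implements. The
forest's vote fraction is used directly as the probability estimate; no
additional calibration is applied.

## The feature scheme

Features divide into three groups, frozen in a versioned manifest
(`feature_manifest()`, 58 names) that every fitted model stores and every
prediction call validates against:

* **Target-specific (3).** Chain length; the effective sequence count
  B\_eff of the target's alignment (redundancy-weighted at 80% identity,
  `compute_beff()`); and the number of predicted contacts with probability
  above 0.5. These encode how much coevolutionary information was
  available, which strongly conditions both modelling success and the
  reliability of contact-based features.
* **Model-specific (12).** Five externally supplied single-model quality
  scores (ingested from delimited tables; the package does not run those
  programs); a consensus score (mean pairwise TM-score of the model
  against the rest of its ensemble, `consensus_scores()`); the PcombC
  combination (weighted sum of a global single-model score, the consensus
  score, and the contact PPV, `pcombc()`); a predicted-contact potential
  (`contact_potential()`); the proportion of predicted contacts satisfied
  in the model (PPV, `contact_ppv()`); and three contact-map alignment
  quantities — the spectral alignment score, and the local alignment
  score and hit length (below).
* **Ensemble-specific (43).** Maximum, minimum, median, and spread
  (maximum minus median) of ten of the twelve model features, computed
  once per target across all of its models; plus the per-target maxima of
  the alignment hit length, the PPV, and the absolute satisfied-contact
  count. The published description counts "10 of 12" summarised features
  plus three maxima for a total of 43; this only balances if the absolute
  satisfied-contact count is carried as an auxiliary thirteenth quantity
  outside the twelve model features, and that is the reading adopted here
  (40 + 3 = 43). It is a documented resolution of an ambiguity, not a
  claim about the original authors' bookkeeping.

Missing external scores are imputed with the per-target median of the
available values for that column (falling back to user-supplied global
medians when a column is absent for a whole target); imputation is logged.
Contact satisfaction uses the same convention everywhere: a predicted pair
is satisfied when the representative atoms (C-beta, C-alpha for glycine)
are strictly closer than 8 Angstrom. The observed contact map applies a
minimum sequence separation of 5 by default; no separation filter is
stated for the source protocol's observed maps, so the parameter is
exposed. Predicted contacts are thresholded at probability 0.5 where a
count or a PPV denominator is needed; whether the original pipeline
thresholded at read time cannot be determined from its description, so
the threshold is a parameter rather than a constant.

## Contact map alignment

Two aligners score the agreement between a model's observed (binary)
contact map and the target's predicted (probabilistic) map. Both operate
on zero-diagonal symmetric matrices and treat thresholding as a
featurization concern, consuming probabilities as they come.

**Local alignment with iterated double dynamic programming**
(`align_local()`). A mapping is a strictly increasing partial
correspondence between the residues of the two maps. Its score sums, over
pairs of aligned positions whose endpoints are in contact in both maps,
the weight `p_pred / (1 + |sep_obs - sep_pred| / 10)` — the predicted
probability discounted by sequence-separation mismatch — plus affine gap
costs (open -1, extend -0.1) for gaps between consecutive aligned
positions; unaligned overhangs are free. No scoring formula is published
for the original map-alignment tool, so this objective is a faithful
re-creation in spirit with every constant exposed as a parameter. The
optimisation is the classic double-DP heuristic: a residue-pair seed
matrix is refined by alternating a Smith-Waterman/Gotoh pass with an
update that rescores residue pairs by the contact-neighbourhood overlap of
the current mapping (up to 20 sweeps). Because single-seeded refinement
can stall in local optima, the search restarts from
contact-neighbourhood-overlap seeds, from diagonal-shift seeds, and — for
maps up to 12 residues — from anchor seeds that force the order-preserving
correspondence of one or two jointly compatible contact pairs, followed by
a greedy drop-polish. The reported score is always the exact objective of
the best mapping found, never the DP proxy. On maps of length up to 8 the
test suite requires the result to equal `brute_force_align()`, an
exhaustive enumeration of every monotone partial correspondence under the
identical objective.

**Spectral alignment** (`align_spectral()`). Both matrices are
eigendecomposed; the leading `k = 15` eigenvectors (by absolute
eigenvalue, clamped to the map length) are scaled by the square roots of
their absolute eigenvalues. Eigenvector sign is fixed by making the entry
of largest magnitude positive, and the residue-pair similarity
`S(i, j) = sum_k |u_k(i) v_k(j)|` uses absolute products, so the score is
exactly invariant under any per-eigenvector sign flip — the inherent
ambiguity of eigendecomposition cannot leak into the feature. A global
affine-gap alignment of the two eigenprofiles yields the score. The tests
compare it against an independent plain-R reimplementation
(eigendecomposition plus textbook Gotoh recursion).

Neither aligner attempts bit-compatibility with the original tools; the
hit-length feature counts aligned residue positions (the published
description does not fix whether "hit length" counts positions or matched
contacts, and this choice is documented here).

## TM-score with a fixed correspondence

Decoys in this package share residue indexing with their native, so
TM-score reduces to maximising `(1/L) sum_i 1/(1 + (d_i/d0)^2)` with
`d0 = 1.24 (L-15)^(1/3) - 1.8` over rigid superpositions
(`tm_score_fixed()`, no alignment search). The search is the standard
heuristic: Kabsch superpositions seeded from contiguous fragments of
lengths L, L/2, and L/4 at stride 4, each iterated by superposing on the
residues currently within d0 until the selection stabilises (at most 20
iterations), keeping the best value seen, run in both directions. `d0` is
clamped below at 0.5 Angstrom, as in the reference implementation, because
the raw formula is non-positive for very short chains; the closed-form
checks in the tests (identity and rigid motion give 1.0; every residue at
d0 gives exactly 0.5) use lengths where the clamp is inactive. This
heuristic is adequate for same-topology decoys; it is not a replacement
for full structural alignment of unrelated folds.

## Evaluation surfaces

`tier_report()` ranks each target's models by classifier score (ties
broken lexicographically by model id), assigns the target the tier of its
top model, and tallies per tier the targets whose top model (Top1) or best
of the top five (Top5) is correct, together with the number of targets
with any correct model (Max). Precisions are emitted both to one decimal
and as integer percent, matching the two styles in which such tables are
usually quoted. `roc_auc()` is the Mann-Whitney rank statistic with
midrank ties; the suite checks it against brute-force concordant-pair
counting and against pROC. Two baselines from large-scale modelling
studies are provided: thresholding a score at the largest recall
satisfying an FPR budget (`fpr_threshold_baseline()`; 0.01 and 0.1 are
the conventional budgets), and the convergence criterion that calls a
target correct when the mean pairwise TM-score of its ten top-ranked
models exceeds 0.65 strictly (`convergence_baseline()`; 0.37 is the
recall-oriented alternative cutoff).

## The iterative protocol

`run_protocol()` grows an ensemble in batches of 500 up to 10,000 models,
re-assembling the ensemble feature block and re-scoring every model after
each batch — mandatory, because ensemble features change as models
accumulate — and stops at the first batch containing a model at or above
the stop tier (high by default). Model-specific features are taken from
the generator as given and are not recomputed per interval; whether the
original study recomputed its external per-model scores at each interval
is not stated, and this assumption is documented here. Partial final
batches are accepted and logged; `protocol_summary()` reports the
per-target model counts and their median.

## The synthetic benchmark

Everything above is testable offline through a generator of fully
synthetic study conditions (`benchmark_spec()`, `synth_benchmark()`):

* **Natives** are compact self-avoiding bundles of helical segments
  (about 12 residues per segment, 8.3 Angstrom axis spacing, serpentine
  packing) with 1-3 long-range contacts per residue at the 8 Angstrom /
  separation-5 definition — the density band typical of globular domains.
* **Decoys** displace the native by a smooth chain-correlated field (three
  low-frequency sinusoidal modes per coordinate plus a small white
  component) scaled to an exact RMS magnitude, plus a random rigid
  motion. The default levels 1, 2, 3, 5, and 8 Angstrom span TM-scores
  from about 0.9 down to 0.25, straddling the fold threshold. A quarter
  of targets are drawn "hard" (all levels scaled by 4), emulating the
  roughly 40% of real targets for which modelling produces no correct
  model and populating the lower confidence tiers.
* **Predicted contacts** keep a coverage fraction of the native contacts
  and add false pairs so the expected precision against the native map
  matches the request (defaults: precision 0.7, coverage 0.9), with true
  entries drawing higher probabilities than false ones.
* **External scores** are informativeness-weighted mixes of the
  standardised true TM-score and Gaussian noise plus a per-target offset
  (default informativeness 0.8), reproducing the key nuisance property of
  real single-model scores: useful within a target, incomparable across
  targets.

The default validation size is 8 targets of 40-80 residues with 50 models
each; featurizing one such benchmark takes seconds to tens of seconds on
one core, which keeps the full suite and the acceptance script within
minutes while leaving all per-target statistics meaningful.

**The uninformative condition.** A degenerate benchmark
(`null_benchmark_spec()`) underpins the negative control: external
informativeness 0, predicted contacts derived from an unrelated fold at
precision 0.05, fixed chain length, and — crucially — single-basin
ensembles (`synth_basin_decoys()`): every decoy sits at a fixed RMS
wobble, in an independent random direction, around one attractor whose
distance to the native is calibrated by bisection so decoy TM-scores
straddle 0.5. The design point is that merely zeroing the simulated score
informativeness does *not* remove all signal: whenever ensemble members
genuinely vary in quality, mean pairwise similarity tracks that quality —
which is exactly why consensus methods work, and why a naive null
benchmark lets the classifier stay well above chance through its
consensus features. In the single-basin geometry, pairwise agreement is
decoupled from correctness by construction (all pairwise distances
concentrate around wobble times sqrt(2) regardless of where the native
lies), and correctness flips on sub-resolution differences no feature
tracks. Under this condition held-out classification falls to chance
levels, while under the informative defaults it is nearly perfect; the
acceptance suite asserts both.

**What passing these tests does and does not show.** The synthetic decoys
are smooth deformations of one basin (or one wrong basin); real
fragment-assembly ensembles are multi-modal, with compactness artefacts,
chain breaks, and mirror topologies the generator does not emulate.
Simulated external scores are Gaussian by construction; real single-model
scores have heavy tails and systematic biases. Passing the parameter
recovery suite therefore shows the pipeline is correctly wired and that
the classifier recovers planted signal under realistic feature geometry —
it does not certify performance figures on real decoy sets.

## Numerical and design choices

* Contact boundary strict (`< 8` Angstrom) everywhere; one convention for
  both map construction and satisfaction.
* PPV with an empty thresholded prediction set returns 0 with a warning
  (alternatives: NA, or an error; 0 keeps downstream feature tables
  total).
* PcombC weights are not published; the default (0.2, 0.5, 0.3) weights
  the consensus component most and is prominently configurable. Since the
  feature feeds a tree ensemble, only its ranking behaviour matters.
* The consensus feature uses mean pairwise TM-score rather than an
  S-score-based superposition, again because only ranking matters
  downstream.
* Tier boundaries assign boundary scores to the lower tier ("high" is
  strictly greater than 0.5).
* Tie-breaks are deterministic everywhere: ranking ties by model id,
  alignment traceback prefers match over gap then smaller index,
  eigenvector signs fixed by largest-magnitude entry.
* Per-target cross-validation (`rfqa_cv()`) assigns whole targets to
  folds so no ensemble straddles the train/test boundary.
* Degenerate inputs error early: single-class training labels, fewer
  targets than folds, length mismatches, probabilities outside [0, 1],
  insertion codes in PDB input.
* B\_eff identity uses all alignment columns (gap characters compare as
  characters) at a configurable 80% threshold; the source definition
  lives in supplementary material that prints no formula beyond the
  clustering rule, so the convention is documented rather than asserted.

## Limitations

Per-residue (local) quality is out of scope — the method scores whole
models. External quality scores are ingested, never computed; PDB input
is single-chain, first-model, C-beta-or-C-alpha only. The TM-score
implementation assumes a fixed residue correspondence and is not a
general structural aligner. The classifier ships untrained: it is fitted
to whatever decoy population the user provides, and, as with the original
protocol, transfers best to ensembles resembling its training
distribution.
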