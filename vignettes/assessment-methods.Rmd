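---
title: "Assessment methods for protein-ligand pose and affinity predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessment methods for protein-ligand pose and affinity predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligassess)
```

# Scope and model

`ligassess` assesses blind predictions of protein–ligand complexes and
binding affinities the way community docking challenges do: crystal
structures are the ground truth for poses, measured IC50 series are the
ground truth for affinities, and groups are compared by aggregate
statistics that penalize selective skipping of targets. The package does
**not** assess overall protein fold accuracy — only the ligand pose and
the binding-site structure — and it deliberately evaluates affinity
predictions by *ranking power* only, because submissions arrive as
absolute constants, relative constants, or plain rankings, and only
their order is comparable across those forms.

All structural metrics are heavy-atom metrics; hydrogens are stripped at
parse time. Ligand identity is element + connectivity: bond orders and
aromaticity flags are ignored when a submitted molfile is checked
against the announced SMILES, so kekulization differences between
predictors' files never cause false rejections.

# Pose metrics

## Binding site and superposition

A binding-site residue is any residue with a heavy atom within
`site_cutoff` (default **4 Å**) of a heavy atom of the ligand instance
under consideration. Site Cα atoms (polymer residues only; at least 3
required, otherwise the superposition is undefined and the pairing is
flagged) are superposed by the Kabsch algorithm, constrained to a proper
rotation. Rank-deficient (e.g. collinear) point sets are flagged
degenerate but still solved by SVD with sign correction. If more than
half of the site residues have no matching Cα in the prediction the
score is computed from those available (≥ 3) and flagged
`partial_site`.

Residue correspondence is by `(chain, residue number)` — no renumbering
is attempted. Because homodimers make chain labels ambiguous, an
optional chain-mapping pass (on by default) tries every chain bijection
among chains with identical residue sequences and keeps the one with
the best LDDT-PLI; the chosen map is then used for all four metrics.

## Symmetry correction

Molecular symmetry is handled through graph automorphisms of the
heavy-atom connectivity graph (element-preserving, adjacency-preserving
permutations), enumerated by deterministic backtracking in lexicographic
order, identity first, truncated at `automorphism_cap` (default
**10 000**) with a warning. A benzene-like ring has 12, the bundled
biphenyl-like template 8. BiSyRMSD minimizes over these permutations;
LDDT-PLI maximizes over the same list. On small ligands the result
provably equals the brute-force minimum over *all* valid permutations
(the acceptance suite checks 200 random ligands against an independent
exhaustive oracle).

## LDDT-PLI and its penalty

Reference contacts are (ligand heavy atom, protein heavy atom) pairs
within `inclusion_radius` (default **4 Å**) in the crystal. For each
contact and each threshold in `thresholds` (default **{0.5, 1, 2, 4} Å**,
the standard LDDT set) a check passes when the model reproduces the
reference distance within the threshold; contacts whose atoms are
missing from the model fail all checks. Predicted contacts that are
within the radius in the model but **not** in the crystal are penalized:
each contributes one failed check per threshold to the denominator,

$$\mathrm{LDDT\text{-}PLI} \;=\;
\frac{\sum_{\text{ref pairs}}\sum_t \mathbf{1}\!\left[\,|d^{model}-d^{ref}|\le t\,\right]}
     {|T|\,\big(N_{\text{ref pairs}} + N_{\text{penalty}}\big)} .$$

This is the simplest penalty that keeps the score in [0, 1] and makes it
strictly non-increasing in the number of spurious contacts; it is
isolated behind `lddt_core()` so a different weighting can be swapped in
without touching callers. Whether the challenge's reference scorer
weights penalties identically cannot be determined from prose alone —
this is a documented judgement call.

Non-polymer groups (structural Zn, glycans, and similar HETATM residues
of the reference protein) are *included* as contact-environment atoms by
default (`include_nonpolymer`), since they genuinely shape the pocket;
incidental crystallization additives are never part of the environment
and are scored separately, with the identical machinery, under their own
flag.

## LDDT-LP and BB-RMSD

LDDT-LP runs the same distance-difference test over all heavy-atom pairs
of the binding site drawn from *distinct* residues, with no penalty
term. Intra-residue pairs are excluded because covalent geometry fixes
them; they would only dilute the score with free passes. BB-RMSD is the
site Cα RMSD under the site superposition. Both are reported from the
best-RMSD pairing, while LDDT-PLI comes from the best-LDDT-PLI pairing —
references with multiple copies or alternate conformations are scored
against every (instance × pose) pairing and the two winners may differ;
both are recorded.

## Aggregation rules

* **Skip penalty**: a group's mean LDDT-PLI and success rate are taken
  over the *full* target list with unsubmitted targets scored 0 /
  unsuccessful. Success means RMSD ≤ `success_cutoff` (default
  **2.5 Å**, boundary inclusive).
* **Best of models**: the highest-LDDT-PLI model per (group, target),
  ties to the lowest model number; a group submitting only Model 1 keeps
  it as its best.
* **Undefined targets**: when the *reference* cannot be scored (e.g. a
  ligand with zero crystallographic contacts), the target is removed
  from both numerator and target list — the defect is the reference's,
  not the predictor's. `undefined_as_skip = TRUE` switches to counting
  them as skips.
* **Target difficulty** means are computed *without* skip penalty:
  difficulty describes targets, not groups. Both variants are
  computable; this default is a documented choice.
* **LScore reliability** is Kendall τ between LScore and LDDT-PLI over
  all of a group's models, no skip penalty; constant LScore vectors are
  excluded as carrying no ranking information.

# Affinity assessment

Measured IC50s (nM) and predictions of any kind are reduced to
strongest-first rankings; accuracy is tie-corrected Kendall **τ-b**
(ranked submissions force ties, so a tie-corrected variant is the only
defensible choice). Missing predictions within a dataset reduce that
group's *n* — unlike poses there is no zero-fill penalty; the
cross-supertarget combination weights by the number of affinities
actually submitted, $\kappa_N = \sum_i N_i\tau_i / \sum_i N_i$.
Previously disclosed targets are removed before scoring via a
config blacklist (the shipped `disclosed_targets.csv`); statistics with
and without the removals are both computable.

## The noise ceiling

Even a perfect predictor cannot reach τ = 1 against noisy measurements.
With $\Delta G \approx RT\ln \mathrm{IC50}$ (RT = **0.6 kcal/mol**, so a
3-fold IC50 error is 0.66 kcal/mol), `ceiling_tau()` draws
`n_resamples` (default **1000**) copies of the dataset with i.i.d.
$\mathcal N(0,\sigma^2)$ added to the comparison copy *only* — the
resample is compared against the actual data, not noisy-vs-noisy — and
reports the mean and SD of τ. Defaults σ = **0.66** (≈3× IC50 error)
and **2.0 kcal/mol** (≈30×) bracket optimistic and pessimistic error
models. The Monte-Carlo mean agrees with the closed form
$\frac{2}{n(n-1)}\sum_{i<j}\big(1-2\Phi(-|\Delta G_i-\Delta G_j|/(\sigma\sqrt2))\big)$
within sampling error (asserted in the acceptance suite). Two
consequences follow and are asserted as properties: the ceiling
decreases in σ, and datasets with wider dynamic range have higher
ceilings at fixed n and σ — which is why a near-ceiling τ on a
narrow-range dataset does not indicate a better method.

# Template similarity

Pocket residues use a looser **6 Å** cutoff than the 4 Å assessment
site, because target and template need not share side chains. Pocket
coverage is the fraction of target-pocket residues mapped by the
supplied residue alignment onto template-pocket residues; the alignment
and any rigid transform are *inputs* (template search is out of scope) —
absent a transform, one is built by Kabsch superposition of aligned
Cα pairs. The SuCOS-style ligand overlap is
0.5 × shape + 0.5 × feature (the conventional weighting; both weights
config-exposed): the shape term is the Gaussian-volume Tanimoto over
heavy atoms with a single fixed radius (**1.7 Å** — per-element radii
are a deliberate simplification), and the feature term averages the same
Tanimoto over pharmacophore families (N/O donor–acceptors, 5/6-ring
centers, non-polar carbons) present in either molecule. Without
hydrogens, donors and acceptors cannot be distinguished, so N/O form a
single family; if neither molecule has any feature the feature term
falls back to the shape term so identity still scores 1. The combined
score is SuCOS × coverage, maximized over templates; a target with no
template scores 0.

# Synthetic data: what it does and does not establish

The generator builds miniature complexes — idealized residues (N, CA,
C, O plus a pseudo side-chain atom) arranged so the ligand has a
well-defined 4 Å site — around three hard-coded templates: a symmetric
6-ring, an asymmetric branched chain, and a two-ring hybrid with one
rotatable bond. Cohorts exercise every scoring branch: multiple copies,
alternate conformations, symmetric flips, skips, incidental ions, and
LScores correlated with true accuracy
(`LScore = clamp(LDDT-PLI + N(0, (1-ρ)·0.3), 0, 1)`, which requires
scoring each model at generation time). Pose noise is translation +
rotation with Model-k noise scaled by $1 + 0.3(k-1)$ so Model 1 is best
on average. Affinity truths are uniform over a span (default 5.4
kcal/mol, matching a realistic ~8700× IC50 range); experimental and
group noises are Gaussian.

What a green test establishes: the pipeline's arithmetic, symmetry
handling, pairing/selection rules, penalty behavior, determinism, and
end-to-end parameter recovery (groups ranked in their true quality
order at 50 targets). What it does not: realism of protein folds,
rotamers, or decoy physics; heavy-tailed experimental error; systematic
(non-Gaussian) prediction biases; performance at PDB scale. Generator
defaults are part of the stated testing world and are not tuned to make
tests pass.

# Numerical and reproducibility choices

* Coordinates are Å throughout; PDB round-trips are exact to the
  format's 3-decimal precision.
* Altloc resolution: highest occupancy wins, ties by altloc letter.
* Proteins distributed as all-zero-coordinate templates are treated as
  absent; none of the four metrics is computable without a predicted
  protein, so such entries are flagged skips rather than silently
  dropped.
* Ties in rankings break to the lower group id; best-of-models ties to
  the lower model number; automorphism enumeration is lexicographic so
  recorded permutation ids are stable.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; cohort and affinity simulations are pure
  functions of (spec, seed), and CLI reruns are byte-identical.

# Known limitations

* Covalent ligands are scored as ordinary ligands; attachment metadata
  is carried but ignored by the metrics.
* mmCIF, protonation/tautomer assignment, and crystallographic symmetry
  expansion are out of scope.
* The SMILES parser covers the organic subset, brackets, branches and
  ring closures — enough for identity graphs, not a general
  cheminformatics toolkit.
* The LDDT-PLI penalty weighting and the feature-family definitions are
  judgement calls isolated behind one function each, as noted above.
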