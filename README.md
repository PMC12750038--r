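# ligassess

Assessment toolkit for blind protein–ligand **pose** and **affinity**
prediction challenges, written for assessors and method developers in
computer-aided drug design who need to score predicted protein–ligand
complexes against crystallographic references and rank participating
groups reproducibly.

In such a challenge, each participating group submits up to five models
(Model 1 = favored) per target: predicted protein coordinates (PDB),
a predicted ligand pose (MDL molfile), optionally a self-reported
reliability score (LScore ∈ [0, 1]), and — for affinity targets —
absolute, relative, or ranked affinities. `ligassess` implements the
full assessment pipeline over such submissions, plus a synthetic-data
generator so the whole pipeline can be exercised and tested without any
proprietary challenge data.

## Metrics

**Pose accuracy** (all heavy-atom, per prediction/reference pairing):

- **BiSyRMSD** — binding-site superposed, symmetry-corrected RMSD.
  Binding-site residues are those with heavy atoms within 4 Å of the
  ligand; their Cα atoms are superposed with the Kabsch algorithm, and
  the reported value is min over ligand graph automorphisms σ of
  `RMSD(x_ref, R x_pred ∘ σ)`, so a 180° phenyl flip costs nothing.
- **LDDT-PLI** — local distance difference test over ligand–protein
  contacts (inclusion radius 4 Å, thresholds {0.5, 1, 2, 4} Å), with a
  penalty for predicted contacts absent in the crystal: each such
  model-only contact adds one failed check per threshold. Range 0–1;
  maximized over ligand automorphisms; superposition-free.
- **BB-RMSD** / **LDDT-LP** — binding-site accuracy: Cα RMSD under the
  site superposition, and LDDT over all inter-residue site atom pairs.

When references carry multiple ligand copies or alternate
conformations, all (instance × pose) pairings — and all chain bijections
of equal sequence, covering homodimer symmetry — are scored; LDDT-PLI is
reported from the best-LDDT-PLI pairing, RMSD (with BB-RMSD and LDDT-LP)
from the best-RMSD pairing.

**Group statistics**: skip-penalized mean LDDT-PLI (skipped targets
count 0), skip-penalized success rate (success = RMSD ≤ 2.5 Å, boundary
inclusive), best-of-models analysis, per-target difficulty, and LScore
reliability as tie-corrected Kendall τ between LScore and LDDT-PLI.

**Affinity ranking**: Kendall τ (τ-b) between predicted and measured
IC50 orderings per supertarget, combined across supertargets as the
submission-count-weighted

    κ_N = (N_A τ_A + N_C τ_C) / (N_A + N_C)

and compared to a resampling **noise ceiling**: with ΔG ≈ RT ln IC50
(RT = 0.6 kcal/mol, so 3× in IC50 ≙ 0.66 kcal/mol), Gaussian noise of
sd σ is added to 1000 resampled copies and τ against the unperturbed
data is averaged — the best τ even a perfect predictor could achieve.

**Template similarity**: SuCOS-style score (½ Gaussian-volume shape
overlap + ½ pharmacophore-feature overlap) × binding-pocket coverage
(6 Å pocket definition, residue alignment supplied as input).

## Worked example

```r
library(ligassess)

spec <- cohort_spec(n_targets = 10, seed = 42,
  group_profiles = data.frame(sigma_pose = c(0.3, 1.5, 4.0),
                              skip_prob  = c(0, 0.1, 0.3),
                              lscore_rho = c(0.9, 0.7, 0.5)))
cohort <- simulate_cohort(spec)
scores <- score_cohort(cohort$refs, cohort$entries)
rank_groups(group_summaries(scores), "skip_penalized_mean_lddt_pli")
#>   rank group_id n_submitted skip_penalized_mean_lddt_pli
#> 1    1        1          10                        0.915
#> 2    2        2          10                        0.678
#> 3    3        3           9                        0.299
#>   skip_penalized_success_rate best_model_mean_lddt_pli
#> 1                         1.0                    0.996
#> 2                         0.9                    0.838
#> 3                         0.3                    0.578
```

Three simulated groups with pose noise 0.3/1.5/4.0 Å and skip
probability 0/0.1/0.3 are recovered in their true quality order by both
skip-penalized statistics; best-of-models means are higher than Model-1
means, as they must be.

```r
sim <- simulate_affinity(affinity_sim_spec(n = 40,
         group_sigmas = c(0.3, 1, 3), seed = 42))
sapply(sim$predictions, function(p) affinity_tau(sim$dataset, p)$tau)
#> [1] 0.7307692 0.5846154 0.4333333
ceiling_tau(ic50_to_dg(sim$dataset$measurements), sigma = 0.66,
            n_resamples = 1000, seed = 42)
#> <ceiling_estimate> mean tau 0.782 (SD 0.032) at sigma 0.66 kcal/mol, 1000 resamples
```

The most accurate simulated predictor (σ = 0.3 kcal/mol) scores
τ = 0.73, below the 0.78 ceiling set by the assumed experimental error —
exactly the comparison used to contextualize real submissions.

## Command line

```sh
Rscript -e 'ligassess::ligassess_cli()' simulate    --out fixtures --seed 7
Rscript -e 'ligassess::ligassess_cli()' score-poses --refs fixtures/refs \
    --subs fixtures/subs --manifest fixtures/manifest.json --out scores.csv
Rscript -e 'ligassess::ligassess_cli()' rank        --scores scores.csv --out ranks
Rscript -e 'ligassess::ligassess_cli()' affinity    --measurements meas.csv \
    --predictions preds.csv --out affinity.json --sigma 0.66,2.0
```

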