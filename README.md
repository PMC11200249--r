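# softmsm

Ensembles of neural soft Markov state models for conformational dynamics,
with optimal-transport state alignment and gradient-based state
interpretation.

## What problem this solves

Intrinsically disordered peptides and other flexible biomolecules visit an
ensemble of interconverting conformations rather than one fold. A Markov
state model (MSM) compresses their dynamics into a few metastable states
with a transition matrix **T**(τ) at a lag time τ. `softmsm` implements the
soft, ensemble-level variant of this analysis for featurized molecular
dynamics trajectories:

* a neural state-assignment function χ: **ξ** → Δ^M maps each frame's
  inter-residue distance vector **ξ** (length (R−2)(R−3)/2, e.g. 780 for
  R = 42 residues) to a probability vector over M states, trained on
  time-lagged frame pairs by maximizing the VAMP-E variational score
  tr[C₀₀⁻¹C₀τ Cττ⁻¹C₀τᵀ] of the output covariances;
* an ensemble of N such models (random 90/10 splits, best of 3
  initializations each by validation VAMP-E) quantifies estimation
  uncertainty; ensembles are aligned to a common state order by
  constrained k-means on per-state mean feature matrices ξ̄ₙₘ (no two
  states of one model may share a cluster);
* two systems (e.g. a peptide with and without a ligand) are compared by
  representing every state as the empirical distribution of its ξ̄ over the
  ensemble, scoring state pairs with the Wasserstein-1 distance, matching
  them with the Hungarian algorithm, and accepting pairs whose cost falls
  below a threshold T_e (default 6 Å);
* kinetics follow from the Koopman matrix K = C₀₀⁻¹C₀τ projected onto
  reversible non-negative transition matrices: equilibrium distribution π,
  mean first-passage times, implied timescales t_i = −τ/ln|λ_i|, and
  Chapman–Kolmogorov validation, each with median and 95th-percentile
  bands over the ensemble;
* per-state saliency maps g_m = ⟨∇_ξ χ_m⟩ (averaged over models and 10,000
  random frames) show which residue-pair distances define each state, and
  tICA + Gaussian-KDE free-energy surfaces visualize the landscape.

A ground-truth synthetic generator (hidden Markov chain over K states with
distance-like emissions) provides closed-loop validation of every stage.

## Worked example

```r
library(softmsm)

spec <- default_fixture(seed = 1)        # K = 3 states, 10 x 10,000 frames
gen  <- generate_hmm_dataset(spec)

ens <- train_ensemble(gen$dataset, M = 3, lag_steps = 5, N = 5,
                      inits_per_split = 3, config = fixture_net_config(),
                      seed = 2)
print(ens)
#> model_ensemble 'default-fixture': 5 models, 3 states, lag 5 steps
#>   validation VAMP-E: median 2.0868 [2.0656, 2.1143]

pairs <- make_frame_pairs(gen$dataset, 5)
print(kinetics_summary(ens, pairs))
#> kinetics_summary at lag 0.5 ns (5 models)
#> equilibrium (median [2.5%, 97.5%]):
#>   state 1: 0.167 [0.167, 0.167]
#>   state 2: 0.536 [0.536, 0.536]
#>   state 3: 0.298 [0.297, 0.298]
#> slowest implied timescale t2: 2.41 [2.41, 2.41] ns
#> median MFPT matrix (ns):
#>      [,1] [,2] [,3]
#> [1,]  0.0  5.4 4.16
#> [2,] 13.4  0.0 6.37
#> [3,] 10.3  4.5 0.00
```

The validation VAMP-E ≈ 2.09 sits near its theoretical ceiling
1 + λ₂² + λ₃² for this chain; the median equilibrium probabilities match
the generator's stationary distribution (0.531, 0.297, 0.172 — here the
ensemble numbered that same set of states 2, 3, 1) to ±0.005; and
t₂ = 2.41 ns is within 2% of the generator's −τ/ln λ₂ = 2.45 ns.

Cross-system comparison, on two simulated systems sharing 2 of 3 states:

```r
fx <- two_system_fixture(shared_states = 2, perturbation = 12, seed = 1)
# ... train an ensemble per system, then:
al <- align_across_systems(cost_matrix(ensemble_state_distributions(e1),
                                       ensemble_state_distributions(e2)),
                           threshold = 6)
print(al)
#> cross_alignment (system 1 -> system 2), total cost 12.19, threshold T_e = 6
#>   state 1 -> state 3  cost 11.57  unmatched
#>   state 2 -> state 1  cost 0.2606  matched
#>   state 3 -> state 2  cost 0.3585  matched
```

The two shared states align at sub-Å cost; the deliberately perturbed
state exceeds T_e and is correctly reported as having no counterpart.

A YAML-configured pipeline (`validate_config()` / `run_pipeline()`) and a
thin CLI (`inst/cli/softmsm.R` with `simulate`, `featurize`, `run`,
`align-across` subcommands) chain the stages with provenance and caching.

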