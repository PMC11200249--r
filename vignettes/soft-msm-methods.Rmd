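---
title: "Neural soft Markov state models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural soft Markov state models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Disordered biomolecules — intrinsically disordered peptides above all — do
not fold into one structure; their behaviour is a distribution over rapidly
interconverting conformations. A Markov state model (MSM) summarizes such
dynamics as a small set of metastable states with a transition-probability
matrix at a fixed lag time $\tau$. `softmsm` implements the *soft*,
ensemble-level variant of this analysis: a neural network maps each
trajectory frame to a probability vector over $M$ states, an ensemble of
such networks quantifies estimation uncertainty, optimal-transport
machinery aligns the learned states within and across systems (e.g., a
peptide with and without a bound ligand), and input-gradient maps explain
*which inter-residue distances define each state*.

# Featurization

A frame of an $R$-residue chain is represented by the upper triangle of its
inter-residue distance matrix with the diagonal and the first two
off-diagonal bands removed: neighbours $i,i\pm1$ and $i,i\pm2$ are
constrained by bonding and carry no conformational signal. That leaves
$F(R) = (R-2)(R-3)/2$ distances (780 for a 42-residue peptide), in
Angstrom. Two conventions are supported because both appear in practice:
the minimum over heavy-atom pairs of the two residues (default), and the
C$\alpha$–C$\alpha$ distance. The mode travels with every artifact; the
two modes share the pair ordering (row-major over $j - i \ge 3$, 1-based in
all reports), so downstream maps are comparable.

Raw features on disk stay physical distances; per-feature standardization
(mean/scale, estimated on training data) is part of the trained model, not
of the stored data. Gradients are chain-ruled back through the
standardizer, so all reported sensitivities are per Angstrom of physical
distance.

# The network and its variational objective

The state-assignment function $\chi$ is a multilayer perceptron with SELU
activations and a softmax head; the two lobes of the classic architecture
share one parameter set, applied to the frame at $t$ and at $t+\tau$.
Training maximizes the VAMP-E score of the output covariances

$$ R_E = \mathrm{tr}\!\left[ C_{00}^{-1} C_{0\tau}\, C_{\tau\tau}^{-1}
C_{0\tau}^\top \right], $$

with $C_{00}, C_{0\tau}, C_{\tau\tau}$ the instantaneous, cross- and lagged
second-moment matrices of the state probabilities over the time-lagged
pairs. Covariances are *not* mean-centered: the constant function is part
of the basis, so a one-state (constant) model scores exactly 1 and a model
resolving the slowest process of a two-state chain approaches
$1 + \lambda_2^2$. Gradients of $R_E$ with respect to the two probability
batches are derived in closed form and backpropagated through the shared
network; optimization is Adam over minibatches.

Two numerical choices matter and are worth stating plainly:

* **Ridge as gauge fixing.** $R_E$ is invariant under any invertible linear
  recombination of the output states — soft mixtures of crisp indicator
  functions score identically to the indicators themselves, so nothing in
  the bare objective selects crisp states. The diagonal ridge added to
  $C_{00}$ and $C_{\tau\tau}$ during training (default `ridge = 0.01`,
  relative to the mean diagonal) breaks this degeneracy gently in favour
  of maximum-variance outputs, i.e. vertex-like, crisp assignments, while
  leaving the reported (unridged) score essentially unchanged. The value
  is a compromise: much larger ridges distort the objective enough to
  favour merged-state solutions on some state geometries.

* **Warm start against state collapse.** Started cold, gradient ascent
  develops the slowest contrast first; the softmax saturates on it, and
  the gradient that would later split a prematurely merged pair of states
  vanishes together with $p(1-p)$ — a state-collapsed local optimum with
  an effectively dead output node, observed in a large fraction of cold
  runs. Training therefore begins with a few cross-entropy epochs toward
  one-hot k-means labels of the standardized training frames (default 3;
  `init = "random"` disables it). This guarantees every output state
  starts populated — the same role geometric clustering plays in
  classical MSM construction — after which the variational phase is free
  to move state boundaries to their kinetic optima. The softmax head is
  additionally initialized at $10^{-2}$ weight scale (near-uniform start,
  no node born dead), with the small noise breaking state symmetry
  deterministically under the run seed.

Model selection follows the ensemble protocol: the time-lagged pairs are
divided into $N$ random 90/10 train/validation splits (default $N = 20$;
splits are independent resamples, not folds), three networks per split are
trained from different derived seeds, and the best by validation VAMP-E is
retained. A model whose validation score drops below the one-state
baseline of 1 carries a warning flag. All randomness flows from one master
seed through a counter-based derivation, so any run is bit-reproducible.

The *soft assignment* of a frame is the ensemble average of its
permutation-corrected state probabilities; the *hard assignment* is the
argmax, with exact ties resolved to the lowest state index.

# Kinetics

The propagator in the basis of the learned state functions is the Koopman
matrix $K = C_{00}^{-1} C_{0\tau}$, whose rows sum to 1 by construction
and whose eigenvalues are invariant to invertible mixing of the outputs —
so implied timescales are estimated consistently even from imperfectly
crisp memberships. (Row-normalized soft counts, the obvious alternative,
are biased toward fast relaxation whenever memberships are fuzzy; the
package deliberately does not use them.) In the default
`reversible-nonnegative` mode, the probability-weighted flux
$\pi_i K_{ij}$ (negatives clipped) is projected onto the reversible set by
the standard self-consistent reweighting iteration (tolerance $10^{-10}$,
cap $10^4$ iterations); detailed balance of the result holds to machine
precision and all entries are non-negative. The unconstrained mode returns
$K$ itself.

From the estimated matrix follow the equilibrium distribution (dominant
left eigenvector), mean first-passage times (the standard linear solve on
the jump chain, scaled by $\tau$; no sub-lag interpolation), implied
timescales $t_i = -\tau / \ln |\lambda_i|$, and Chapman–Kolmogorov checks
comparing $T(\tau)^k$ with matrices estimated directly at lag $k\tau$.
Ensemble summaries report, per quantity, the median and the
95th-percentile band centered on it (quantiles 0.025/0.975, linear
interpolation).

# State alignment

The output order of a trained network is arbitrary, so states must be put
into correspondence before anything ensemble- or cross-system-level can be
said.

**Within a system** the $N$ models are aligned by constrained k-means on
their per-state average feature matrices $\bar\xi_{nm}$ (soft-weighted
means by default, matching the use of soft assignments elsewhere; hard
available). Centers are initialized from one (seed-chosen) model; each
iteration assigns every model's states to distinct clusters greedily — all
state–center distances of a model sorted ascending, ties to the lower
state then cluster index — and recomputes centers as member means. The
greedy step does not guarantee a monotone objective, so termination
combines assignment-fingerprint cycle detection with an iteration cap
(default 100); the `converged` flag distinguishes a genuine fixed point.

**Across systems** each state is represented by the uniform empirical
distribution of its $N$ per-model $\bar\xi$ vectors. State pairs are
compared by the Wasserstein-1 distance with Euclidean ground cost. For
uniform empirical distributions the transportation linear program is
solved exactly by replicating atoms to the least common multiple of the
two supports and solving the resulting assignment problem — a vertex of
the uniform transportation polytope is a permutation matrix, so no
generality is lost. The assignment itself, and the final matching of the
smaller system's states into the larger's, use a Jonker–Volgenant-style
Hungarian solver written for this package (no assignment solver exists in
the dependency stack); it is cross-checked against exhaustive enumeration
in the tests. Matched pairs count as genuinely aligned when their cost
falls below the threshold $T_e$ (default 6, in feature-space Angstrom —
an empirical choice; reports always carry raw costs so users can
re-threshold).

# Gradient maps

For state $m$, the map $g_m$ is the gradient of the ensemble's output
probability of $m$ with respect to the raw input distances, averaged over
models and over 10,000 frames sampled uniformly without replacement
(seed-controlled). The sign convention is fixed: positive means the state
probability increases when that residue-pair distance increases. Maps are
re-arranged into the $R \times R$ distance-matrix shape (excluded bands
marked) and aggregated per residue both as signed sums and absolute sums;
the absolute profile is the default "importance" curve, a declared choice
rather than a reproduction of any particular published aggregation.
Because the states' probabilities sum to one, the per-frame gradients sum
to zero across states — an identity the tests enforce at $10^{-8}$ — and
gradient maps permute equivariantly with state relabeling.

# Free-energy surfaces

Features are projected onto the two leading tICA components (symmetrized,
mean-free covariance estimator; instantaneous covariance whitened with an
eigenvalue floor and a warning under rank deficiency; lag defaults to the
MSM lag). The surface is $-\ln \hat p$ in kT units from a Gaussian KDE on
a 10% seed-controlled subsample, on a $100\times100$ grid padded 5% beyond
the data extent, shifted so the minimum is 0. Bandwidths follow Scott's
rule per dimension with a scalar multiplier; the KDE itself is
`MASS::kde2d`.

# The synthetic reference system

Because real adaptive-sampling MD datasets are out of scope, validation
runs against a generator whose ground truth is known exactly. Frames are
emitted by a hidden Markov chain over $K$ states, started at stationarity;
each state emits its mean feature vector plus isotropic Gaussian noise
truncated at zero (features are distance-like). The canonical fixture has
$K = 3$ states over a 12-pseudo-residue chain (45 features), transition
matrix rows (0.98, 0.015, 0.005), (0.03, 0.95, 0.02), (0.01, 0.04, 0.95),
and states that differ only in a 12-feature block (4, 8, 12 Angstrom
against an 8-Angstrom baseline, noise 2 Angstrom) — roughly $7\sigma$
total separation between adjacent states, so the Bayes-optimal assignment
accuracy exceeds 0.99 by a wide margin and any honest pipeline should
recover the states. The noise scale is deliberately not smaller: a
classifier trained on an even more separated system saturates completely,
and saturated softmax outputs have vanishing input gradients, which would
make saliency maps reflect initialization noise rather than the
discriminative block.
Ten trajectories of 10,000 frames (~$10^5$ frames at 0.1 ns spacing) are
the default study size; closed-loop checks train a 5-model ensemble (3
initializations per split, one 32-unit hidden layer — see
`fixture_net_config()`), which keeps a full run in the minutes range on
one CPU while leaving the protocol (random 90/10 splits, best-of-inits by
validation VAMP-E, constrained-k-means alignment) fully exercised.

The two-system fixture copies the canonical system, shifts the emission
means of the non-shared states by a vector of norm 12 (twice the alignment
threshold) inside the discriminative block, relabels states by a recorded
permutation, and re-simulates with an independent seed. A correct
cross-alignment must recover the permutation, match the shared states
below $T_e$ and leave the perturbed state unmatched.

What the generator does *not* emulate — and what passing tests therefore
do not show — includes: non-Markovian memory from projected degrees of
freedom, state-dependent and correlated noise, slow drift between
trajectories from adaptive seeding, and feature correlations induced by
chain geometry (triangle inequalities among distances). Results on real
MD data depend on those; the package's claims from synthetic validation
are about correctness of the machinery, not about biology.

# Degenerate inputs and edge rules

* Fewer than 4 residues: no features exist; featurization refuses.
* Fewer pairs than states: covariances are singular; scoring refuses with
  a hint.
* A state whose total soft weight vanishes (never-visited): named error at
  estimation and at $\bar\xi$ computation.
* Hard-assignment ties: lowest state index, documented and tested.
* Eigenvalues $\le 0$ in implied timescales: flagged `NA`, not an error.
* Datasets smaller than the requested gradient sample: all frames with a
  warning, and the count is recorded.

# Known limitations

* Pure-R training; practical up to ~$10^5$–$10^6$ frames and modest
  networks. The architecture is configurable but not the place for very
  deep models.
* Pairwise cross-system alignment only; no joint alignment of three or
  more systems, and no fractional (soft) state matching.
* The reversible estimator projects the Koopman matrix rather than
  constraining network weights; equivalence with constraint-layer
  formulations is asserted only at the level of the stated properties
  (reversibility, non-negativity, stochasticity).
* Trajectory ingest covers PDB topologies and DCD coordinate files (via
  bio3d, optional); other coordinate formats should be featurized
  upstream and imported as CSV feature tables.
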