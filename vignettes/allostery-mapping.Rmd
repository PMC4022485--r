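---
title: "Mapping interdomain allostery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping interdomain allostery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(allomap)
```

allomap integrates two complementary views of how a two-domain protein such
as the Hsp70 chaperone DnaK transmits signals between its nucleotide-binding
domain (NBD) and substrate-binding domain (SBD): the *mechanical* view
(elastic network models of one structure) and the *evolutionary* view
(coevolution statistics over a family alignment).  This vignette documents
the models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices a maintainer
would want spelled out.

## Elastic network dynamics

**Gaussian network model (GNM).**  Each residue contributes one node at its
C-alpha; two nodes interact when closer than the cutoff `r_c` (default
**7.3 Å**, the classical GNM value for C-alpha networks).  The Kirchhoff
matrix is the graph Laplacian of this contact graph, scaled by a uniform
spring constant `gamma` (default 1; it only sets the overall scale and
cancels in every quantity we report).  The model assumes isotropic,
Gaussian-distributed fluctuations about one equilibrium structure; it knows
nothing about side chains, solvent, or anharmonicity.

Eigen-decomposition gives modes ordered by eigenvalue.  One zero mode exists
per connected component (checked against an explicit graph-component count
at relative tolerance 1e-8).  The per-mode *mobility profile* is
`M_i = u_i^2 / lambda`, so slow (small-eigenvalue) modes dominate; the
cumulative profile over the `m` slowest nonzero modes (default **m = 10**)
is the global-mobility picture, and the captured-dynamics fraction is the
inverse-eigenvalue mass of those modes.  Mobility is kept unnormalized
internally; normalization to [0, 1] happens only in plotting, because the
scientific anchors (minima positions, captured fraction) are
normalization-independent.

**Hinge detection.**  The literature says only that hinges are "minima of
the global modes"; the operational definition here is ours: a hinge is a
*strict local minimum* within a `window` of ±5 residues that also lies below
the `percentile = 20` level of the profile.  Both knobs are exposed.  For
the synthetic two-lobe benchmark we score the *slowest-mode* profile: with
exactly two quasi-rigid lobes, mode 1 is the interdomain mode and its node
sits in the linker, whereas higher modes add intra-lobe deformations whose
minima sit at lobe cores.  For a real multi-domain protein the 10-mode
cumulative profile is the right object, and that is what `run_dynamics()`
uses.

**Anisotropic network model (ANM) and perturbation-response scanning
(PRS).**  The ANM Hessian uses the standard rank-1 super-elements along
inter-residue bonds, cutoff **13 Å** (a conventional ANM choice; the
upstream literature for this analysis does not state one, so it is exposed
as `anm_cutoff`).  Linear response gives displacements `dR = H^+ F`.  PRS
perturbs each residue in turn and records everyone's squared displacement.
Two compute paths exist and are tested against each other:

* *closed form* (default): the isotropic average over force directions is
  exactly `s_ik = ||G_ki||_F^2 / 3`, with `G` the Hessian pseudoinverse —
  exact and fast;
* *stochastic*: the original randomized protocol (unit forces in uniformly
  random directions, averaged over `m_trials`), retained as a validation
  mode.  At 4000 trials its max relative error on a 20-node fixture is a
  few percent — this is plain Monte-Carlo error, so it is seeded.

Rows of the map are normalized by the self-response (diagonal), making
entries relative responses; this removes the trivial "floppy residues
respond a lot" scaling and is what gives the map its directionality
(the raw closed-form map is symmetric).  Effectiveness (effector strength)
and sensitivity (sensor strength) are row and column means with the
diagonal excluded — self-response is not signal propagation.  Zero-mode
handling: the six smallest Hessian eigenvalues are discarded after
verifying they are below 1e-8 of the largest; fewer or more than six is an
error (it indicates degenerate geometry, e.g. dangling or collinear
nodes).

## Sequence conservation and coevolution

Alignments are handled in a 21-letter alphabet (20 amino acids + gap).
Sequence redundancy is corrected by identity-based weighting
(`identity_threshold = 0.8`): each sequence is weighted by the inverse size
of its 80%-identity neighbourhood, giving the effective count `M_eff`.
Following the conventions of the original methods, MIp, OMES and SCA run
unweighted by default (with a switch), while DI and PSICOV always weight.
Gaps are excluded (with renormalization) for entropy, MI, OMES and SCA, and
treated as the 21st state for DI and PSICOV — again matching each method's
home convention.

* **Shannon entropy** per column, in nats (base configurable), over the 20
  amino acids.
* **MIp**: mutual information with the average product correction
  `S'(i,j) = S(i,j) − S̄_i S̄_j / S̄` (off-diagonal means), removing shared
  background/phylogenetic signal.  For L = 2 the correction degenerates and
  returns zeros with a warning.
* **OMES**: `sum_ab (N_obs − N_exp)^2 / N_valid` over the sequences ungapped
  at both columns, expectations from the same valid subset.
* **SCA**: of the several published formulations we implement the
  deterministic positional-weight form: conservation weights
  `phi_i(a) = |log(f(1−q_a)/((1−f)q_a))|` against a background amino-acid
  distribution, scores as the Frobenius norm of the phi-weighted covariance
  tensor.  This variant needs no perturbation subalignments and is exactly
  reproducible; the variant id is recorded in the result's parameter
  record.  `phi` is regularized by a 3% mixture with the background so
  boundary frequencies stay finite.
* **DI** (mean-field direct coupling analysis): 21-state frequencies with
  pseudocount fraction **0.5** (the standard mean-field choice), connected
  correlations on the 20-state reduction (gap is the gauge state), couplings
  from the negative inverse, and per-pair direct distributions fitted by
  marginal matching (tolerance 1e-4, the customary value; the fixed-point
  iteration is cheap but can need tens of thousands of iterations for
  extreme couplings, hence the high default `max_iter`).  DI is the KL
  divergence of the fitted two-site model from independence; note it is not
  bounded by the empirical mutual information.
* **PSICOV-style scoring**: sample covariance of the 21-state indicators
  (states never observed at a column are dropped — they carry no signal and
  only make the matrix singular), shrunk toward its diagonal until positive
  definite, then a sparse precision matrix via an L1-penalized inverse
  covariance (graphical lasso, implemented in C++ as block coordinate
  descent with warm starts; convergence is declared on the relative change
  of the covariance estimate, tolerance 1e-3, and non-convergence is an
  error, not a silent result).  The penalty default is `rho = 0.005`;
  block L1 norms over amino-acid states give the pair score, followed by
  APC.

Null behaviour worth knowing: mean-field DI on independent columns is *not*
numerically zero — inverting a finite-sample correlation matrix leaves
coupling noise of order 0.01–0.1 nats at `M_eff` of a few hundred.  The
tests therefore assert separation (planted pairs score several-fold above
the whole null matrix) and the strong-pseudocount limit, not an absolute
near-zero null.

## Interdomain synthesis

The interdomain submatrix takes rows from one residue group and columns
from the other.  For DnaK the NBD side is residues 1–388 and the SBD side
393–604, giving the 388 × 212 = 82,256 candidate pair space; note the NBD
side deliberately includes residues 1–2, which precede subdomain IA in the
subdomain partition but belong to the NBD by the conventional boundary —
this is what makes the printed pair count come out.  The pair-space
denominator convention (full group sizes vs mapped columns only) is
configurable; full group sizes is the default because that is how the
printed tables count.

Per-method ranking keeps the top `fraction = 0.0006` (0.06%) of the pair
space, `k = ceiling(fraction * n_pairs)` — 50 for DnaK, matching the
"top-ranking 50" convention — with ties broken by residue ids and an
all-tied block flagged degenerate.  The consensus keeps pairs supported by
at least `min_methods = 2` methods.  Whether ranking runs on raw or
APC-corrected matrices is a method property here: MIp and PSICOV are
APC-corrected by construction (their published forms), OMES/SCA/DI are
ranked raw; each result's parameter record says which.

Cumulative interdomain coevolution propensity is the row/column sum of the
submatrix — a per-residue measure of how much interdomain signal a residue
carries.  Structural annotation classifies pairs by minimum heavy-atom
distance ≤ 4.5 Å ("contact"), C-alpha distance > 30 Å ("distant"), or
in between ("neighboring_no_contact"), the conventions of the printed
contact table; both distance conventions are exposed because the printed
table does not say which it used.

## Synthetic generators: what they emulate, what they do not

`make_two_domain_structure()` emulates the NBD–linker–SBD architecture:
two compact lobes (random sequential packing on a jittered 3.8 Å cubic
lattice — guarantees compactness, self-avoidance and connectivity cheaply)
joined through one-bead stalks by an extended linker (default 4 beads, the
Hsp70-linker length).  The linker is a gentle helix rather than a straight
segment: rank-1 ANM springs along a collinear chain would have zero
transverse stiffness and create spurious zero modes.  Interior linker beads
touch only their chain neighbours at the GNM cutoff, so the hinge is planted
by construction.  The generator does not emulate secondary structure,
side-chain packing, or realistic domain shapes — passing the hinge benchmark
shows the detector finds connectivity bottlenecks, not that it understands
proteins.

`make_coupled_msa()` emulates the statistical structure the scorers assume:
independent background columns from per-column Dirichlet(0.5) profiles
(diverse but uneven amino-acid usage), planted pairs drawn from
permutation-matched joint tables (with probability `coupling` the second
state is a fixed bijection of the first — default coupling 0.75 over 4
states gives ~0.7 nats, comfortably above the 0.5-nat planting floor used
in the recovery suite), optional conserved columns and appended duplicate
groups to exercise weighting.  The realized mutual information of every
planted pair is computed from the sampled counts and written into the truth
record, so tests never re-derive truth from the fixture.  The generator
does not emulate phylogeny (sequences are exchangeable draws), alignment
errors, or contact-map-coupled evolution; consequently the null-calibration
results below speak to sampling noise, not to phylogenetic confounding.

Every generator is a pure function of its arguments and seed (RNG state is
saved and restored), and truth records serialize to JSON next to the
fixtures.

## Problem sizes and runtimes

The test-suite conditions are: planted-coupling recovery at L = 100 columns,
N = 2000 sequences, 10 planted pairs; null calibration at L = 50, N = 1000,
20 seeds; hinge recovery on 50 dumbbells of 25–45 beads per lobe; PRS
convergence at 4000 trials on a 20-node fixture.  These sizes keep the full
suite in the minutes range on one CPU while leaving every statistic in its
asymptotically meaningful regime (PSICOV's graphical lasso on the
2100-dimensional indicator covariance is the dominant cost).

## Known limitations

* **Correlated scorers under the null.**  All five coevolution statistics
  are deterministic functions of the same pairwise count tables, so under
  an independent-column null their extreme order statistics coincide far
  more often than independent methods would (top-1 coincidence between at
  least one method pair in roughly a quarter to a half of null alignments at
  k = 1, e.g. MIp and OMES selecting the identical pair).  A ≥ 2-method
  consensus on null data is therefore *not* reliably empty at very small k.
  We examined a robust-z "significance" flag (null maxima reach z ≈ 11,
  planted pairs z ≥ 50): the separation is real but the null tail is broad
  enough that any cutoff rescuing near-perfect emptiness would sit inside
  the null distribution itself, so no such flag is applied by default.
  Practical reading: treat small-k consensus hits as candidates whose
  per-method scores must be inspected, not as significance calls.
* **DnaK reference data are not bundled.**  The crystal structure of
  ATP-bound DnaK (PDB 4B9Q) and the Pfam PF00012 alignment must be supplied
  by the user (see `?dnak_structure_file`); the DnaK-specific checks and
  report fields activate when they are present.
* **Mean-field DI nulls.**  See above — DI backgrounds of 0.01–0.1 nats at
  moderate `M_eff` are expected and are handled by ranking, not by absolute
  thresholds.
* The ANM cutoff, PRS normalization and trial count are conventions chosen
  here (13 Å, self-response row normalization, closed form); results
  reported as rankings are robust to these, absolute response magnitudes
  are not.
* `alpha` (Dirichlet concentration), lobe packing, and all other generator
  defaults are fixed study conditions; changing them changes the meaning of
  the benchmark numbers.
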