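---
title: "Methods: pool-based protein model refinement at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-based protein model refinement at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refine2lite)
```

This vignette records the models, algorithms and numerical decisions behind
`refine2lite`, in the order the pipeline runs them. It states no empirical
result that the test suite does not itself compute.

## 1. The refinement problem and the overall procedure

The input is a single protein chain in PDB format, at most 300 residues,
with no internal missing residues (`validate_input()` reports
`OVER_LENGTH` and `CHAIN_BREAK`; the library warns on over-length and
refuses broken chains, while the CLI refuses both — the length cap is an
operational limit, not an algorithmic one). The task is *refinement*: the
input is assumed to be a largely correct model whose errors are local —
misplaced loops, frayed termini, slightly shifted secondary-structure
elements — and the goal is to move it closer to the (unknown) true
structure without destroying what is already right.

The procedure is a pool-based stochastic search:

1. estimate residue-wise error and mark unreliable local regions (ULRs);
2. optionally thread the sequence onto homolog structures and harvest
   non-ULR backbone patches;
3. seed a pool of `capacity` (48) structures by rebuilding the ULRs;
4. for `cycles` (5) iterations, generate `trials_per_member` (10)
   operator perturbations of every pool member (480 trials/cycle),
   relax each under restraints, and let low-energy trials replace
   structurally similar higher-energy pool members;
5. re-score all generated structures (2400 by default) *without*
   restraints, and report the 10 lowest after a final full-atom polish.

Everything is deterministic given the master seed: one integer fans out
to per-member, per-trial and per-operator seeds through a fixed
multiplicative splitting scheme (`split_seed`), and all stochastic code
runs under scoped RNG state, so two runs with the same configuration are
bit-identical.

## 2. Residue-wise error estimation

Three per-residue signals feed a linear model:

* **RMSF** (Å): the input is relaxed `rmsf_n_runs` (24) times in
  noisy-minimize mode (seeded Gaussian coordinate kicks and side-chain
  repacks every `sidechain_repack_every` steps between minimization
  segments). The end structures are superposed onto their iteratively
  refined CA mean; RMSF is the per-residue root-mean-square deviation
  from that mean. Flexible/strained regions fluctuate more.
* **FRAG** (degrees): for each window position, the minimum over library
  fragments of the mean circular |Δphi| + |Δpsi| difference; a residue's
  score averages the windows covering it. Backbone conformations unlike
  anything in a fragment library are suspect.
* **MSA** (dimensionless): per position, the sign-flipped mean of the 20
  PSSM components, optionally smoothed by a centred moving average.
  The sign convention — larger value, less conserved, larger expected
  error — is this package's contract. The alternative reading (the native
  residue's own component) is exposed as `msa_score(component =
  "native")`.

Predicted error is `intercept + w_rmsf·RMSF + w_frag·FRAG + w_msa·MSA`,
clamped at zero. The shipped defaults (0, 1.0, 0.05, 0.3) put the three
signals on comparable scales given their units (Å, tens of degrees,
units of PSSM score); they are deliberately simple because the original
fitted values are unpublished, and `fit_error_model()` (ordinary least
squares via `stats::lm`) lets a user recalibrate on any data with known
true errors.

ULRs are maximal runs of residues with predicted error above a threshold
(default: mean + 1 SD of the profile), with runs separated by at most
`ulr_merge_gap` (1) below-threshold residues merged and runs shorter
than `ulr_min_len` (3) discarded. Terminal residues receive no special
treatment: a short terminal run is discarded like any other (the merge
example in `detect_ulrs()`'s documentation fixes this interpretation).

## 3. Geometry engine

Torsions follow the standard conventions (phi: C(i−1)–N–CA–C, psi:
N–CA–C–N(i+1), omega: CA–C–N(i+1)–CA(i+1)); rebuilding uses NeRF chain
extension with ideal bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å, and the angle set in `bb_geom()`). Omega is held at 180° when
rebuilding — no cis-proline sampling. Superposition is Kabsch with the
determinant correction; its optimality is cross-checked in the tests
against a quaternion-parametrized numerical optimizer.

**Triaxial loop closure (TLC).** Every backbone move re-closes the chain
analytically. Given fixed N- and C-side anchors and fixed torsions at all
non-pivot loop residues, the six free torsions (phi/psi at three pivots)
are solved by the classic reduction: the middle pivot's CA lies on the
circle intersecting two spheres (the two virtual CA–CA distances to the
outer pivots are conformation-invariant); for each circle point the outer
bond-angle constraints yield at most 2×2 discrete branches in closed form
(a sinusoidal equation each), and the remaining N–CA–C bond-angle
constraint at the middle pivot is a one-dimensional root-finding problem
in the circle angle. Numerical choices:

* the circle is scanned on an `n_scan` grid (360 for direct calls, the
  `tlc_grid` config value, default 240, inside operators) with the
  residual evaluated for all grid points at once (vectorized);
* roots inside a grid interval are bracketed by nested 33-point scans and
  polished by secant iteration;
* solution curves pass *between* sinusoid branches where a branch's
  discriminant vanishes, so intervals where a branch appears or vanishes
  are handled specially: the existence edge is located by nested scans
  and a sign change against the near-seam value is root-found. Without
  this, roots hiding at branch seams are systematically missed;
* every candidate is verified by a full NeRF rebuild; solutions are kept
  only if all three anchor atoms match to `gap_tol` (1e-6 Å), and
  duplicates from adjacent branches are removed by rounding the six pivot
  torsions to 1e-3 degrees.

Pivot choice (start/middle/end of the span) follows common practice; the
original protocol does not specify it. When closure has no real solution
the caller re-draws (operators) or widens the span (threading) — an
insertion between two rigid, adjacent template anchors is frequently
unreachable for a minimal 3-residue span, so the threading module absorbs
flanking aligned residues progressively (up to 4) until closure succeeds.

Secondary structure is assigned from torsion bins (H: phi ∈ (−100,−30),
psi ∈ (−80,−5); E: phi ∈ (−180,−80), psi ∈ (80,180) ∪ (−180,−170);
singletons smoothed to C) rather than hydrogen bonding: it needs no DSSP
dependency and is exact on the ideal fixtures.

## 4. Energy model and relaxation

The published protocol relaxes trials with short restrained molecular
dynamics under a full physics force field. That force field is not
public and true MD is out of scope here, so `refine2lite` substitutes a
*documented surrogate*: this is the package's declared energy contract,
not a claim of equivalence.

`evaluate_energy()` terms (each reported after weighting):

| term | form | default weight |
|---|---|---|
| steric | Σ (1 − r/r₀)² for non-bonded pairs r < r₀ (r₀ = vdW radii sum) | 1.0 |
| hbond | −Σ exp(−(r−3.0)²/2σ²) over backbone N–O pairs, σ = 0.3 Å | 0.5 |
| torsion_stat | per-residue −log f from a coarse Ramachandran bin table | 0.5 |
| compactness | (Rg − 2.2·L^0.38)² | 0.05 |
| restraint | see below | 1.0 |

Restraints are built from the input structure (or, in oracle test mode,
from a reference): one CA anchor per residue, all CA–CA pairs with
sequence separation ≥ 4 and distance < 12 Å, and all N–O pairs with
distance < 3.5 Å and separation ≥ 2. Penalties are harmonic `d²` or
Lorentzian `d²/(d²+c²)` with `lorentz_c = 3` Å; the Lorentzian is bounded
with a gradient that vanishes at large deviation (checked numerically in
the tests), which is the mechanism that permits wider sampling than the
harmonic form. Within each class the worst `ceil(f·N)` penalties
(`neglect_fraction`, default 0.10; 0.05 in conservative mode) are dropped,
re-evaluated at every call. CA anchors are evaluated after Kabsch
superposition of the current CA trace onto the anchors; their analytic
gradient treats the rotation as fixed, which the envelope theorem makes
exact for full-set harmonic anchors and approximate otherwise — the
gradient-vs-finite-difference check runs in the exact regime.

`relax()` replaces MD with L-BFGS minimization of the smooth terms plus
distance-harmonic bonded surrogates (bonds, 1-3 distances derived from
the ideal angles, a 1-4 CA–CA distance that holds trans omega, and
current-geometry pairs within side chains). Angle/dihedral terms are
deliberately avoided: pure distance harmonics have trivial exact
gradients and keep bond lengths within 2% of ideal, which is the whole
contract. The Ramachandran term is piecewise constant, so it is excluded
from the minimized objective; because of that, descent is enforced by a
monotone safeguard — if the full restrained total did not decrease, or
the chain broke, the input is returned unchanged. The three relaxation
contexts map the published 14.4 : 3.0 : 1.2 ps schedule onto step counts
1200 : 250 : 100 (`steps_long : steps_standard : steps_short`); only the
ratios are contractual, and toy configurations scale all three down
together.

## 5. Operators

All six operators are deterministic given the context seed, preserve the
sequence, return structures with finite coordinates, and flag a no-op
(rather than throwing) when sampling fails, letting the trial loop
re-draw up to five times.

* **Fragment assembly**: window chosen with probability proportional to
  its mean predicted error; torsions replaced from a random fragment;
  TLC re-closure (terminal windows rebuilt freely).
* **Loop modelling**: a ULR's torsions are either circularly interpolated
  toward a random pool partner (`mix_coeff`) or perturbed by Gaussian
  noise (`mutate_sigma` 30°); TLC re-closure. Trials made by this
  operator get the short relaxation schedule.
* **Side-chain perturbation**: greedy repack on the chi1/chi2 grid
  {−60, 60, 180}° minimizing local steric clash; the backbone is
  bit-identical. Coarse (backbone+CB) models make it a no-op.
* **Normal-mode perturbation**: one of the `n_low_modes` (10) lowest
  non-rigid elastic-network modes (CA springs within `enm_cutoff` 10 Å)
  scaled to RMS amplitude `nm_amplitude` (1 Å); residues ride rigidly on
  their CAs, then covalent geometry is restored by a direct minimization
  under displaced-CA anchors (`nm_relax_steps`). This geometric
  restoration replaces literal torsion refitting; the operator's
  contracts (zero amplitude is the identity, exact pre-rebuild RMS
  amplitude, displacement within the chosen mode's span) are unaffected.
* **Structure hybridization**: a random patch from the threaded-homolog
  library is superposed via two flanking anchor residues per side, the
  span replaced, and 4-residue junction loops re-closed by TLC (terminal
  sides rebuilt freely).
* **Secondary-structure perturbation**: a random H/E chunk (≥ 4 residues)
  is rotated up to `ss_max_rot` (10°) about its centroid and translated
  up to `ss_max_trans` (1 Å); junctions re-close by TLC; chunk-internal
  geometry is exactly preserved.

Operator selection is uniform over *applicable* operators (no side
chains, no patches, or no ULRs zero the corresponding weights); the
original publishes no schedule.

## 6. Pool management and final selection

Trials are processed in ascending restrained energy — the published rule
("each low-energy trial replaces …") does not fix an order, and ascending
order makes it deterministic. A trial first looks for pool members within
`closeness_radius` CA-RMSD: if any exist it may only replace the
highest-energy such member (diversity preservation); otherwise it may
replace the pool's overall worst. Both replacements require strictly
lower energy, so the pool minimum never increases. The radius widens
linearly from `closeness_start` (0.5 Å) to `closeness_end` (2.0 Å) across
cycles — "gradually increased" made concrete.

Final selection ranks **all** generated trials by restraint-free energy,
takes the 10 lowest, applies a full-atom polish (side-chain repack plus
unrestrained minimization), and re-sorts. Trials are ranked as stored
(no extra relaxation before ranking); whether the original re-relaxes
before the final scoring is unstated.

## 7. The synthetic world

`make_refinement_case()` builds everything the pipeline consumes:

* **native**: two ideal antiparallel helices at 10.5 Å separation joined
  by a TLC-closed coil loop — compact (CA contacts under 12 Å across the
  helices feed the pair restraints), clash-free, single chain. The free
  join torsions at the helix ends and the helix-2 placement are found by
  a deterministic grid search, so the fixture is reproducible;
* **start**: torsion-space Gaussian noise, weighted 4× on the loop and
  3× on the termini, scaled by bisection until the CA-RMSD to the native
  lands within [0.8, 1.2] × the target (default 2.5 Å) — the error is
  planted where refinement servers expect it;
* **fragment library**: the native's own 7-residue torsion windows plus
  30 random-coil fragments, so the FRAG score is low where the start
  matches the native and high in the perturbed loop;
* **PSSM**: uniformly high scores at helix positions and low at the loop
  (±, small seeded noise). Real conserved columns have one large positive
  and many negative components; the planted version instead shifts whole
  rows so that the row-mean convention sees helix positions as conserved.
  It is a signal-direction fixture, not a statistical model of PSSMs;
* **homologs**: two perturbed natives with identity alignments — one at
  1.5 Å (above the TM-score 0.5 filter for these sizes), one at 8 Å
  (below it); the pair calibrates the threading filter.

What a green test on this world establishes: the machinery — error
signals, closure, operators, pool bookkeeping, restraint behaviour,
recovery under informative restraints — functions as specified. What it
does not establish: refinement accuracy on real predictions, where error
signals are noisier, fragment libraries are genome-scale, homologs are
remote, and the energy surrogate faces real physics. The published
benchmark numbers live at that scale and are intentionally out of scope.

## 8. Degenerate inputs, tie-breaks, tolerances

* Chains shorter than 16 residues clamp the TM-score d0 to 0.5 Å with a
  warning; GDT-style maximizations become exhaustive over CA subsets for
  chains of ≤ 12 residues (exactness over speed at toy sizes).
* `detect_ulrs` ties: runs are merged left-to-right; equal-error plateaus
  follow the strict `> threshold` rule.
* TLC keeps at most one of two numerically identical solutions (pivot
  torsions rounded to 1e-3°); unreachable anchors return an empty list.
* `perturb_structure` fails loudly after 50 bisection steps if the target
  RMSD is unreachable (short chains saturate below ~6-7 Å).
* Multi-model PDB files: first model only; MSE is read as MET; other
  non-standard residues are rejected.
* The `update_pool` closeness test uses superposed CA-RMSD, so uniform
  translations never count as structural novelty.

## 9. Known limitations

* The energy is a surrogate; its absolute values are meaningful only
  relative to one another within a run.
* The Lorentzian/neglected CA-anchor gradient is approximate (fixed
  superposition); L-BFGS tolerates this, and the descent safeguard
  catches the rare failure.
* No cis peptide bonds, no backbone-dependent rotamers, chi1/chi2 only.
* LDDT omits the stereochemistry penalty of the full definition;
  the clash score plus Ramachandran-favored fraction stand in for
  composite stereochemical quality scores and are reported side by side,
  never under the composite's name.
* Threading assumes the alignment is right; it rebuilds geometry, not
  alignments.
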