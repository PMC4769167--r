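---
title: "Collective-motion gate-opening analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective-motion gate-opening analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatemodes)
```

## The scientific problem

CLC transporters are homodimeric antiporters that exchange two Cl⁻ for one
H⁺. Equilibrium molecular-dynamics trajectories of such a protein, even
hundreds of nanoseconds long, sample only fluctuations around the starting
(crystallographic) conformation; the actual opening of the Cl⁻ pathway gates
is too slow to observe directly. Essential-dynamics analysis works around
this: the fluctuations are decomposed into collective modes (principal
components of the Cα coordinate covariance), the reference structure is
deformed along each dominant mode by a fixed, larger-than-sampled amplitude,
and each mode is scored by whether that deformation widens the residue pairs
lining a gate. Comparing the per-segment counts of gate-opening modes between
two conditions — for instance a wild-type transporter and one carrying an
inter-subunit cross-link — asks whether the perturbation selectively dampens
the motions that open a particular gate.

`gatemodes` implements this pipeline end to end: structure/trajectory IO,
rigid-body (Kabsch) alignment, per-segment covariance PCA, fixed-RMSD mode
deformation with Δr gate scoring, exact rank-sum comparison of conditions,
plus a sphere-fitting pore-radius profiler for interpreting gate geometry in
static structures, and a synthetic homodimer generator that makes every stage
testable against a known generative model.

## The model and its steps

Let $X_n \in \mathbb{R}^{M\times 3}$ be the Cα coordinates of the selected
atoms in frame $n$ of an aligned trajectory segment. The pipeline computes:

1. **Covariance.** The population covariance of the $3M$ flattened
   coordinates about their mean,
   $c_{ij} = \langle (x_{in} - \langle x_{in}\rangle)(x_{jn} - \langle
   x_{jn}\rangle)\rangle$. Alignment (iterated superposition onto the running
   mean) must precede this step, otherwise rigid-body tumbling dominates the
   spectrum.
2. **Modes.** Orthonormal eigenvectors $R_k$ of the covariance, ranked by
   eigenvalue. By default the top `k_max = 20` are retained; their summed
   eigenvalues over the trace give the fraction of motion they capture.
3. **Deformation.** For each mode, $X' = X_0 \pm A R_k$ with
   $A = \mathrm{RMSD}\cdot\sqrt{M}$, so the deformed structure sits at exactly
   the target RMSD (default 3.5 Å) from the reference $X_0$ — for
   $M = 538$ this gives $A = 81.18$ Å. No re-superposition is applied: the
   displacement *is* the deformation.
4. **Gate scoring.** For a gate pair $(i, j)$,
   $\Delta r = |x'_i - x'_j| - |x_i - x_j|$. A mode *opens* the pair when
   $\Delta r$ strictly exceeds the threshold (default 1.5 Å) in either
   deformation direction (sign policy `"both"`).
5. **Segments.** After discarding the first 50 ns, the trajectory is split
   into three equal time blocks, crossed with the two subunits: six segments,
   each analysed independently (covariance → modes → counts).
6. **Comparison.** Per gate pair, the two six-segment count vectors are
   compared with an exact Wilcoxon–Mann–Whitney test.

### Assumptions

* The selected atoms (transmembrane Cα) capture the architecture whose
  collective motions matter; side chains are not modelled.
* Fluctuations around the reference are informative about larger-amplitude
  motions along the same directions (the essential-dynamics extrapolation).
  The fixed-RMSD deformation is a linear extrapolation; it does not preserve
  stereochemistry and is meaningful only through the distance changes it
  induces.
* Segments are treated as exchangeable replicates for the rank-sum test.
  Time blocks from one trajectory are not strictly independent; the exact
  test is valid under the randomization null but the effective sample size
  is optimistic if the blocks are strongly correlated.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k_max` | 20 | modes | modes retained per segment |
| `mode_select` | `"count"` | — | `"count"` = fixed `k_max`; `"variance"` = smallest $k$ reaching `variance_target` |
| `variance_target` | 0.75 | fraction | coverage target for `"variance"` selection |
| `target_rmsd` | 3.5 | Å | deformation RMSD per mode |
| `threshold` | 1.5 | Å | Δr above which a mode counts as opening |
| `discard_ns` | 50 | ns | equilibration discarded before segmenting |
| `n_blocks` | 3 | — | time blocks per subunit |
| `sign_policy` | `"both"` | — | which deformation directions may open a pair |
| `scope` | `"segment"` | — | `"segment"` or `"whole"`-trajectory PCA |

The defaults are the standard study parameters of this kind of analysis; the
deformation RMSD (3.5 Å) is large relative to thermal fluctuation amplitudes
but small enough that the linear extrapolation stays interpretable, and the
1.5 Å Δr threshold is roughly the widening needed to make a sterically
closed gate passable.

### Design choices where the procedure was genuinely open

* **Sign policy.** The deformation formula carries ±, and a collective
  motion along $-R_k$ is the same motion. The default therefore counts a
  mode if *either* direction opens the pair; `"plus"`/`"minus"` are
  available, and counts under `"both"` always dominate either single-sign
  count.
* **Strict threshold.** Counting uses $\Delta r > 1.5$, not ≥.
* **Covariance normalisation.** Population (1/N). The eigenvectors — the
  only quantity consumed downstream — are identical under 1/(N−1).
* **Remainder frames.** "Divided evenly" leaves a remainder for most frame
  counts; remainder frames go to the final blocks (83/83/84 for 250 frames).
* **Segment vs whole-trajectory PCA.** Both are implemented (`scope`).
  Segment-level is the default: each (subunit × block) segment gets its own
  covariance and modes, and the six per-segment counts feed the test. The
  `"whole"` scope computes per-subunit modes from the whole post-discard
  trajectory and yields one count per subunit.
* **Tie handling in the exact test.** Opening counts are small integers, so
  ties are the norm. The test uses mid-ranks and computes the exact
  permutation distribution *conditional on the observed tie pattern* (via an
  integer convolution over doubled mid-ranks — equivalent to enumerating all
  $\binom{n+m}{n}$ assignments, which the test suite does explicitly as an
  oracle). The two-sided p is twice the smaller tail, capped at 1. For
  $n + m > 30$ a tie-corrected normal approximation is used and flagged.
  Under the six-vs-six design the smallest attainable two-sided p is
  $2/\binom{12}{6} = 2/924 \approx 0.002$.

## The synthetic-data generator

`make_dimer_template()` builds a C2-symmetric dimer of ideal-helix bundles
(default: two 25-residue helices per 50-atom subunit, helix axes 8 Å apart,
subunit centroids 24 Å apart). `default_planted_model()` equips it, per
subunit, with five orthonormal planted modes: one **gate mode** (amplitude
3 Å — the dominant motion) and four smooth **background modes** (2.5, 2,
1.5, 1 Å), plus isotropic coordinate noise (σ = 0.1 Å) and mild rigid-body
jitter (≤3°, ≤1 Å). Frames are independent Gaussian draws along the modes —
PCA is distribution-free over frames, so temporal correlation would add
nothing to covariance-recovery tests while complicating block independence.

Mode construction is exact where it matters:

* All planted modes are projected orthogonal to the six rigid-body
  generators of their subunit, so alignment does not eat planted variance.
* Background modes are smooth low-order polynomial displacement fields
  pinned to **exactly zero** displacement at the gate and control pair
  atoms. A pure background deformation therefore changes neither measured
  pair distance at all.
* The gate mode is a smooth carrier (also pinned at the measured pairs)
  plus a small opening component that pulls the gate pair apart along its
  axis, with tapered displacement of sequence neighbours. With the default
  `opening_share = 0.01`, about 5.5% of the mode's displacement norm sits on
  each gate atom's axis component, giving a pure-mode
  $\Delta r \approx 2\cdot A\cdot 0.055 \approx 2.7$ Å at the study
  deformation ($A = 3.5\sqrt{50}$) — comfortably above the 1.5 Å threshold,
  but small enough that the slight mode mixing expected from
  finite-sample PCA does not push background modes over it.

### How dampening becomes detectable

`dampen(model, "gate", 1/3)` scales the gate-mode amplitude (3 → 1 Å), i.e.
its variance by 1/9, emulating a motion restricted by a cross-link. At fixed
deformation RMSD, a mode's Δr depends only on its *shape*, not its
amplitude, so a dampened-but-still-retained mode would be counted unchanged.
Detection instead operates through mode selection: with
`mode_select = "variance"` and the 75% coverage target, the undampened gate
mode (the largest eigenvalue, ~9 Å² of ~24 Å² total) is always among the
selected modes, while after 3× dampening (~1 Å² of ~16 Å²) the target is
reached by the three background modes alone and the gate mode drops out.
The per-segment counts on the target pair then fall from 1 to 0 while the
pinned control pair stays at 0 in both conditions — the same qualitative
signature as a cross-link that selectively cripples a gate-opening motion.
These expectations follow from the generative model's eigenvalues
(9, 6.25, 4, 2.25, 1 plus noise) and were derived before any test was run;
the test suite then verifies them by Monte Carlo (20 seeded replicate pairs
for detection, 500 for null calibration).

### What the generator does *not* emulate

Real MD trajectories have temporally correlated frames, anharmonic and
state-dependent fluctuations, solvent/lipid coupling, and collective modes
that are not exactly orthogonal localized fields. Passing the synthetic
tests demonstrates that the *estimator and statistic* behave correctly under
a model with known truth — not that a particular biological conclusion is
correct, and not that six time blocks of a single real trajectory are
independent samples.

## Pore-radius profiler

The profiler scores static structures, not trajectories. At each position
$z$ along the chosen axis (default: the dimer two-fold from
`twofold_axis()`, which for a membrane-protein dimer approximates the
membrane normal; origin at the central bound anion from
`central_anion_site()`), it finds the largest sphere centred in the slice
plane touching no atom:
$r(z) = \max_c \min_i (|c - a_i| - \mathrm{vdw}_i)$. The search is
deterministic: a 0.25 Å grid within ±2 Å of the previous slice's centre,
refined by Nelder–Mead. Seeding from the previous centre makes the profile
follow one connected pathway instead of hopping between cavities. Radii may
be negative (blocked) and are capped at 15 Å; slices with no nearby atoms
report the cap with a warning. Two vdW tables ship: the simple pore-profiling
set (`"hole"`: C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 Å) and Bondi
radii; absolute bottleneck values shift by up to a few tenths of an Å between
tables, which is why structure-based bottleneck comparisons carry a ±0.3 Å
tolerance. A Cl⁻ ion (radius ≈ 1.81 Å) needs $r(z)$ at least that large
along the whole pathway to pass.

## Numerical choices

* **Superposition** is the SVD-based Kabsch solution restricted to proper
  rotations (the smallest singular direction is flipped when the
  unconstrained optimum is a reflection), so chirality is never inverted.
  Collinear or degenerate coordinate sets are rejected as ill-conditioned.
* **Mean alignment** iterates align-to-running-mean until the mean moves
  < 1e-6 Å (at most 20 passes), making the result independent of frame
  order.
* **Eigen-decomposition** uses the symmetric path; tiny negative eigenvalues
  are clipped at zero. Eigenvector signs are arbitrary and all downstream
  statistics are sign-invariant (asserted by test).
* **Degenerate eigenvalues** make individual eigenvectors non-identifiable;
  every recovery test therefore compares subspaces (mean squared singular
  value of the cross-projection), never single vectors.
* **File formats.** The frame-matrix trajectory format carries 6 decimals
  and round-trips to 1e-6 Å; fixed-column PDB carries 3 decimals, so PDB
  round-trips are exact only to 5e-4 Å. Binary MD formats are deliberately
  not parsed; `trajectory_from_coords()` is the adapter seam for any reader
  that can produce a frames × atoms × 3 array.

## Problem sizes used by the shipped tests

The suite exercises the full pipeline at sizes chosen to make the
statistics sharp while keeping a full run of tests plus acceptance script in
the minutes range on one core: 50-atom subunits, 350-frame trajectories
(50 discarded, 3 × 100-frame blocks) for detection runs, 5000 frames for
covariance-recovery checks, 20 replicate seed pairs for detection and
500 replicates for null calibration (110-frame trajectories there; the
exactness of the rank-sum test makes its level independent of segment
length). The reconstruction of the transmembrane Cα selection that yields
M = 538 per subunit for the real protein is not shipped: the residue ranges
are not published, so the selection is a user input, and the package
documents the value only through the deformation relation
$A = 3.5\sqrt{538} = 81.18$ Å.

## Known limitations

* The deposited CLC crystal structures cannot be redistributed with the
  package; structure-based checks (interface Cα–Cα distances, cross-variant
  superposition RMSDs, pore bottlenecks) run only when the user supplies the
  PDB files (see `inst/extdata/pdb/README.txt`).
* The exact test's conditional-on-ties null is standard but not the only
  convention; published analyses rarely state theirs, so p-values may differ
  in the third decimal from other software when ties are heavy.
* The profiler's connectivity heuristic follows a single pathway; branched
  pores would need multiple seeded starts.
* `scope = "whole"` reduces the design to one count per subunit, which is
  too few segments for a meaningful rank-sum comparison on its own.
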