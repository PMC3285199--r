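---
title: "Validating protein force fields against NMR and folding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein force fields against NMR and folding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffvalidate)
```

## The problem

Molecular mechanics force fields are judged by whether the conformational
ensembles they generate reproduce experiment. ffvalidate implements the
analysis side of a three-part validation battery:

1. **Folded proteins.** Back-calculate backbone NMR observables from an
   ensemble of a stable folded protein (the classic test systems are
   ubiquitin and GB3) and quantify the deviation from measured values:
   scalar couplings via Karplus relations, residual dipolar couplings (RDCs)
   via an alignment-tensor fit and the Q factor, and Lipari–Szabo-type
   order parameters from internal autocorrelation functions.
2. **Peptide propensities.** Helical fraction of an alanine-rich 15-mer
   and folded fraction of a β-hairpin decapeptide as functions of
   temperature (melting curves), the latter assigned with a dual-cutoff
   RMSD scheme.
3. **Folding.** Count folding and unfolding events of two fast folders
   (an α-helical villin headpiece variant and a β-sheet WW domain variant)
   in long trajectories run near the melting temperature, again with
   segment-wise dual-cutoff detection.

Each test is condensed to an integer score 0–2 (0 = reasonable agreement,
2 = severe discrepancy) and the three scores are summed to a 0–6 total per
force field; plotting totals against publication year asks whether force
fields have improved over time.

The package does **not** run molecular dynamics. It consumes conformational
ensembles (multi-model PDB as the interchange format) and experimental
tables, and ships synthetic generators with known ground truth so that
every stage of the analysis can be validated end to end without
trajectories.

## Geometric substrate

Ensembles are plain containers: an atom table (PDB atom names, 1-based
author residue numbering) plus an `n_atoms × 3 × n_frames` coordinate
array. Multi-model PDB I/O is delegated to bio3d. Two design rules worth
stating:

* **Author numbering is preserved** and all residue ranges are inclusive in
  that numbering, so segment definitions like "residues 3–31" read exactly
  as printed in the structural literature. Alternate locations other than
  blank/'A' are dropped; insertion codes are rejected with an error rather
  than silently renumbered.
* **Superposition** uses the Kabsch SVD algorithm with the determinant
  correction (proper rotations only, collinear selections rejected). The
  test suite validates it against an independently implemented quaternion
  (Horn) oracle on a thousand random instances; the two agree to better
  than 10⁻⁸ Å.

Backbone dihedrals follow the IUPAC sign convention with range
(−180°, 180°], computed by a vectorized atan2 formula and cross-checked
against bio3d's torsion code. `build_backbone()` constructs idealized
geometries from internal coordinates (natural-extension placement with
Engh–Huber-like bond lengths/angles); it exists so that tests and
generators have exact known-answer structures, not to model real peptides.

Experimental structures usually lack amide hydrogens;
`reconstruct_amide_h()` places H 1.01 Å from N opposite the
CA/C(i−1) bisector (ideal planar amide) and flags the residues it touched.

## Back-calculated observables

**Scalar couplings.** \(J(\phi) = A\cos^2(\phi+\delta) +
B\cos(\phi+\delta) + C\), evaluated per frame and averaged. Because the
relation is linear in its trigonometric terms, averaging the terms first
would give the identical ensemble mean; we average J per frame for
clarity. Karplus coefficients are configuration data, not constants of the
method: the defaults in `default_karplus()` are transcribed from commonly
used published calibrations for the four backbone couplings (HNHA, HNCO,
HNCB, HACO), and every report records the parameter set used. Agreement
with experiment is the RMS deviation over rows matched on
(residue, coupling type); unmatched rows are listed, never silently
dropped, and never imputed.

**RDCs.** For internuclear unit vector *b* under alignment described by
the traceless symmetric Saupe tensor *S*, \(D = s\, b^\top S b\) with the
pair-specific maximal coupling absorbed into the scale *s*. We fit a
single tensor per alignment medium by linear least squares over the five
independent tensor components, using the ensemble-averaged normalized
dyadic ⟨b bᵀ⟩ after superposition. Averaging the dyadic (rather than
fitting per-frame tensors) matches the ensemble-versus-experiment design
and keeps the fit linear; fewer than five usable RDCs, or degenerate bond
directions, raise an under-determined error rather than returning a
meaningless fit. Agreement is the Q factor
\(Q = \mathrm{rms}(D_\mathrm{calc} - D_\mathrm{exp}) /
\mathrm{rms}(D_\mathrm{exp})\) — the simplest variant of the published
definition, without rescaling by a theoretical axial component. Refitting
the tensor makes Q invariant under global rotation of the ensemble, which
the tests verify.

**Order parameters.** The internal autocorrelation function
\(C(t) = \langle P_2(\mu(\tau)\cdot\mu(\tau+t))\rangle\) of each residue's
N–H vector is estimated over all overlapping time origins after
superposing frames onto a reference to remove overall tumbling (which
atoms define the superposition is configurable; the default is all
backbone heavy atoms, since the analysis targets rigid, folded systems).
S² is read off as the mean of C(t) in a lag window around the experimental
rotational correlation time τ_c — τ_c is user input, never estimated from
the ensemble, and the window half-width defaults to ±20 % of τ_c because
"close to τ_c" is otherwise under-specified. Estimates are clipped to
[0, 1] with a warning.

**Standard errors.** Frames along a trajectory are strongly
autocorrelated, so each agreement metric's SEM comes from contiguous block
averaging (default 5 blocks, each block re-analyzed independently
including its own tensor refit): SEM = sd(block estimates)/√n. Constant
blocks give SEM = 0 exactly.

## Conformational states

**Helicity.** A residue is helical in a frame iff (φ, ψ) falls in a
rectangular helical basin — default φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°] —
and belongs to a run of ≥ 3 consecutive in-box residues. The literature
definitions this emulates are cooperative (an isolated helical residue is
not a helix); box and run length are configurable and recorded. Terminal
residues with undefined dihedrals are never helical and break runs. The
helical fraction averages the indicator over frames and assignable
residues.

**Dual-cutoff state assignment.** The detector walks per-segment Cα-RMSD
series: a frame where *all* segments drop strictly below their fold
thresholds triggers the folded state; all segments strictly above their
unfold thresholds triggers unfolded; otherwise the previous state
persists. The hysteresis gap suppresses spurious recrossings that a single
cutoff would count as events. Built-in presets carry the segment
definitions for the three benchmark systems: villin (reference 2F4K;
3–31/1.2 Å, 3–18/0.9 Å, 14–31/0.9 Å folding, 5.0/4.6/2.5 Å unfolding), the
WW domain (reference 2F21; 2–33/2.0 Å, 8–22/1.1 Å, 12–18/0.6 Å,
19–30/0.9 Å folding, 7.0/5.8/1.8/3.8 Å unfolding) and the single-segment
hairpin criterion (1.0 Å fold / 4.0 Å unfold versus the NMR structure).

Two interpretive choices were genuinely open and are fixed as follows:

* *Simultaneity* is applied at the frame level for both folding and
  unfolding in every multi-segment system (the printed criteria state it
  explicitly only for one system's unfolding).
* *Initial state*: frames before the first threshold crossing are
  `undetermined` — folding benchmarks start unfolded by construction, but
  the detector must not assume it. The first crossing establishes the
  state without recording an event; events are counted only on
  folded ↔ unfolded transitions. Undetermined frames are excluded from
  the fraction-folded denominator (and counted in the report). The same
  hysteresis persistence defines the folded fraction between the cutoffs.

Event lists therefore alternate strictly and |n_fold − n_unfold| ≤ 1 by
construction — both are asserted property-style in the tests.

## Score cards

Per-test scores are summed to a 0–6 total; ranking is ascending with
competition ties (tied force fields share the minimum rank). The published
per-test triples are explicitly subjective, so they ship as a packaged
fixture (`ff_score_fixture()`, including each force field's
most-recent-correction year) and are never rederived from data.
`apply_rubric()` offers a clearly labelled reproducible alternative: two
strictly increasing cut-points per test map a continuous badness metric to
{0, 1, 2}, boundary values going to the lower class. The default
cut-points are artifact-defined (the original scoring printed none) and
every rubric output records its version. The year trend is a Spearman rank
correlation; on the packaged fixture it is strongly negative (newer force
fields score better), reproduced by `analysis/04_scorecard.R`.

## Synthetic generators and what they do (not) show

Every generator takes a mandatory seed and is byte-reproducible.

* **Two-state traces** sample a continuous-time Markov chain with
  exponential dwell times, discretize at the frame interval, and emit
  per-segment RMSD as state level plus Gaussian noise (levels directly,
  not coordinates — the detector consumes RMSD series). Ground truth is
  the discretized state sequence; transitions shorter than a frame are
  invisible to any frame-based detector and are likewise absent from the
  truth. With equal rates 1/T over a 10 T horizon the expected event count
  is ≈ 5 fold + 5 unfold (transition times form a Poisson process of rate
  1/T, so ≈ 10 transitions alternating in kind), which is what a
  perfectly balanced force field should show in a folding benchmark ten
  times longer than the folding time.
* **Helix–coil chains** are sampled exactly from a Zimm–Bragg-type
  nucleation–propagation distribution by backward-weighted conditional
  sampling; the analytic mean helicity comes from the same transfer
  matrix and is verified against brute-force 2ⁿ enumeration for n ≤ 12.
  Default parameters (σ = 0.003, per-residue van't Hoff propagation
  enthalpy −0.9 kcal/mol, w = 1 at 295 K) are in the range classically
  fitted for short alanine-rich peptides and produce a steep melting curve
  of the right scale for a 15-mer; no claim is made of reproducing the
  specific peptide's physics.
* **Cone ensembles** redraw each N–H vector uniformly within a cone of
  half-angle θ₀ about its reference orientation every frame (heavy atoms
  fixed; optional random global rigid motion exercises tumbling removal).
  The analytic order parameter is S² = [cos θ₀ (1 + cos θ₀)/2]², and
  because successive frames are independent, C(t > 0) = S² exactly in
  expectation — a clean fixture for the plateau estimator, not a model of
  diffusive relaxation (there is no decay toward the plateau).
* **Observable datasets** (couplings, RDCs) are generated from known
  Karplus parameters/tensors plus Gaussian noise, with the noiseless truth
  attached.

Passing these tests shows the estimators are correct on data satisfying
their assumptions: well-separated RMSD levels, uncorrelated frames,
axially symmetric restricted motion, exact two-state kinetics. Real
trajectories violate all of these to some degree (intermediate states,
correlated noise, anisotropic internal motion, slow convergence); the
generators bound implementation error, not force-field error.

## Numerical choices and problem sizes

* Kabsch rejects selections whose second singular value is < 10⁻⁸ of the
  largest (collinearity); rotations are proper by construction.
* The ACF estimator divides by the number of terms per lag (all
  overlapping origins); lags must end short of the trajectory length.
* Tensor fits use QR with an explicit rank check; the fitted Saupe matrix
  is symmetrized and re-detraced to machine precision.
* Angle range is (−180°, 180°]; −180° maps to +180°.
* Dual-cutoff thresholds are strict inequalities ("dropped below", "rose
  above").
* Validation problem sizes: 1,000 two-state traces of 1,000 frames for
  the event-count expectation; 100 traces for exact recovery; 10⁴ frames
  per cone half-angle (20°, 40°, 60°, 80°) for S², recovered within 0.02;
  15-residue chains, 10⁴ frames, 5 temperatures for helicity, matched
  within 3 SEM; 1,000 random instances for the superposition oracle.
  These sizes make the whole battery run in well under a minute per stage
  while leaving Monte-Carlo error far below the tolerances checked.

## Known limitations

* Only backbone observables: no chemical shifts, no relaxation rates, no
  side-chain couplings.
* One alignment tensor per medium; ensembles whose alignment varies along
  the trajectory are outside the model.
* The helicity criterion is a documented stand-in for the cited
  literature definitions, which differ in detail; with the run condition
  it is close but not identical.
* Simulated-tempering reweighting is out of scope — per-temperature
  ensembles are taken as given, and temperature is a label.
* The score fixture's years follow the most-recent-correction convention
  and are recorded data, not bibliometrics computed here.
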