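---
title: "Methods: docking, trajectory readouts and assay analytics in nfyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: docking, trajectory readouts and assay analytics in nfyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfyscreen)
```

`nfyscreen` implements the computational arm of a small-molecule discovery
campaign against NF-Y, the CCAAT-binding transcription factor.  The target
pocket sits on the NF-YB/NF-YC histone-fold surface where an NF-YA arginine
side chain normally docks; the package provides the tooling to search that
pocket with rigid conformers, curate the resulting ranked list, quantify
binding stability from molecular-dynamics trajectories, and analyze the
downstream biochemical assays.  This vignette records the models, the
tunable parameters and the design decisions, and states exactly what the
synthetic fixtures do and do not demonstrate.

## Structure handling

PDB parsing and serialization are delegated to `bio3d`; the package layer
adds the columns the docking code needs (partial charge, van der Waals
radius) and fixes a small, deterministic dialect:

* only `ATOM`/`HETATM`/`MODEL`/`ENDMDL`/`TER` records are interpreted, and
  only the **first model** of a multi-model file is read as a structure;
* alternate-location indicators other than blank or `A` are dropped;
* residue numbers are taken verbatim from the file — pocket residues are
  referred to by author numbering, so nothing is renumbered;
* charges default to 0 and can be supplied through a two-column
  `serial charge` sidecar file; radii come from a fixed element table
  (Bondi-style values, 1.70 Å fallback).  This keeps docking usable
  without any force-field machinery.

Distance selections (`select_within`) use a **closed** boundary: an atom at
exactly the cutoff distance is included.  The docking box
(`box_from_atom`) is centred on a single named atom — for the NF-Y system,
the zeta carbon of the pocket-defining arginine — and an ambiguous or
missing match is an error, never a silent pick.

## The pose score

The paper-scale screening engine this package emulates ranks poses by an
empirical binding energy; the published description does not fix a
functional form, so the score here is the package's own, with every
constant exposed in `scoring_params()`:

$$E \;=\; \sum_{i\in \mathrm{lig}}\sum_{j\in \mathrm{rec}}
  \Big[\, \varepsilon\big((r_m/r)^{12} - 2(r_m/r)^6\big)
  \;+\; \frac{k\, q_i q_j}{4\,r^2}
  \;+\; \kappa\,(0.6\,r_m - r)_+ \Big]
  \qquad (r \le 8\ \text{Å})$$

with $r_m = R_i + R_j$.  Defaults: well depth $\varepsilon = 0.2$ kcal/mol
per pair, Coulomb constant $k = 332.0636$ kcal·Å/(mol·e²) with
distance-dependent dielectric $\epsilon(r) = 4r$, per-pair repulsion capped
at 10 kcal/mol (a softened core, so random poses inside the receptor do
not produce astronomic energies), and a linear clash penalty
($\kappa = 10$ kcal/mol/Å) below 60% of the combined radii.  The total is
the exact sum of the three components by construction.

The inner loop is compiled (Rcpp) and evaluates whole pose batches, which
makes two things cheap: GA generations, and exhaustive lattice enumeration
(`grid_minimum`, translations every 0.25 Å and z-y-z Euler angles every
15°) used as the brute-force reference on toy systems.  An independent
plain-R pairwise scorer lives in the test suite and must agree with the
compiled path to 1e-9.

## Evolutionary docking

`ga_dock` reproduces the elitist scheme of the original screen: generation
0 scores `n_poses` random poses (centroid uniform in the box, orientation
uniform on SO(3) via normalized 4-normal quaternions); each subsequent
generation keeps the `n_elite` lowest-energy poses and refills the
population with mutants of uniformly chosen elites.  Defaults follow the
published scheme (20,000 / 1,000 / 10); tests and the toy system run
500 / 50 / 10.

Choices the original description leaves open, decided here:

* **Mutation** is a Gaussian translation step per axis (default sd 1.0 Å,
  clipped so the ligand centroid stays inside the box) composed with a
  rotation about a uniform random axis with Gaussian angle (default sd
  0.26 rad).  No crossover: none is described, and elitist
  mutation-only search is sufficient for rigid bodies.
* **The box constraint applies to the ligand centroid only** — the
  cheapest well-defined rule; ligand atoms may extend past the box.
* **Seeding**: one master seed; `screen_library` derives a per-conformer
  stream from the master seed and the conformer identity (a fixed integer
  hash), so screening order cannot change any per-compound result.
* Because elites survive unchanged, the per-generation best is
  non-increasing for every seed — asserted as a property test.

## The toy complex and what it shows

`make_toy_complex` builds a ~20-atom concave receptor (the lower half of a
4 Å sphere, seeded coordinate jitter, weak positive charges on the pocket
floor) and a rigid 3-atom rod ligand with a complementary negative centre.
The search box is a 6 Å cube over the pocket: wide enough that pure random
search with a GA-sized budget does not saturate the space (at 3 Å it
does, which would make "GA beats random search" vacuous), small enough
that the exhaustive 0.25 Å / 15° enumeration — about 1.2 × 10⁸ poses —
runs in about a minute.  The enumerated minimum is stored with the fixture
and is the reference for the recovery tests: the GA (500/50/10) must land
within 0.5 kcal/mol of it in at least 18 of 20 seeds.  Note the grid
itself has finite resolution, so a continuous search can legitimately
undercut the lattice minimum by a few hundredths of a kcal/mol.

## Hit triage

* **cLogP** is OpenBabel's additive Wildman–Crippen-style estimate
  (via `ChemmineOB`).  The acceptance window is a *required* argument of
  `triage_hits` — the original campaign does not state its window, so the
  package refuses to invent a default.
* **PAINS screening** originally ran against two web services; for a
  hermetic test surface the package ships a small curated SMARTS list of
  classic frequent-hitter chemotypes (quinones, catechols, rhodanines,
  hydrazones, azo dyes, alkylidene barbiturates, aromatic nitro groups).
  Patterns are validated at load time; an empty match list means pass.
  This list is deliberately minimal — it demonstrates the mechanism, not
  the full published PAINS catalogue.
* **Diversity selection** is greedy max–min on Tanimoto distance over
  OpenBabel FP2 path fingerprints (1024 bits).  FP2 was chosen over a
  hashed circular fingerprint because it is what the available chemistry
  backend computes natively; the greedy rule seeds with the best-scoring
  compound and breaks ties by score, then lexicographic id, so selections
  are deterministic.

## Trajectory readouts

Trajectories are multi-model PDB files (dependency-free and
text-reviewable); frames share one topology.

* **Superposition** is a standard Kabsch fit (SVD with determinant
  correction, so reflections are never returned); fewer than 3 points or
  a rank-deficient covariance (e.g. collinear selections) is an error.
* **Ligand RMSD**: each frame is fitted to frame 1 *on the receptor
  selection*, then the ligand RMSD is computed without further fitting —
  so the series reports ligand motion relative to the binding site, and
  joint rigid motion of the whole complex cancels exactly.  Reported in
  nm to match MD plotting conventions (computed in Å, divided by 10).
* **RMSF** uses a two-pass mean-structure protocol (fit to frame 1,
  average, refit to the mean), then the per-residue RMSF of the selected
  atoms' centroid.  For isotropic Gaussian jitter of per-coordinate sd σ
  the expected RMSF is σ√3 — the closed form the recovery tests check at
  amplitudes 0.9 and 0.3 Å (high/low flexibility contrast) with 5,000
  frames and 3% tolerance.
* **Contact occupancy**: fraction of frames with any ligand heavy atom
  within 4.0 Å (configurable) of any residue heavy atom; monotone in the
  cutoff by construction.
* **Interaction enthalpy**: the same pairwise molecular-mechanics function
  as the docking score evaluated per frame.  No solvation term of any
  kind is included — this is the MM interaction component only, intended
  for stability monitoring, not for absolute binding free energies.  The
  moving average (default window 50 frames) is centred and
  edge-truncated, never padded.

## Assay analytics

* **Dose-response**: 4PL on the linear dose scale,
  $y = b + (t-b)/(1+(d/\mathrm{IC}_{50})^h)$, with IC50 parameterized
  internally as log(IC50) and multi-start Levenberg–Marquardt
  (`minpack.lm::nls.lm`; 4 log-spaced IC50 starts × 3 Hill starts, best
  residual sum of squares wins, diverging log-IC50 solutions discarded).
  Vehicle (dose 0) evaluates to `top` exactly.  For vehicle-normalized
  reporter data `fixed_top_bottom = c(1, 0)` restricts the fit to IC50
  and Hill slope; both constrained and free modes are exposed because the
  original analysis does not state which was used.  Non-convergence is a
  flag, never an exception.  Fits use all replicate points rather than
  dose means, which keeps standard errors honest.
* **Half-life**: ordinary least squares of log(level) on time ("slope of
  the line"), $t_{1/2} = \ln 2 / k$, delta-method SE; a nonlinear
  exponential fit (`fit_half_life_nls`) is provided as a cross-check.
  Non-decaying data return an infinite half-life with a warning flag.
  Statistical comparison of half-lives between conditions is left to
  standard two-sample tests on per-replicate fits — not re-implemented.
* **Densitometry** divides each band by its loading control and rescales
  so the reference lane equals exactly 1.0.  **Hit calling** uses a
  strict `>` threshold on mean inhibition, default 0.60 (the
  reporter-screen criterion).

## Synthetic presets and the noise model

The packaged presets (`inst/extdata/presets.json`) carry the ground truths
the recovery machinery aims back at: reporter IC50s of 19.95 μM (human)
and 12.73 μM (rat); NF-YA half-lives of 16.5 h (control) and 8.5 h
(inhibitor-treated); and the FLAG-tagged constructs at 8.8 h (wild type)
and 8.1 h (lysine-free mutant) untreated, 6.2 h and 5.7 h treated.

Design choices:

* **Noise is mean-one lognormal** (cv 10% for dose-response, 5% for chase
  data): luminescence and densitometry readouts are positive and
  right-skewed, and the published figures report SEMs rather than raw
  noise, so the cv values are this package's stand-ins.
* **Dose design**: 0–30 μM (6 levels × 4 replicates), matching the span
  of the published dose series around the ~20 μM IC50.
* **Chase design**: the main presets use extended timepoints
  (0, 4, 8, 16, 24 h × 4 replicates) for stable slope recovery; a
  two-point (0, 8 h) preset mirrors the minimal published design.
* Generators are bit-reproducible from `(preset, seed)`, and `t = 0`
  chase levels are renormalized to mean 1 after noising, as in the assay
  convention.

With 200 replicate simulations the median fitted IC50 and mean fitted
half-life recover every preset truth within ~1%, comfortably inside the
10% recovery tolerance the test suite enforces.  `scripts/acceptance.R`
recomputes exactly these quantities from scratch.

## Problem sizes

The published campaign screened 8 million compounds (160 million
conformers) and ran 100 ns simulations; this package demonstrates the
identical algorithms at fixture scale, chosen so the full test suite runs
in well under five minutes of compute: toy docking populations of
200–500 poses, one ~10⁸-pose enumeration shared across tests, 5,000-frame
jitter trajectories for the RMSF closed form, and 200-replicate recovery
loops for the assay fits.

## What passing tests do and do not show

The synthetic generators reproduce the *statistical structure* of the
study's readouts — known score minima, region-specific Gaussian
flexibility, prescribed contact fractions, 4PL curves and exponential
decays under multiplicative noise.  They do not emulate real MD physics
(no bonded terms, no solvent, no correlated motion), real conformer
strain, or real assay artifacts (plate effects, aggregation, incomplete
translation block).  Passing recovery tests therefore validates the
*estimators and search machinery*, not the biological conclusions; on
real data the same functions apply unchanged, but their error structure
will be richer than the presets assume.

## Known limitations

* Rigid-ligand, rigid-receptor docking only; no flexible side chains.
* The scoring function is deliberately generic — it reproduces the
  rank-by-energy GA *procedure*, not any proprietary energy model's
  values.
* Solvation/entropy terms are out of scope throughout; the enthalpy
  series is an MM interaction energy.
* The PAINS list is a compact demonstration set, not a complete catalogue.
* mmCIF input, hydrogen placement and protonation assignment are not
  handled.
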