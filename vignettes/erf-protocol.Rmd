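---
title: "Fragment-based ensembles of disordered peptides and their NMR reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based ensembles of disordered peptides and their NMR reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intrinsically disordered peptides have no single native structure: their
observable behaviour is an average over a broad conformational ensemble.
Sampling that ensemble directly for a 31-residue peptide is expensive, and
an ensemble sampled by any generator still carries no guarantee that its
statistical weights reproduce experiment. `erfr` implements a two-part
answer for peptides such as tau 210-240
(`SRTPSLPTPPTREPKKVAVVRTPPKSPSSAK`, optionally phosphorylated at T212,
T217, T231 and S235):

1. **Ensemble construction by fragment recombination.** The peptide is cut
   into short overlapping fragments (here three fragments of roughly 11
   residues sharing one overlap residue, acetyl/N-methyl capped at the cut
   ends). Each fragment's conformer pool is reduced to its major
   conformations by affinity propagation, and full-length conformers are
   formed from *every* combination of fragment exemplars by rigid-body
   superposition on the shared overlap residue. A log-normal fit to the
   conformer energy distribution supplies a cutoff covering 80% of the
   fitted mass; survivors get a bounded 20-step relaxation. The result is a
   sparse, broad ensemble with uniform prior weights.

2. **Observable-restrained reweighting.** Backbone ³J(HN–Hα) couplings are
   back-calculated with the Karplus equation
   `J = A cos²(φ+Δ) + B cos(φ+Δ) + C` under several literature parameter
   sets; the consensus is their mean and the per-observable uncertainty is
   twice the spread of the ensemble-level predictions across sets
   (chemical-shift predictions are ingested from file, never predicted
   in-package). Posterior weights take the form of a hypothetical
   harmonically restrained ensemble,
   `w_i(k) ∝ w⁰_i exp(-½ Σ_j k_j z_ij²)` with
   `z_ij = (M_ij - ô_j)/σ_j`, and the restraint strengths `k ≥ 0` minimise

   `L(k) = ½ Σ_j ((⟨M_j⟩_w(k) - ô_j)/σ_j)² + θ·KL(w(k) ‖ w⁰)`.

   Larger θ preserves the prior ensemble more strongly; θ = 0.1 is the
   default. Diagnostics are the Kish effective sample size
   `(Σw)²/Σw²`, the ensemble preservation (mean over conformers of 100%
   for raised weights and the remaining fraction for lowered ones), the KL
   divergence, and weighted radius-of-gyration densities.

The restraint/KL objective above is this package's stated contract for the
reweighting stage; the limiting behaviours are guaranteed by construction
(`k = 0` returns the prior exactly, and θ → ∞ drives the posterior back to
the prior).

## Running the protocol

```{r}
library(erfr)

cfg <- default_config(seed = 1L)
man <- run_pipeline(cfg, outdir = "erf_run", synthetic_experiment = TRUE)
rep <- report(man)
rep
autoplot(rep)            # prior/posterior RGYR densities
autoplot(man$reweight)   # predicted vs experimental couplings
```

Every stage writes a plain artifact (multi-model PDB, TSV, JSON) under the
run directory, and the manifest records sizes, settings and MD5 checksums.
Re-running with the same configuration and seed reproduces every artifact
bitwise: all randomness flows from the single configured seed, from which
each stage derives its own sub-seed by a fixed offset (library m uses
`seed + 1000·m`; the synthetic experiment generator uses `seed + 77`).

## The synthetic conformer generator

The reference data for this protocol are molecular-dynamics fragment
trajectories, which are far outside desk scale. The package therefore
ships a first-class synthetic generator so every downstream stage runs and
can be tested end to end:

* Backbone dihedrals are drawn per residue from a small Ramachandran basin
  model (PPII-like, β, right- and left-handed α basins) with coil-like
  weights; ω is held trans (180°), matching the behaviour reported for
  this peptide. Proline uses its own class with φ fixed near −65°; glycine
  gets broader, more left-handed-permissive basins; pre-proline residues
  shift toward PPII/β. The numbers live in `inst/extdata/basins.yaml` and
  are configuration, not claims about any force field.
* Conformers are built by sequential internal-to-Cartesian (natural
  extension of reference frame) placement from an ideal-geometry table
  (`inst/extdata/geometry.yaml`; e.g. N–CA 1.458 Å, CA–C 1.525 Å,
  C–N 1.329 Å). Built backbone dihedrals reproduce the inputs to numerical
  precision, which the tests exploit as an exact round-trip oracle. Only
  backbone, amide H, carbonyl O and CB atoms are placed — the minimal set
  every downstream stage needs (the six-point junction alignment uses N,
  H, CA, CB, C, O of the overlap residue; glycine contributes five points,
  proline five).
* Draws whose built conformer exceeds a soft-sphere clash threshold are
  rejected and redrawn (bounded retries), giving diverse, mostly
  clash-free coil libraries.

What passing tests on synthetic libraries do **not** show: fidelity of any
force field, side-chain packing, solvent effects, or the true basin
statistics of the tau fragments. The generator emulates the *shape* of the
problem (diverse capped coil fragments), not its physics; conclusions
about the real peptide require real fragment ensembles, which the package
ingests as multi-model PDB.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `fragment_lengths`, `overlap` | 11/11/11, 1 | residues | tiling of the parent sequence; the tiling arithmetic must be exact and is never silently adjusted |
| `clustering$preference` | −17 | Å² (on −RMSD²) | affinity-propagation exemplar preference; more negative → fewer exemplars |
| `clustering$damping` | 0.9 | — | message damping of affinity propagation |
| `gating$coverage` | 0.8 | fraction | mass of the fitted log-normal below the energy cutoff |
| `refinement$n_steps`, `max_step` | 20, 0.1 | steps, Å | bounded steepest-descent relaxation of gate survivors |
| `reweighting$theta` | 0.1 | — | prior-adherence strength of the reweighting objective |
| `reweighting$sigma_floor` | 0.1 | Hz | lower bound on consensus-coupling uncertainties |
| `library$n_pool` | 300 | conformers | synthetic pool size per fragment before clustering |

The reference protocol's preference is −30 on its (far larger,
MD-derived) fragment pools, chosen there to yield around 35 exemplars per
fragment; `select_exemplars()` keeps that −30 default. The pipeline
default applies the same calibration criterion to the synthetic
libraries: with 300-member coil pools, preference −17 yields roughly 30
exemplars per fragment and a raw ensemble in the tens of thousands, which
is the intended toy scale (about 30 000 recombinations). These study
conditions are fixed; they were chosen once from the calibration rule, not
per run.

## Numerical choices

* **Superposition** is closed-form least squares (SVD with a
  determinant-sign correction, so the rotation is always proper). The
  junction "minimisation" is therefore exact in one step; no iterative
  minimiser is involved. Tests cross-check against an independent
  quaternion (Horn) implementation at 1e-9 Å.
* **Assembly** composes precomputed per-junction rigid transforms instead
  of literally merging pair by pair; because every operation is rigid the
  two routes agree to 1e-9 Å (property-tested). Fragment 1 defines the
  global frame; the N-terminal copy of each overlap residue survives, and
  seam bond geometry is inherited from the alignment — relieving seam
  strain is the refinement stage's job.
* **Log-normal gate**: scores are shifted by `min - 1e-6·range` so logs
  are finite; (μ, σ) are the mean and population SD of the shifted logs
  (the maximum-likelihood fit); the cutoff is
  `shift + exp(μ + σ·Φ⁻¹(coverage))`. A fit needs at least 10 distinct
  scores.
* **Refinement** uses the analytic soft-sphere gradient with backtracking
  and a hard 0.1 Å per-atom per-step cap; the score never increases and
  clash-free conformers pass through untouched. Arbitrary scorers are
  accepted and differentiated by central finite differences.
* **Reweighting optimiser**: L-BFGS-B on `log(1+k)` (enforcing k ≥ 0),
  objective tolerance 1e-8, fully deterministic. The objective is not
  convex in k — with tight uncertainties the point k = 0 can be a boundary
  local minimum — so the solver runs a fixed fan of starting points (k = 0,
  a few fixed magnitudes, and a data-adaptive scale at which the typical
  restraint term is order one) and keeps the best optimum. If the best
  optimum is still worse than k = 0, the prior is returned, so the fit can
  never be worse than no reweighting.
* **Weighted KDE**: Silverman-type bandwidth with the Kish effective
  sample size in place of n, a 512-point grid spanning the data ± 3
  bandwidths; mode ties resolve to the lower value.
* **Tie-breaks**: affinity-propagation assignment ties go to the
  lowest-index exemplar; all enumeration orders are fixed (last fragment
  index fastest), so results are reproducible across runs.

## Design decisions

* Phosphosites are annotated as lowercase letters in sequence text
  (`"SRtP…"`), and written as the standard component codes SEP/TPO/PTR in
  PDB output. Observables on phospho-flagged residues are excluded from
  reweighting. Full-atom phosphate groups are not generated — phospho
  residues built synthetically carry backbone + CB only, and full-atom
  phospho conformers must be ingested.
* Residue indices are 0-based half-open internally; author numbering
  (e.g. 210-based) appears only at I/O boundaries and in observable
  tables. Caps are ordinary flagged residues at indices −1 and n, which
  makes cap stripping during assembly deterministic.
* The built-in energy backend is a soft-sphere clash score (pairs within
  three bonds excluded, radii slightly below van der Waals so
  hydrogen-bond-range contacts are not penalised). It is a pluggable
  stand-in: per-conformer scores from any external backend can be passed
  to the gate instead.
* The uncertainty of consensus couplings is computed from the spread of
  *ensemble-level* predictions across Karplus sets (then doubled, floored
  at 0.1 Hz), not per conformer — the coarser and more conservative of
  the two readings of "standard deviation over sets".
* The fragment tiling consistency equation
  `Σ lengths − overlap·(k−1) = length(sequence)` is enforced strictly.
  Note that 11 + 11 + 12 with two single-residue overlaps covers 32
  residues, not 31, so a 31-residue peptide uses e.g. 11/11/11.

## Known limitations

* Synthetic libraries carry no force-field realism (see above); the
  package's quantitative claims are about the protocol machinery, and the
  shipped acceptance checks measure protocol behaviour on synthetic
  conditions only.
* The refinement stage relaxes clashes, not seam bond lengths: with the
  soft-sphere backend there is no bonded term, so a strained seam relaxes
  only insofar as it clashes.
* θ is scanned, never auto-selected; `theta_scan()` tabulates
  (θ, χ², KL, ESS, preservation) so the overfitting trade-off can be
  inspected, and the reported default θ = 0.1 is a convention of the
  reference protocol.
* Problem sizes in the tests and the acceptance script (300-member pools,
  ~30 000 recombinations, ~20 observables) are the package's chosen desk
  scale for the toy protocol.
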