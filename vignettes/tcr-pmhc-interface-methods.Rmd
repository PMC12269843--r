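---
title: "Interface and binding-model methods for TCR–pMHC-II analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface and binding-model methods for TCR-pMHC-II analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrint)
library(dplyr)
```

# Scope and model of the data

`tcrint` analyses a T cell receptor bound to a peptide–MHC class II
molecule: a five-chain ternary complex (MHC α and β chains, the groove-bound
peptide, and the TCR α and β chains), optionally alongside the unliganded
TCR. The motivating biology is autoimmune recognition of citrullinated
self-peptides: arginine deiminated to neutral citrulline changes the peptide
surface a TCR sees, and HLA-DRB1 alleles carrying the shared-epitope motif
(QKRAA, QRRAA or RRRAA at β-chain positions 70–74, forming the P4 pocket)
dominate genetic risk. Everything the package computes — footprint areas,
contact tables, docking geometry, equilibrium affinities, competition
IC50s, mutational impact bins — is a standard quantity of this field, and
the defaults reproduce the reporting conventions of crystallographic
interface tables.

All structural containers are plain tibbles, one row per atom; annotation
steps add columns (`role`, `region`, `pocket`, `radius`, `sasa`) so the
pipeline composes with the usual dplyr verbs.

# Structure annotation

**Parsing.** PDB and mmCIF files are read through bio3d. Alternate
locations keep the highest-occupancy conformer, ties resolved toward
altloc "A"; the deposited structures this workflow targets do not state a
policy, so a deterministic one is fixed here. Hydrogens are dropped
everywhere: at 2.4–3.2 Å resolution they are not observed, and every
criterion in the package is heavy-atom based. Modified polymer residues —
citrulline (`CIR`) in particular — are recognised by their α-carbon and
kept in chain sequence; waters, ions and glycans are flagged `het` and take
no part in interface computations, which are strictly protein–protein.

**Chain roles.** Explicit chain→role maps are preferred; a single
unassigned chain of 9–25 residues is auto-detected as the peptide (the
bound epitope including flanks is a 14-mer, so the window is generous on
both sides).

**IMGT regions.** Deposited TCR coordinates are assumed to follow IMGT
unique numbering. The CDR intervals default to the IMGT standard —
CDR1 27–38, CDR2 56–65, CDR3 105–117 — and every other variable-domain
position (1–129) is framework. Constant-domain residues (numbered beyond
129) are left unlabelled rather than guessed, since constant-domain
numbering conventions vary between deposits.

**Pocket register.** The peptide register is anchored at a caller-supplied
P1 residue; positions run P-2…P9 and anything outside that window is
`flank` (e.g. C-terminal lysines added for solubility). Labels are
order-preserving by construction.

# Surface areas

SASA uses the Shrake–Rupley construction: each atom's solvent-expanded
sphere (van der Waals radius + probe, probe 1.4 Å ≈ one water) is sampled
at `n_points` lattice points and a point is accessible if it lies outside
every neighbouring expanded sphere. Two numerical choices matter:

- **Lattice.** A deterministic Fibonacci sphere lattice, so areas are
  exactly reproducible run-to-run and convergence is smooth in `n_points`.
  The default 960 points reproduces the analytic two-sphere cap areas to
  well under 1% (the test suite checks 0.5% convergence against a 3840-point
  lattice on sphere fixtures).
- **Radii.** A Chothia-style element-keyed protein set (C 1.87, N 1.65,
  O 1.40, S 1.85 Å). Citrulline side-chain atoms are ordinary C/N/O and
  need no special casing. Unknown elements are a hard error unless an
  override radius is supplied — a silent default would bias every
  downstream area.

Buried surface area is the two-sided sum
`SASA(TCR) + SASA(pMHC) − SASA(complex)`; published interface totals for
complexes of this kind are conventionally two-sided, and the report states
the convention explicitly so one-sided readings can be halved. Per-residue
burial is the atom-level SASA loss summed within each residue; loop
percentages are computed over TCR-side burial only, which is how CDR
footprint contributions are quoted.

# Contacts

Contact classification is purely distance-based, matching the conventions
of crystallographic contact tables (no angular terms): all inter-side
heavy-atom pairs within 4.0 Å are van der Waals contacts; N/O
donor–acceptor pairs (S accepted as a partner) within 3.5 Å are
additionally hydrogen bonds; SG–SG within 4.5 Å is a disulfide; Lys
NZ/Arg NE,NH1,NH2 against Asp OD1,OD2/Glu OE1,OE2 within 4.0 Å is a salt
bridge. Citrulline is neutral — deimination removes the guanidinium
charge — so it can hydrogen-bond but never salt-bridge. A pair may carry
several kinds; reports order kinds most-specific-first
(disulfide > salt bridge > H-bond > vdW).

The neighbour search uses a cell list at the largest cutoff. Candidate
pairs are collected with a small slack and distances are then recomputed
atom-by-atom, so the grid path and the exhaustive O(n²) path return
bit-identical tables — an invariant the suite checks on 100 random
fixtures.

# Geometry

The docking angle is measured between the line connecting the Vα and Vβ
centroids (centroids over variable-domain Cα only) and the
total-least-squares axis through the peptide Cα trace (flanking residues
excluded), folded to [0°, 90°]. The centroid convention follows the usual
center-of-mass depiction of TCR engagement; folding makes the value
independent of axis orientation, and the peptide axis is signed from the
P-2 end toward P9 only for reporting. Canonical TCR–pMHC-II engagement
falls around 35–80°.

Superposition is the Kabsch algorithm: SVD of the covariance matrix with
the determinant-corrected sign so only proper rotations are returned;
r.m.s.d. is invariant under rigid pre-motion of either input (tested), and
rank-deficient (collinear) selections warn that the rotation is not
unique. Apo/holo comparisons match TCR Cα atoms by chain role and residue
number.

# Binding models

**Steady-state SPR.** Equilibrium responses follow the one-site isotherm
`R_eq(C) = R_max·C/(K_D + C)`. The fit is unweighted nonlinear least
squares (no weighting scheme is standard for these dilution series), with
replicates pooled into a single joint fit by default — affinities quoted
from "n independent experiments in duplicate" are naturally a pooled
estimate, and per-replicate fitting remains available via `pool = FALSE`.
Initialisation is robust on sparse series: K_D starts at the concentration
nearest half-maximal response, R_max at 1.1× the maximum response.
Standard errors come from the Jacobian at the optimum; non-convergence is
returned as a flagged result, never silently.

**FP competition.** Normalized relative binding (controls anchored to
0%/100%) is fitted with the four-parameter logistic; IC50 is the
concentration at 50% inhibition. With hill 1, bottom 0, top 100 the 4PL
reduces to the one-site isotherm, a cross-model identity the tests assert.
Two explicit flags guard interpretation: a fitted bottom plateau above 20%
residual binding means the curve never reaches full inhibition, and an
IC50 beyond the tested range (or a fitted curve that never crosses 50%) is
reported as "> max tested" rather than as a number.

**Impact bins.** Mutant affinities are classified by fold change
`K_D(mut)/K_D(wt)`: <2 no effect, 2–5 moderate, 5–10 severe, ≥10
deleterious. The prose convention ("2–5-fold", ">10-fold") is ambiguous at
exact boundaries, so bins are left-closed: a fold of exactly 5 is severe.
Improved affinity (fold < 1) is reported as no effect with an `improved`
note.

# Synthetic data: what it emulates and what it does not

The generators provide every fixture the test suite needs, with ground
truth attached:

- `make_sphere_cluster()` — atom pairs/clusters whose SASA and buried caps
  have closed forms; the oracle for the area code.
- `make_toy_complex()` — a five-chain miniature (a 12-mer peptide carrying
  citrulline at P-1, mirroring the epitope layout; polyglycine MHC chains
  whose β-chain covers the 70–74 window; TCR chains with residues spanning
  all IMGT regions). Planted atoms realise exactly one hydrogen bond, one
  vdW-only pair, one salt bridge and one disulfide across the interface,
  everything else is spaced beyond the cutoffs, and the Vα/Vβ Cα blobs are
  placed symmetrically so the centroid line makes an exact, chosen angle
  with the peptide axis.
- `simulate_spr()` / `simulate_fp()` — dilution-series curves with additive
  Gaussian noise, independent per replicate, bit-reproducible under a
  required seed. Defaults mirror the bench protocols: SPR as a 10-point
  twofold series from 200 µM, R_max 100 RU, σ 2 RU, duplicates; FP as a
  12-point series from 500 µM, σ 3%, triplicates. The FP protocol states
  its starting concentration but not the dilution factor; threefold is
  used, placing points on both plateaus around a ~1 µM IC50.

These fixtures validate algorithmic correctness, not realism: toy atoms are
spheres on exact positions, chains are not stereochemically sensible, noise
is homoscedastic Gaussian, and SPR curves have no drift, depletion or
rebinding. Passing tests therefore demonstrate that the implementations
compute their definitions correctly at any scale, and that the estimators
recover generating parameters under idealised noise — they do not certify
behaviour on pathological crystal structures or misbehaving sensorgrams.

```{r recovery}
curve <- simulate_spr(kd = 25.8, rmax = 100, noise_sd = 2, seed = 11)
glance(fit_steady_state(curve))
```

# Problem sizes and determinism

The shipped tests run on miniature fixtures (tens of atoms; hundreds of
atoms for the grid-vs-exhaustive property; 200 simulated curves for the
estimator-consistency check), chosen so the whole suite completes in well
under a minute while still exercising every code path; the SASA kernel
itself handles full deposited complexes (~20k atoms) in seconds thanks to
the compiled point-occlusion loop. All randomness flows through explicit
seeds; report files are formatted at fixed precision (1 decimal for Å² and
%, 2 for Å, 3 significant figures for µM) so identical inputs give
byte-identical outputs.

# Known limitations

- Hydrogen-bond assignment has no geometric (angle) term and no
  donor/acceptor saturation; it is a distance criterion, as in the contact
  tables it reproduces.
- Water-mediated contacts and electrostatic surfaces are out of scope.
- Constant-domain residues are unlabelled; analyses restricted to variable
  domains are unaffected.
- The one-site SPR model assumes reference-subtracted, equilibrium
  responses; kinetic (on/off-rate) fitting is not provided.
- Auto-detection of chain roles covers only the peptide; MHC and TCR
  chains must be mapped explicitly.
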