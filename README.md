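# tcrint

Quantitative analysis of T cell receptor (TCR) recognition of peptide–MHC
class II complexes, built around the structural and biophysical workflow used
to characterize autoimmune TCRs against citrullinated self-epitopes (the
rheumatoid-arthritis setting: HLA-DRB1 molecules carrying the shared-epitope
motif presenting citrullinated peptides such as tenascin-C).

It is aimed at structural immunologists who have (i) a crystal structure of a
TCR–pMHC-II ternary complex (and optionally the unliganded TCR) and (ii) the
accompanying binding assays, and want the standard interface and affinity
numbers computed reproducibly from the deposited coordinates and raw curves.

## What it computes

**Structure side.** From a PDB/mmCIF file with chain roles assigned
(`tcr_alpha`, `tcr_beta`, `mhc_alpha`, `mhc_beta`, `peptide`):

- Solvent-accessible surface area by the Shrake–Rupley method: each atom's
  solvent-expanded sphere (van der Waals radius + 1.4 Å probe) is sampled on
  a deterministic Fibonacci lattice and points occluded by neighbouring
  spheres are removed.
- Buried surface area of the interface,
  `BSA = SASA(TCR) + SASA(pMHC) − SASA(complex)`, attributed per residue and
  decomposed by IMGT region (CDR1/2/3 and framework of each TCR chain), with
  the percent contribution of each loop to the TCR-side footprint.
- Distance-criterion contacts across the interface: van der Waals within
  4.0 Å, hydrogen bonds (N/O donor–acceptor pairs) within 3.5 Å, salt bridges
  (Lys/Arg side-chain N against Asp/Glu carboxylate O) within 4.0 Å,
  disulfides (SG–SG) within 4.5 Å. Citrulline is treated as neutral. A
  cell-list grid accelerates the search and provably equals the exhaustive
  scan.
- Docking geometry: the angle between the Vα→Vβ centroid line and the
  total-least-squares axis through the peptide Cα trace, folded to [0°, 90°].
- Kabsch least-squares superposition (proper rotation enforced) for apo/holo
  r.m.s.d. comparisons.
- Peptide pocket register (P-2…P9 anchored at P1, flanking residues
  labelled) and detection of the HLA-DRB1 shared-epitope motif
  (QKRAA/QRRAA/RRRAA at β70–74).

**Assay side.**

- Steady-state SPR affinity: pooled nonlinear least-squares fit of the
  one-site model `R_eq(C) = R_max · C / (K_D + C)` with standard errors.
- Fluorescence-polarization competition: four-parameter logistic fit with
  IC50 read at 50% inhibition, control-anchored normalization, and explicit
  flags when inhibition is incomplete or the IC50 lies beyond the tested
  range.
- Mutational impact classification by affinity fold change:
  `<2×` no effect, `2–5×` moderate, `5–10×` severe, `≥10×` deleterious.

Synthetic-data generators (`make_sphere_cluster()`, `make_toy_complex()`,
`simulate_spr()`, `simulate_fp()`) produce fixtures whose ground truth is
known analytically or by construction; every stage of the pipeline is tested
against them.

## Worked example

```r
library(tcrint)

# a miniature ternary complex with planted ground truth
toy <- make_toy_complex(docking_angle = 70)
bsa <- compute_bsa(toy$atoms)
bsa
#> Buried surface area breakdown
#>   total BSA: 212.7 A^2 (TCR side 107.8 + pMHC side 105.0)
#>   TCR chain share: tcr_alpha 43.4%, tcr_beta 56.6%
#>   region shares (% of TCR-side burial):
#>     CDR3b   34.8%
#>     CDR3a   24.0%
#>     FWb     21.8%
#>     CDR2a   19.4%
#>     CDR1a    0.0%
#>     CDR1b    0.0%
#>     CDR2b    0.0%
#>     FWa      0.0%
docking_geometry(toy$atoms)
#> Docking angle: 70.0 degrees

detect_contacts(toy$atoms) |> dplyr::count(kind)
#>   kind        n
#> 1 disulfide   1
#> 2 salt_bridge 1
#> 3 hbond       2
#> 4 vdw         3

# steady-state SPR: simulate at a known K_D, fit it back
curve <- simulate_spr(kd = 25.8, rmax = 100, noise_sd = 2, seed = 7)
fit <- fit_steady_state(curve)
fit
#> One-site steady-state fit (n = 20): KD = 26.9 +/- 1.7 uM, Rmax = 103 +/- 2.1 RU
classify_impact(kd_mut = 50, kd_wt = fit$kd)$label
#> [1] no_effect
#> Levels: no_effect moderate severe deleterious
```

The toy complex's numbers mean: a ~213 Å² interface carried by the loops
that hold the planted contacts (CDR3α hydrogen-bonds the P-1 citrulline),
zero burial everywhere else, and a 70° crossing angle — the same quantities
reported for a real ternary complex, at miniature scale. The SPR fit
recovers the generating K_D within its standard error, and a mutant at
50 µM versus this wild type is a sub-twofold change, i.e. `no_effect`.

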