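#' Closed-form areas for two overlapping solvent-expanded spheres
#'
#' Analytic oracle for SASA/BSA tests. For two spheres with expanded radii
#' `R1 = r1 + probe` and `R2 = r2 + probe` whose centers are `d` apart, the
#' area occluded on sphere 1 is the spherical cap `2 * pi * R1 * h1` with
#' `h1 = R1 - (d^2 + R1^2 - R2^2) / (2 d)`.
#'
#' @param r1,r2 Van der Waals radii (angstroms).
#' @param d Center-center distance (angstroms).
#' @param probe Probe radius (angstroms).
#' @return List with `sasa1`, `sasa2` (accessible areas of each sphere),
#'   `buried1`, `buried2` (cap areas) and `bsa = buried1 + buried2`.
#' @export
two_sphere_areas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  full1 <- 4 * pi * R1^2
  full2 <- 4 * pi * R2^2
  if (d >= R1 + R2) {
    b1 <- 0; b2 <- 0
  } else {
    if (d <= abs(R1 - R2)) {
      abort("Spec error: one sphere fully engulfs the other")
    }
    h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
    b1 <- 2 * pi * R1 * h1
    b2 <- 2 * pi * R2 * h2
  }
  list(sasa1 = full1 - b1, sasa2 = full2 - b2,
       buried1 = b1, buried2 = b2, bsa = b1 + b2)
}

new_atoms <- function(chain, resno, resname, atom, element, x, y, z) {
  tibble(
    chain = chain, resno = as.integer(resno), icode = "",
    resname = resname, atom = atom, element = element,
    altloc = "", occ = 1, x = x, y = y, z = z, het = FALSE
  )
}

#' Analytic sphere-cluster fixtures
#'
#' Generates miniature atom clusters whose SASA and pairwise buried areas
#' are known in closed form, for oracle-based testing of the Shrake-Rupley
#' implementation. Geometries: `"two_sphere"` (two atoms `separation`
#' apart, treated as two single-atom chains A and B) and `"far_cluster"`
#' (`n_atoms` atoms spaced far beyond any mutual occlusion).
#'
#' @param geometry `"two_sphere"` or `"far_cluster"`.
#' @param separation Center-center distance for `two_sphere` (angstroms).
#' @param r Van der Waals radius; for `two_sphere` a length-2 vector gives
#'   the two spheres different radii (engulfment is rejected).
#' @param probe Probe radius used for the attached expected values.
#' @param n_atoms Atom count for `far_cluster`.
#' @param spacing Atom spacing for `far_cluster` (angstroms).
#' @return List with `atoms` (tibble; a `radius` column is preset so the
#'   chosen `r` applies) and `expected` (closed-form per-atom SASA and, for
#'   `two_sphere`, the buried areas).
#' @export
make_sphere_cluster <- function(geometry = c("two_sphere", "far_cluster"),
                                separation = 4, r = 1.7, probe = 1.4,
                                n_atoms = 10, spacing = 100) {
  geometry <- match.arg(geometry)
  if (geometry == "two_sphere") {
    if (separation <= 0) abort("Spec error: separation must be positive")
    r <- rep_len(r, 2)
    atoms <- new_atoms(
      chain = c("A", "B"), resno = c(1L, 1L),
      resname = "SPH", atom = "C", element = "C",
      x = c(0, separation), y = 0, z = 0
    )
    atoms$radius <- r
    exp <- two_sphere_areas(r[1], r[2], separation, probe)
    list(atoms = atoms,
         expected = list(per_atom_sasa = c(exp$sasa1, exp$sasa2),
                         bsa = exp$bsa, buried = c(exp$buried1,
                                                   exp$buried2)))
  } else {
    atoms <- new_atoms(
      chain = "A", resno = seq_len(n_atoms), resname = "SPH",
      atom = "C", element = "C",
      x = spacing * (seq_len(n_atoms) - 1), y = 0, z = 0
    )
    atoms$radius <- r
    iso <- 4 * pi * (r + probe)^2
    list(atoms = atoms,
         expected = list(per_atom_sasa = rep(iso, n_atoms),
                         total_sasa = n_atoms * iso))
  }
}

#' Miniature annotated TCR-pMHC-II complex with planted ground truth
#'
#' Builds a five-chain toy complex (MHC alpha/beta, a 12-mer peptide with
#' citrulline at register position P-1, TCR alpha/beta) whose interface
#' contact inventory and docking angle are known by construction: one
#' planted hydrogen bond (CDR3-alpha Asn113 to the P-1 citrulline side
#' chain), one van-der-Waals-only pair, one salt bridge (CDR2-alpha Lys58 to
#' an MHC-beta glutamate) and one disulfide, with every other cross-side
#' atom pair farther than any cutoff. The TCR variable-domain C-alpha blobs
#' are placed symmetrically so the centroid line makes exactly
#' `docking_angle` degrees with the peptide axis.
#'
#' @param docking_angle Planted docking angle in degrees (0-90).
#' @param tcr_displacement Rigid translation (length-3) applied to all TCR
#'   atoms; displacing by 50 angstroms empties the interface.
#' @return List with `atoms` (annotated tibble: roles, IMGT regions, pocket
#'   register) and `truth` (planted contact table, docking angle, P1 residue
#'   number).
#' @export
make_toy_complex <- function(docking_angle = 70, tcr_displacement = c(0, 0, 0)) {
  stopifnot(docking_angle >= 0, docking_angle <= 90,
            length(tcr_displacement) == 3)
  pep_seq <- c("ASP", "CIR", "TYR", "CIR", "LEU", "ASN", "TYR", "SER",
               "LEU", "PRO", "THR", "GLY")
  pep <- new_atoms("C", 1013:1024, pep_seq, "CA", "C",
                   x = 3.8 * (0:11), y = 0, z = 0)
  cit_o <- new_atoms("C", 1014L, "CIR", "O7", "O", x = 3.8, y = 0, z = 3)

  mhc_a <- new_atoms("A", 1:26, "GLY", "CA", "C",
                     x = 3.8 * (1:26) - 50, y = -40, z = -20)
  mhc_a_sg <- new_atoms("A", 5L, "CYS", "SG", "S", x = 10, y = 20, z = 0)
  mhc_a$resname[mhc_a$resno == 5] <- "CYS"
  # beta-chain numbering covers the 70-74 shared-epitope window
  mhc_b <- new_atoms("B", setdiff(60:90, 70L), "GLY", "CA", "C",
                     x = 3.8 * seq_len(30) - 50, y = -40, z = -28)
  mhc_b_glu <- bind_rows(
    new_atoms("B", 70L, "GLU", "CA", "C", x = 0, y = 20, z = -6),
    new_atoms("B", 70L, "GLU", "OE1", "O", x = 0, y = 20, z = 0)
  )

  # symmetric CA blobs: centroid is exact
  blob <- function(chain, resno, center) {
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    k <- length(resno)
    use <- offs[rep_len(seq_len(6), k), , drop = FALSE]
    # pair up offsets so they cancel: use first k offsets cyclically, then
    # subtract the mean so the centroid lands exactly on `center`
    use <- sweep(use, 2, colMeans(use))
    new_atoms(chain, resno, "GLY", "CA", "C",
              x = center[1] + use[, 1], y = center[2] + use[, 2],
              z = center[3] + use[, 3])
  }
  theta <- docking_angle * pi / 180
  ca_cen <- c(10, 30, 25)
  cb_cen <- ca_cen + 20 * c(cos(theta), sin(theta), 0)
  tcr_a_res <- c(1L, 27L, 30L, 38L, 56L, 58L, 64L, 105L, 113L, 117L)
  tcr_b_res <- c(1L, 27L, 38L, 56L, 65L, 90L, 105L, 110L, 117L)
  tcr_a <- blob("D", tcr_a_res, ca_cen)
  tcr_a$resname[tcr_a$resno == 113] <- "ASN"
  tcr_a$resname[tcr_a$resno == 58] <- "LYS"
  tcr_b <- blob("E", tcr_b_res, cb_cen)
  tcr_b$resname[tcr_b$resno == 110] <- "PRO"
  tcr_b$resname[tcr_b$resno == 90] <- "CYS"
  planted <- bind_rows(
    new_atoms("D", 113L, "ASN", "ND2", "N", x = 3.8, y = 0, z = 5.9),
    new_atoms("D", 58L, "LYS", "NZ", "N", x = 0, y = 20, z = 3.5),
    new_atoms("E", 110L, "PRO", "CB", "C", x = 19, y = 0, z = 3.8),
    new_atoms("E", 90L, "CYS", "SG", "S", x = 10, y = 20, z = 4.2)
  )
  tcr <- bind_rows(tcr_a, tcr_b, planted) %>%
    mutate(x = .data$x + tcr_displacement[1],
           y = .data$y + tcr_displacement[2],
           z = .data$z + tcr_displacement[3])

  atoms <- bind_rows(mhc_a, mhc_a_sg, mhc_b, mhc_b_glu, pep, cit_o, tcr) %>%
    assign_chain_roles(roles = c(A = "mhc_alpha", B = "mhc_beta",
                                 C = "peptide", D = "tcr_alpha",
                                 E = "tcr_beta")) %>%
    assign_imgt_regions() %>%
    assign_peptide_register(p1_seq_id = 1015)

  displaced <- any(tcr_displacement != 0)
  truth_contacts <- if (displaced) {
    tibble(chain_a = character(), resno_a = integer(), atom_a = character(),
           chain_b = character(), resno_b = integer(), atom_b = character(),
           distance = double(), kind = character())
  } else {
    tibble(
      chain_a = c("D", "D", "D", "D", "D", "E", "E"),
      resno_a = c(113L, 113L, 58L, 58L, 58L, 110L, 90L),
      atom_a = c("ND2", "ND2", "NZ", "NZ", "NZ", "CB", "SG"),
      chain_b = c("C", "C", "B", "B", "B", "C", "A"),
      resno_b = c(1014L, 1014L, 70L, 70L, 70L, 1018L, 5L),
      atom_b = c("O7", "O7", "OE1", "OE1", "OE1", "CA", "SG"),
      distance = c(2.9, 2.9, 3.5, 3.5, 3.5, 3.8, 4.2),
      kind = c("hbond", "vdw", "salt_bridge", "hbond", "vdw", "vdw",
               "disulfide")
    )
  }
  list(
    atoms = atoms,
    truth = list(
      contacts = truth_contacts,
      docking_angle = docking_angle,
      p1_seq_id = 1015L,
      displaced = displaced
    )
  )
}

#' Simulate a steady-state SPR dilution series
#'
#' Generates equilibrium responses `Rmax * C / (KD + C)` on a geometric
#' dilution series with additive Gaussian noise, independent per replicate.
#' Defaults emulate the bench protocol: a 10-point twofold dilution from
#' 200 uM, Rmax 100 RU, sigma 2 RU, duplicate injections.
#'
#' @param kd Generating dissociation constant (uM).
#' @param rmax Saturation response (RU).
#' @param top_conc,dilution,n_conc Dilution series: top concentration (uM),
#'   fold dilution, number of points.
#' @param noise_sd Gaussian response noise (RU).
#' @param n_replicates Replicate curves.
#' @param seed RNG seed; required whenever `noise_sd > 0` so every curve is
#'   reproducible.
#' @return Tibble with `concentration_uM`, `response`, `replicate`.
#' @export
simulate_spr <- function(kd, rmax = 100, top_conc = 200, dilution = 2,
                         n_conc = 10, noise_sd = 2, n_replicates = 2,
                         seed = NULL) {
  stopifnot(kd > 0, rmax > 0, top_conc > 0, dilution > 1, n_conc >= 2,
            noise_sd >= 0, n_replicates >= 1)
  if (noise_sd > 0 && is.null(seed)) abort("A seed is required when noise_sd > 0")
  conc <- top_conc / dilution^(seq_len(n_conc) - 1)
  if (kd < min(conc) || kd > max(conc)) {
    warn("Concentration series does not span the generating KD")
  }
  mean_resp <- rmax * conc / (kd + conc)
  gen <- function() {
    purrr::map(seq_len(n_replicates), function(rep) {
      tibble(concentration_uM = conc,
             response = mean_resp + rnorm(n_conc, 0, noise_sd),
             replicate = rep)
    }) %>% bind_rows()
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a fluorescence-polarization competition series
#'
#' Generates normalized relative binding from a four-parameter logistic
#' `bottom + (top - bottom) / (1 + (C / ic50)^hill)` with additive Gaussian
#' noise. Defaults emulate the bench protocol: a 12-point threefold dilution
#' from 500 uM, triplicate wells, sigma 3%.
#'
#' @param ic50 Generating IC50 (uM).
#' @param hill Hill slope.
#' @param top,bottom Upper/lower plateaus (%).
#' @param top_conc,dilution,n_conc Dilution series.
#' @param noise_sd Gaussian noise on normalized binding (%).
#' @param n_replicates Replicate curves.
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return Tibble with `competitor_conc_uM`, `normalized_binding`,
#'   `replicate`.
#' @export
simulate_fp <- function(ic50, hill = 1, top = 100, bottom = 0,
                        top_conc = 500, dilution = 3, n_conc = 12,
                        noise_sd = 3, n_replicates = 3, seed = NULL) {
  stopifnot(ic50 > 0, top > bottom, top_conc > 0, dilution > 1, n_conc >= 2,
            noise_sd >= 0, n_replicates >= 1)
  if (noise_sd > 0 && is.null(seed)) abort("A seed is required when noise_sd > 0")
  conc <- top_conc / dilution^(seq_len(n_conc) - 1)
  mean_y <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  gen <- function() {
    purrr::map(seq_len(n_replicates), function(rep) {
      tibble(competitor_conc_uM = conc,
             normalized_binding = mean_y + rnorm(n_conc, 0, noise_sd),
             replicate = rep)
    }) %>% bind_rows()
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
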