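#' Deterministic Fibonacci sphere lattice
#'
#' Quasi-uniform unit-sphere sample points used by the Shrake-Rupley
#' algorithm. Deterministic for a given `n`, so SASA values are exactly
#' reproducible.
#'
#' @param n Number of points (>= 100 for meaningful areas).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  theta <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by rolling a solvent probe over the heavy-atom van
#' der Waals surface: each atom's solvent-expanded sphere (radius + probe) is
#' sampled on a deterministic Fibonacci lattice and points falling inside any
#' neighbouring expanded sphere are occluded. Waters/ligands (`het = TRUE`)
#' and hydrogens take no part; their `sasa` is `NA`.
#'
#' @param atoms Atom tibble; a `radius` column is added via [assign_radii()]
#'   if absent.
#' @param probe_radius Solvent probe radius in angstroms (default 1.4, a
#'   water molecule).
#' @param n_points Lattice sample count per atom (default 960).
#' @param radii,overrides Passed to [assign_radii()] when radii are missing.
#' @return The atom tibble with `radius` and `sasa` (square angstroms)
#'   columns.
#' @export
#' @examples
#' a <- tibble::tibble(chain = "A", resno = 1L, icode = "", resname = "ALA",
#'                     atom = "C", element = "C", altloc = "", occ = 1,
#'                     x = 0, y = 0, z = 0, het = FALSE)
#' compute_sasa(a)$sasa  # isolated sphere: 4*pi*(1.87 + 1.4)^2
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii(), overrides = NULL) {
  stopifnot(probe_radius >= 0, n_points >= 100)
  if (!"radius" %in% names(atoms)) {
    atoms <- assign_radii(atoms, radii = radii, overrides = overrides)
  }
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  use <- !atoms$het
  sasa <- rep(NA_real_, nrow(atoms))
  if (any(use)) {
    coords <- as.matrix(atoms[use, c("x", "y", "z")])
    storage.mode(coords) <- "double"
    rad <- atoms$radius[use] + probe_radius
    sasa[use] <- sasa_kernel(coords, rad, fibonacci_sphere(n_points))
  }
  dplyr::mutate(atoms, sasa = sasa)
}
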