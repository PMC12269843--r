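#' Van der Waals radii tables
#'
#' Element-keyed van der Waals radii (in angstroms) used for solvent-accessible
#' surface area and sphere-overlap computations. The default `"chothia"` set is
#' the classic protein crystallography table (Chothia-style, as used by
#' NACCESS-lineage programs); side-chain atoms of modified residues such as
#' citrulline (CIR) carry standard C/N/O radii, so no special casing is needed.
#'
#' @param set Name of the radii set. Currently `"chothia"`.
#' @return A named numeric vector mapping element symbols to radii in angstroms.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function(set = "chothia") {
  set <- match.arg(set, "chothia")
  c(
    C = 1.87, N = 1.65, O = 1.40, S = 1.85,
    P = 1.90, SE = 1.90, H = 1.20, D = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
  )
}

#' Assign van der Waals radii to atoms
#'
#' Adds a `radius` column to an atom tibble, looked up by element. Unknown
#' elements are an error unless an override is supplied, since a silent default
#' would corrupt every downstream area.
#'
#' @param atoms Atom tibble with an `element` column (see [read_structure()]).
#' @param radii Named radii vector, by default [vdw_radii()].
#' @param overrides Optional named vector of extra element -> radius entries.
#' @return The input tibble with a `radius` column (angstroms).
#' @export
assign_radii <- function(atoms, radii = vdw_radii(), overrides = NULL) {
  stopifnot(is.data.frame(atoms), "element" %in% names(atoms))
  tab <- radii
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  ele <- toupper(atoms$element)
  r <- unname(tab[ele])
  if (anyNA(r)) {
    bad <- unique(ele[is.na(r)])
    abort(paste0(
      "No van der Waals radius for element(s): ", paste(bad, collapse = ", "),
      ". Supply `overrides = c(", bad[1], " = <radius>)`."
    ))
  }
  dplyr::mutate(atoms, radius = r)
}
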