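#' Read a macromolecular structure into an atom tibble
#'
#' Parses a PDB or mmCIF file (via bio3d) into a one-row-per-atom tibble, the
#' container every downstream step of the package consumes. Alternate
#' locations are resolved by keeping the highest-occupancy conformer (ties go
#' to altloc "A"). Modified polymer residues -- citrulline (CIR) in
#' particular -- are retained in chain sequence; waters, ions and ligands are
#' kept but flagged `het = TRUE` and excluded from interface computations.
#' Hydrogens are dropped: all distance criteria in this package are
#' heavy-atom based.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param altloc One of `"highest-occupancy"` (default) or `"all"`.
#' @param drop_hydrogens Drop H/D atoms (default `TRUE`).
#' @return A tibble with columns `chain`, `resno`, `icode`, `resname`,
#'   `atom`, `element`, `altloc`, `occ`, `x`, `y`, `z`, `het`.
#' @export
read_structure <- function(path, altloc = c("highest-occupancy", "all"),
                           drop_hydrogens = TRUE) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) abort(paste0("Structure file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) abort(paste0("Cannot parse '", path, "': ", conditionMessage(e)))
  )
  atoms_from_bio3d(parsed, altloc = altloc, drop_hydrogens = drop_hydrogens)
}

# residue-level het call: modified amino acids (HETATM with a carbon CA) stay
# polymer; waters/ions/glycans are flagged het
atoms_from_bio3d <- function(pdb, altloc = "highest-occupancy",
                             drop_hydrogens = TRUE) {
  a <- tibble::as_tibble(pdb$atom)
  ele <- a$elesy
  if (is.null(ele)) ele <- rep(NA_character_, nrow(a))
  miss <- is.na(ele) | trimws(ele) == ""
  if (any(miss)) {
    ele[miss] <- suppressWarnings(bio3d::atom2ele(a$elety[miss], rescue = TRUE))
  }
  out <- tibble(
    chain = a$chain,
    resno = as.integer(a$resno),
    icode = dplyr::coalesce(a$insert, ""),
    resname = a$resid,
    atom = a$elety,
    element = toupper(trimws(ele)),
    altloc = dplyr::coalesce(a$alt, ""),
    occ = dplyr::coalesce(a$o, 1),
    x = a$x, y = a$y, z = a$z,
    rectype = a$type
  )
  out$icode[is.na(out$icode)] <- ""
  out$altloc[is.na(out$altloc)] <- ""
  if (drop_hydrogens) out <- dplyr::filter(out, !.data$element %in% c("H", "D"))
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("Non-finite coordinates in structure")
  }
  if (altloc == "highest-occupancy") out <- resolve_altlocs(out)

  out <- out %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$resname) %>%
    mutate(het = all(.data$rectype == "HETATM") &&
             !any(.data$atom == "CA" & .data$element == "C")) %>%
    ungroup() %>%
    select(-"rectype")
  if (!any(!out$het)) abort("Empty structure: no polymer residues found")
  out
}

resolve_altlocs <- function(atoms) {
  atoms %>%
    mutate(.ord = row_number()) %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$atom) %>%
    arrange(dplyr::desc(.data$occ), .data$altloc != "A", .data$altloc,
            .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}

#' Write an atom tibble as a PDB file
#'
#' Serializes an atom tibble (as produced by [read_structure()] or the
#' synthetic generators) to PDB format via bio3d. Round-tripping through this
#' writer preserves the residue/atom inventory.
#'
#' @param atoms Atom tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  het <- if ("het" %in% names(atoms)) atoms$het else rep(FALSE, nrow(atoms))
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(het, "HETATM", "ATOM"),
    resno = atoms$resno, resid = atoms$resname,
    eleno = seq_len(nrow(atoms)), elety = atoms$atom,
    chain = atoms$chain,
    insert = ifelse(atoms$icode == "", NA, atoms$icode),
    alt = ifelse(atoms$altloc == "", NA, atoms$altloc),
    o = atoms$occ, b = rep(0, nrow(atoms)), elesy = atoms$element
  )
  invisible(path)
}

#' Per-residue view of an atom tibble
#'
#' @param atoms Atom tibble.
#' @return Tibble with one row per residue (polymer only), in chain order.
#' @export
residues <- function(atoms) {
  atoms %>%
    filter(!.data$het) %>%
    distinct(.data$chain, .data$resno, .data$icode, .data$resname) %>%
    arrange(.data$chain, .data$resno, .data$icode)
}
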