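#' Default interface contact distance criteria
#'
#' Heavy-atom distance cutoffs in angstroms: hydrogen bond within 3.5,
#' van der Waals within 4.0, disulfide (SG-SG) within 4.5, salt bridge
#' (charged-group N-O) within 4.0.
#'
#' @return Named numeric vector of cutoffs.
#' @export
contact_criteria <- function() {
  c(hbond = 3.5, vdw = 4.0, disulfide = 4.5, salt_bridge = 4.0)
}

contact_kind_levels <- c("disulfide", "salt_bridge", "hbond", "vdw")

# side-chain atoms carrying formal charge; citrulline (CIR) is neutral and
# deliberately absent
salt_basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
salt_acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect and classify interface contacts
#'
#' Finds all heavy-atom pairs across the two interface sides within the
#' largest cutoff and classifies them: every pair within the vdw cutoff is a
#' `vdw` contact; nitrogen/oxygen donor-acceptor pairs (sulfur accepted as a
#' partner) within the hbond cutoff are additionally `hbond`; cysteine SG-SG
#' pairs within 4.5 are `disulfide`; Lys/Arg side-chain nitrogens against
#' Asp/Glu carboxylate oxygens within 4.0 are `salt_bridge`. A pair may carry
#' several kinds and yields one row per kind. Purely distance-based, matching
#' crystallographic contact-table conventions; no angular term.
#'
#' @param atoms Annotated atom tibble (roles assigned; region/pocket columns
#'   are carried through when present).
#' @param criteria Named cutoffs, see [contact_criteria()].
#' @param method `"grid"` (cell-list acceleration, default) or
#'   `"exhaustive"` (all-pairs scan). Both return identical contact sets.
#' @param side_a_roles,side_b_roles Role sets defining the interface sides.
#' @return A `contact_set` tibble: one row per (atom pair, kind) with atom
#'   identities of both partners, `distance` (angstroms) and `kind` (ordered
#'   factor, most specific first).
#' @export
detect_contacts <- function(atoms, criteria = contact_criteria(),
                            method = c("grid", "exhaustive"),
                            side_a_roles = c("tcr_alpha", "tcr_beta"),
                            side_b_roles = c("mhc_alpha", "mhc_beta",
                                             "peptide")) {
  method <- match.arg(method)
  stopifnot("role" %in% names(atoms))
  atoms <- dplyr::filter(atoms, !.data$het)
  if (!"region" %in% names(atoms)) atoms$region <- NA_character_
  if (!"pocket" %in% names(atoms)) atoms$pocket <- NA_character_
  ia <- which(atoms$role %in% side_a_roles)
  ib <- which(atoms$role %in% side_b_roles)
  maxcut <- max(criteria)
  empty <- contact_tibble(atoms, integer(0), integer(0), numeric(0))
  if (length(ia) == 0 || length(ib) == 0) return(empty)

  # candidate search uses a small slack, then distances are recomputed
  # per pair from the raw coordinates so grid and exhaustive results are
  # bit-identical
  pairs <- if (method == "grid") {
    grid_pairs(atoms, ia, ib, maxcut + 0.1)
  } else {
    exhaustive_pairs(atoms, ia, ib, maxcut + 0.1)
  }
  if (nrow(pairs) > 0) {
    pairs$d <- sqrt((atoms$x[pairs$i] - atoms$x[pairs$j])^2 +
                      (atoms$y[pairs$i] - atoms$y[pairs$j])^2 +
                      (atoms$z[pairs$i] - atoms$z[pairs$j])^2)
    pairs <- pairs[pairs$d <= maxcut, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(empty)

  ea <- atoms$element[pairs$i]
  eb <- atoms$element[pairs$j]
  d <- pairs$d
  kinds <- list()
  kinds$vdw <- d <= criteria[["vdw"]]
  polar <- function(e) e %in% c("N", "O", "S")
  no <- function(e) e %in% c("N", "O")
  kinds$hbond <- d <= criteria[["hbond"]] & polar(ea) & polar(eb) &
    (no(ea) | no(eb))
  kinds$disulfide <- d <= criteria[["disulfide"]] &
    atoms$atom[pairs$i] == "SG" & atoms$atom[pairs$j] == "SG" &
    ea == "S" & eb == "S"
  charged <- function(idx, table) {
    rn <- atoms$resname[idx]
    at <- atoms$atom[idx]
    purrr::map2_lgl(rn, at, function(r, a) a %in% (table[[r]] %||% character()))
  }
  basic_a <- charged(pairs$i, salt_basic); acidic_a <- charged(pairs$i, salt_acidic)
  basic_b <- charged(pairs$j, salt_basic); acidic_b <- charged(pairs$j, salt_acidic)
  kinds$salt_bridge <- d <= criteria[["salt_bridge"]] &
    ((basic_a & acidic_b) | (acidic_a & basic_b))

  rows <- purrr::imap(kinds, function(sel, kind) {
    if (!any(sel)) return(NULL)
    contact_tibble(atoms, pairs$i[sel], pairs$j[sel], d[sel], kind)
  })
  if (all(purrr::map_lgl(rows, is.null))) return(empty)
  out <- bind_rows(rows) %>%
    mutate(kind = factor(.data$kind, levels = contact_kind_levels)) %>%
    arrange(.data$chain_a, .data$resno_a, .data$atom_a, .data$distance,
            .data$kind)
  class(out) <- c("contact_set", class(out))
  out
}

contact_tibble <- function(atoms, i, j, d, kind = character(0)) {
  out <- tibble(
    chain_a = atoms$chain[i], resname_a = atoms$resname[i],
    resno_a = atoms$resno[i], atom_a = atoms$atom[i],
    role_a = atoms$role[i], region_a = atoms$region[i],
    chain_b = atoms$chain[j], resname_b = atoms$resname[j],
    resno_b = atoms$resno[j], atom_b = atoms$atom[j],
    role_b = atoms$role[j], pocket_b = atoms$pocket[j],
    distance = d,
    kind = if (length(d)) kind else factor(character(0),
                                           levels = contact_kind_levels)
  )
  class(out) <- c("contact_set", class(out))
  out
}

exhaustive_pairs <- function(atoms, ia, ib, maxcut) {
  ca <- as.matrix(atoms[ia, c("x", "y", "z")])
  cb <- as.matrix(atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  hit <- which(d2 <= maxcut^2, arr.ind = TRUE)
  tibble(i = ia[hit[, 1]], j = ib[hit[, 2]],
         d = sqrt(pmax(d2[hit], 0)))
}

grid_pairs <- function(atoms, ia, ib, maxcut) {
  cb <- as.matrix(atoms[ib, c("x", "y", "z")])
  gb <- floor(cb / maxcut)
  keyb <- paste(gb[, 1], gb[, 2], gb[, 3])
  bmap <- split(seq_along(ib), keyb)
  ca <- as.matrix(atoms[ia, c("x", "y", "z")])
  ga <- floor(ca / maxcut)
  keya <- paste(ga[, 1], ga[, 2], ga[, 3])
  amap <- split(seq_along(ia), keya)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  res <- purrr::map(names(amap), function(k) {
    asel <- amap[[k]]
    cell <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
    nk <- paste(cell[1] + off[, 1], cell[2] + off[, 2], cell[3] + off[, 3])
    bsel <- unlist(bmap[nk], use.names = FALSE)
    if (length(bsel) == 0) return(NULL)
    pa <- ca[asel, , drop = FALSE]
    pb <- cb[bsel, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    hit <- which(d2 <= maxcut^2, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble(i = ia[asel[hit[, 1]]], j = ib[bsel[hit[, 2]]],
           d = sqrt(pmax(d2[hit], 0)))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) tibble(i = integer(), j = integer(), d = double())
  else out
}

#' Summarize the TCR footprint by region
#'
#' Builds the per-loop footprint table: one row per TCR region label (CDR1a
#' ... FWb, all regions present in the annotation, zeros where a loop makes
#' no contact), with buried-surface-area percentage, contact counts by kind,
#' the peptide pockets contacted, and the split of contacts between peptide
#' and MHC.
#'
#' @param contacts A `contact_set` from [detect_contacts()].
#' @param atoms The annotated atom tibble (for the full region label set).
#' @param bsa Optional `bsa_breakdown` supplying the BSA percentages.
#' @return A tibble with one row per region label.
#' @export
summarize_footprint <- function(contacts, atoms, bsa = NULL) {
  stopifnot(all(c("role", "region") %in% names(atoms)))
  labels <- atoms %>%
    filter(.data$role %in% c("tcr_alpha", "tcr_beta"), !is.na(.data$region)) %>%
    distinct(.data$region, .data$role) %>%
    mutate(label = region_label(.data$region, .data$role)) %>%
    pull(.data$label)
  labels <- unique(labels)
  per <- purrr::map(labels, function(lab) {
    sub <- contacts %>%
      filter(!is.na(.data$region_a),
             region_label(.data$region_a, .data$role_a) == lab)
    pockets <- sort(unique(sub$pocket_b[!is.na(sub$pocket_b)]))
    tibble(
      label = lab,
      n_contacts = nrow(sub),
      n_hbond = sum(sub$kind == "hbond"),
      n_vdw = sum(sub$kind == "vdw"),
      n_salt_bridge = sum(sub$kind == "salt_bridge"),
      n_disulfide = sum(sub$kind == "disulfide"),
      n_to_peptide = sum(sub$role_b == "peptide"),
      n_to_mhc = sum(sub$role_b != "peptide"),
      pockets = paste(pockets, collapse = ",")
    )
  }) %>% bind_rows()
  if (!is.null(bsa) && !is.null(bsa$per_region)) {
    per <- left_join(per, select(bsa$per_region, "label", bsa_pct = "pct"),
                     by = "label") %>%
      mutate(bsa_pct = dplyr::coalesce(.data$bsa_pct, 0))
  }
  arrange(per, dplyr::desc(.data$n_contacts))
}
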