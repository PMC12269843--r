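#' Default IMGT region boundaries for TCR variable domains
#'
#' Inclusive IMGT unique-numbering intervals for the complementarity
#' determining regions; every other variable-domain position (1-129) is
#' framework (FW). Residues numbered beyond 129 belong to the constant domain
#' and are left unlabelled.
#'
#' @return Named list of `c(from, to)` integer pairs plus the variable-domain
#'   span under `variable`.
#' @export
imgt_default_ranges <- function() {
  list(
    CDR1 = c(27L, 38L),
    CDR2 = c(56L, 65L),
    CDR3 = c(105L, 117L),
    variable = c(1L, 129L)
  )
}

#' Assign chain roles in a TCR-pMHC-II complex
#'
#' Labels every chain of the structure with its role in the ternary complex:
#' `tcr_alpha`, `tcr_beta`, `mhc_alpha`, `mhc_beta`, `peptide`, or `other`.
#' Chains absent from `roles` are auto-detected as `peptide` when their
#' polymer length is 9-25 residues (the bound epitope including flanking
#' residues is a 14-mer), otherwise `other`.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param roles Named character vector `c(chain_id = role, ...)`; may be
#'   partial or `NULL` (auto-detect peptide only).
#' @param mode `"ternary"` (all five roles required) or `"apo"` (the two TCR
#'   roles required).
#' @param peptide_len Length window for peptide auto-detection.
#' @return The atom tibble with a `role` column.
#' @export
assign_chain_roles <- function(atoms, roles = NULL,
                               mode = c("ternary", "apo"),
                               peptide_len = c(9L, 25L)) {
  mode <- match.arg(mode)
  role_levels <- c("tcr_alpha", "tcr_beta", "mhc_alpha", "mhc_beta",
                   "peptide", "other")
  if (!is.null(roles)) {
    if (!all(roles %in% role_levels)) {
      abort(paste0("Unknown role(s): ",
                   paste(setdiff(roles, role_levels), collapse = ", ")))
    }
    named <- roles[roles != "other"]
    if (anyDuplicated(named)) {
      abort("Config error: two chains mapped to the same role")
    }
  }
  res <- residues(atoms)
  chain_len <- res %>% group_by(.data$chain) %>%
    summarise(len = dplyr::n(), .groups = "drop")
  chain_role <- setNames(rep("other", nrow(chain_len)), chain_len$chain)
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), chain_len$chain)
    if (length(unknown) > 0) {
      abort(paste0("Config names chain(s) absent from structure: ",
                   paste(unknown, collapse = ", ")))
    }
    chain_role[names(roles)] <- unname(roles)
  }
  if (!"peptide" %in% chain_role) {
    cand <- chain_len$chain[chain_len$len >= peptide_len[1] &
                              chain_len$len <= peptide_len[2] &
                              chain_role[chain_len$chain] == "other"]
    if (length(cand) == 1) chain_role[cand] <- "peptide"
  }
  need <- if (mode == "ternary") {
    c("tcr_alpha", "tcr_beta", "mhc_alpha", "mhc_beta", "peptide")
  } else {
    c("tcr_alpha", "tcr_beta")
  }
  missing_roles <- setdiff(need, chain_role)
  if (length(missing_roles) > 0) {
    abort(paste0("Role error (mode = ", mode, "): unassigned role(s): ",
                 paste(missing_roles, collapse = ", ")))
  }
  pep_chain <- names(chain_role)[chain_role == "peptide"]
  if (length(pep_chain) == 1) {
    plen <- chain_len$len[chain_len$chain == pep_chain]
    if (plen < 8) abort("Peptide chain shorter than 8 residues")
  }
  dplyr::mutate(atoms, role = unname(chain_role[.data$chain]))
}

#' Assign IMGT CDR/framework regions to TCR chains
#'
#' Labels every TCR variable-domain residue (IMGT positions 1-129) as CDR1,
#' CDR2, CDR3 or FW using inclusive residue-number intervals. Assumes the
#' deposited coordinates already follow IMGT unique numbering. Constant-domain
#' residues (numbered beyond the variable span) are left `NA`.
#'
#' @param atoms Atom tibble with a `role` column ([assign_chain_roles()]).
#' @param ranges IMGT intervals, by default [imgt_default_ranges()].
#' @return The atom tibble with a `region` column (`NA` outside TCR variable
#'   domains).
#' @export
assign_imgt_regions <- function(atoms, ranges = imgt_default_ranges()) {
  stopifnot("role" %in% names(atoms))
  cdr <- ranges[c("CDR1", "CDR2", "CDR3")]
  iv <- do.call(rbind, cdr)
  if (any(iv[, 1] > iv[, 2])) abort("Malformed IMGT interval")
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)])) {
    abort("IMGT intervals overlap within a chain")
  }
  vspan <- ranges$variable %||% c(1L, 129L)
  is_tcr <- atoms$role %in% c("tcr_alpha", "tcr_beta")
  rn <- atoms$resno
  region <- rep(NA_character_, nrow(atoms))
  in_v <- is_tcr & rn >= vspan[1] & rn <= vspan[2]
  region[in_v] <- "FW"
  for (lab in names(cdr)) {
    hit <- in_v & rn >= cdr[[lab]][1] & rn <= cdr[[lab]][2]
    region[hit] <- lab
  }
  below <- is_tcr & rn < vspan[1]
  if (any(below)) {
    warn("TCR residue numbered below the variable-domain span; labelled FW")
    region[below] <- "FW"
  }
  dplyr::mutate(atoms, region = region)
}

#' Assign the MHC-II pocket register to the peptide chain
#'
#' Maps each peptide residue to its binding-groove pocket, anchored at the P1
#' residue: upstream residues become P-1 and P-2, downstream P2..P9, and
#' anything beyond that window (e.g. C-terminal solubility lysines) is
#' labelled `flank`.
#'
#' @param atoms Atom tibble with a `role` column.
#' @param p1_seq_id Author residue number of the P1 anchor residue.
#' @return The atom tibble with a `pocket` column (`NA` off the peptide
#'   chain).
#' @export
assign_peptide_register <- function(atoms, p1_seq_id) {
  stopifnot("role" %in% names(atoms))
  pep <- residues(dplyr::filter(atoms, .data$role == "peptide"))
  if (nrow(pep) == 0) abort("No peptide chain to assign a register to")
  k <- which(pep$resno == p1_seq_id)
  if (length(k) != 1) {
    abort(paste0("Register error: P1 residue ", p1_seq_id,
                 " not found (or ambiguous) in peptide chain"))
  }
  offset <- seq_len(nrow(pep)) - k   # 0 at P1
  pocket <- dplyr::case_when(
    offset >= 0 & offset <= 8 ~ paste0("P", offset + 1),
    offset %in% c(-1L, -2L) ~ paste0("P", offset),
    TRUE ~ "flank"
  )
  pep$pocket <- pocket
  atoms %>%
    select(-dplyr::any_of("pocket")) %>%
    left_join(select(pep, "chain", "resno", "icode", "pocket"),
              by = c("chain", "resno", "icode"))
}

#' One-letter sequence of a chain
#'
#' @param atoms Atom tibble.
#' @param chain Chain identifier.
#' @return Character scalar; non-standard residues (e.g. CIR) become `X`.
#' @export
chain_sequence <- function(atoms, chain) {
  res <- residues(dplyr::filter(atoms, .data$chain == !!chain))
  paste(suppressWarnings(bio3d::aa321(res$resname)), collapse = "")
}

#' Detect the HLA-DRB1 shared-epitope motif
#'
#' Tests whether mature-chain positions 70-74 of an MHC class II beta-chain
#' sequence match one of the rheumatoid-arthritis risk pentapeptides QKRAA,
#' QRRAA or RRRAA (case-insensitive). The result depends only on the 70-74
#' window.
#'
#' @param sequence One-letter amino-acid string of the beta chain.
#' @param numbering_offset Mature position of `substr(sequence, 1, 1)` minus
#'   one; 0 when the string starts at mature position 1.
#' @return One-row tibble: `positive`, `motif` (matched pentapeptide or
#'   `""`), `window` (the 70-74 pentapeptide).
#' @export
detect_shared_epitope <- function(sequence, numbering_offset = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  i <- 70 - numbering_offset
  j <- 74 - numbering_offset
  if (i < 1 || j > nchar(sequence)) {
    abort("Coverage error: sequence does not span mature positions 70-74")
  }
  window <- toupper(substr(sequence, i, j))
  motifs <- c("QKRAA", "QRRAA", "RRRAA")
  hit <- motifs[motifs == window]
  tibble(
    positive = length(hit) == 1,
    motif = if (length(hit) == 1) hit else "",
    window = window
  )
}
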