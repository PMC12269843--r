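#' Build and validate a run configuration
#'
#' Normalizes a configuration (a named list or a YAML/JSON file path) for the
#' interface pipeline, rejecting unknown keys before any computation starts.
#'
#' @param config Named list, or path to a YAML (or JSON) config file.
#' @return Validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    structure = NULL, mode = "ternary", roles = NULL, imgt_ranges = NULL,
    p1_seq_id = NULL, se_offset = 0,
    hbond_cutoff = 3.5, vdw_cutoff = 4.0, disulfide_cutoff = 4.5,
    salt_bridge_cutoff = 4.0,
    probe_radius = 1.4, n_points = 960,
    holo_reference = NULL, out_dir = ".", verbose = FALSE
  )
  # se_offset NULL means: derive from the beta chain's first residue number
  defaults["se_offset"] <- list(NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$structure)) abort("Config error: `structure` path missing")
  if (identical(cfg$mode, "ternary")) {
    if (is.null(cfg$roles)) abort("Config error: `roles` map missing")
    if (is.null(cfg$p1_seq_id)) abort("Config error: `p1_seq_id` missing")
  }
  cfg
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

config_digest <- function(cfg) rlang::hash(cfg)

#' Run the full interface analysis and write a report bundle
#'
#' Orchestrates the structural pipeline on one complex: parse, annotate
#' (roles, IMGT regions, pocket register, shared-epitope status), buried
#' surface area with region decomposition, classified contacts, docking
#' geometry, and a footprint table. Writes `bsa.json`, `contacts.tsv`,
#' `footprint.tsv`, `geometry.json`, `se.json` and a human-readable
#' `summary.txt` into `out_dir`; every file embeds nothing random, so
#' identical config and inputs give byte-identical output. In `mode =
#' "apo"` only a superposition against `holo_reference` (TCR C-alpha
#' r.m.s.d.) is computed.
#'
#' @param config See [run_config()]. Keys: `structure` (file path), `mode`
#'   (`"ternary"`/`"apo"`), `roles` (chain -> role), `p1_seq_id`, optional
#'   `imgt_ranges`, cutoffs (`hbond_cutoff` etc.), `probe_radius`,
#'   `n_points`, `holo_reference`, `out_dir`.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_interface <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(cfg)
  provenance <- list(tool = "tcrint",
                     version = as.character(utils::packageVersion("tcrint")),
                     config_digest = digest)
  atoms <- read_structure(cfg$structure)
  roles <- if (is.null(cfg$roles)) NULL else unlist(cfg$roles)

  if (identical(cfg$mode, "apo")) {
    if (is.null(cfg$holo_reference)) {
      abort("Config error: apo mode needs `holo_reference`")
    }
    tcr_roles <- roles[roles %in% c("tcr_alpha", "tcr_beta")]
    apo <- assign_chain_roles(atoms, roles = tcr_roles, mode = "apo")
    holo <- read_structure(cfg$holo_reference)
    # match TCR C-alpha atoms by chain role + residue id
    sup <- superpose_tcr(holo, apo, holo_roles = roles)
    out <- file.path(cfg$out_dir, "superposition.json")
    jsonlite::write_json(
      c(provenance, list(rmsd = round(sup$rmsd, 2), n_atoms = sup$n)),
      out, auto_unbox = TRUE, digits = NA
    )
    summary_path <- file.path(cfg$out_dir, "summary.txt")
    writeLines(c(
      paste0("tcrint apo superposition (config ", digest, ")"),
      sprintf("TCR C-alpha r.m.s.d.: %s A over %d atoms",
              fmt_num(sup$rmsd, 2), sup$n)
    ), summary_path)
    return(invisible(list(superposition = sup,
                          paths = c(out, summary_path))))
  }

  imgt <- cfg$imgt_ranges %||% imgt_default_ranges()
  ann <- atoms %>%
    assign_chain_roles(roles = roles, mode = "ternary") %>%
    assign_imgt_regions(ranges = imgt) %>%
    assign_peptide_register(p1_seq_id = cfg$p1_seq_id)
  criteria <- c(hbond = cfg$hbond_cutoff, vdw = cfg$vdw_cutoff,
                disulfide = cfg$disulfide_cutoff,
                salt_bridge = cfg$salt_bridge_cutoff)
  bsa <- compute_bsa(ann, probe_radius = cfg$probe_radius,
                     n_points = cfg$n_points)
  contacts <- detect_contacts(ann, criteria = criteria)
  geom <- docking_geometry(ann)
  foot <- summarize_footprint(contacts, ann, bsa)
  beta_chain <- unique(ann$chain[ann$role == "mhc_beta"])
  beta_start <- min(ann$resno[ann$role == "mhc_beta" & !ann$het])
  se <- detect_shared_epitope(chain_sequence(ann, beta_chain),
                              numbering_offset = cfg$se_offset %||%
                                (beta_start - 1))

  paths <- character()
  p <- file.path(cfg$out_dir, "bsa.json")
  jsonlite::write_json(c(provenance, list(
    total_bsa = round(bsa$total_bsa, 1),
    tcr_side_bsa = round(bsa$side_a_bsa, 1),
    pmhc_side_bsa = round(bsa$side_b_bsa, 1),
    chain_share_pct = setNames(as.list(round(bsa$chain_share$pct, 1)),
                               bsa$chain_share$role),
    per_region_pct = setNames(as.list(round(bsa$per_region$pct, 1)),
                              bsa$per_region$label),
    note = "total BSA is the two-sided sum SASA(TCR)+SASA(pMHC)-SASA(complex)"
  )), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  p <- file.path(cfg$out_dir, "contacts.tsv")
  ct <- contacts %>%
    mutate(distance = fmt_num(.data$distance, 2)) %>%
    arrange(.data$chain_a, .data$resno_a, .data$atom_a, .data$kind)
  utils::write.table(ct, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(cfg$out_dir, "footprint.tsv")
  ft <- foot
  if ("bsa_pct" %in% names(ft)) ft$bsa_pct <- fmt_num(ft$bsa_pct, 1)
  utils::write.table(ft, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(cfg$out_dir, "geometry.json")
  jsonlite::write_json(c(provenance, list(
    docking_angle = round(geom$docking_angle, 1),
    v_alpha_centroid = round(geom$v_alpha_centroid, 2),
    v_beta_centroid = round(geom$v_beta_centroid, 2),
    peptide_axis = round(geom$peptide_axis, 4)
  )), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  p <- file.path(cfg$out_dir, "se.json")
  jsonlite::write_json(c(provenance, as.list(se)), p, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, p)

  summary_path <- file.path(cfg$out_dir, "summary.txt")
  region_lines <- sprintf("  %-6s %s%%", bsa$per_region$label,
                          fmt_num(bsa$per_region$pct, 1))
  writeLines(c(
    paste0("tcrint interface report (config ", digest, ")"),
    sprintf("Total BSA: %s A^2 (TCR side %s + pMHC side %s; two-sided sum)",
            fmt_num(bsa$total_bsa, 1), fmt_num(bsa$side_a_bsa, 1),
            fmt_num(bsa$side_b_bsa, 1)),
    paste0("TCR chain share: ",
           paste(sprintf("%s %s%%", bsa$chain_share$role,
                         fmt_num(bsa$chain_share$pct, 1)), collapse = ", ")),
    "Region share of TCR-side burial:",
    region_lines,
    sprintf("Docking angle: %s degrees", fmt_num(geom$docking_angle, 1)),
    sprintf("Contacts: %d rows (%d hbond, %d vdw, %d salt bridge, %d disulfide)",
            nrow(contacts), sum(contacts$kind == "hbond"),
            sum(contacts$kind == "vdw"),
            sum(contacts$kind == "salt_bridge"),
            sum(contacts$kind == "disulfide")),
    sprintf("Shared epitope: %s (window %s)",
            if (se$positive) paste0("positive, ", se$motif) else "negative",
            se$window)
  ), summary_path)
  paths <- c(paths, summary_path)

  invisible(list(atoms = ann, bsa = bsa, contacts = contacts,
                 geometry = geom, footprint = foot, se = se, paths = paths))
}

# superpose TCR C-alpha traces of two structures, matching on chain role and
# residue number
superpose_tcr <- function(ref_atoms, mov_atoms, holo_roles = NULL,
                          ref_roles = NULL) {
  if (!"role" %in% names(ref_atoms)) {
    ref_atoms <- assign_chain_roles(ref_atoms, roles = ref_roles %||%
                                      holo_roles, mode = "ternary")
  }
  ca <- function(a) {
    a %>%
      filter(!.data$het, .data$atom == "CA",
             .data$role %in% c("tcr_alpha", "tcr_beta")) %>%
      distinct(.data$role, .data$resno, .data$icode, .keep_all = TRUE)
  }
  r <- ca(ref_atoms)
  m <- ca(mov_atoms)
  key <- c("role", "resno", "icode")
  matched <- dplyr::inner_join(
    select(r, dplyr::all_of(key), rx = "x", ry = "y", rz = "z"),
    select(m, dplyr::all_of(key), mx = "x", my = "y", mz = "z"),
    by = key
  )
  if (nrow(matched) < 3) abort("Fewer than 3 matched TCR C-alpha atoms")
  superpose(
    ref = matrix(c(matched$rx, matched$ry, matched$rz), ncol = 3),
    mov = matrix(c(matched$mx, matched$my, matched$mz), ncol = 3)
  )
}

#' Fit binding curves from CSV inputs and write a report bundle
#'
#' Orchestrates the assay computations: steady-state SPR fits (columns
#' `concentration_uM`, `response`, optional `replicate`, optional `sample`),
#' four-bin impact classification against a wild-type reference, and
#' fluorescence-polarization competition fits (`competitor_conc_uM`,
#' `normalized_binding`). Unresolved competition fits are reported as
#' `"> <max tested>"`.
#'
#' @param config Named list with any of: `spr_csv` (path), `wildtype`
#'   (sample name of the wild-type row for impact classification), `fp_csv`
#'   (path), `out_dir`.
#' @return Invisibly, a list with `kd_table` and/or `ic50_table` tibbles and
#'   output paths.
#' @export
run_binding <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c("spr_csv", "fp_csv", "wildtype",
                                      "out_dir"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(paths = character())

  if (!is.null(config$spr_csv)) {
    spr <- read_assay_csv(config$spr_csv,
                          c("concentration_uM", "response"))
    if (!"sample" %in% names(spr)) spr$sample <- "sample"
    kd_table <- spr %>%
      group_by(.data$sample) %>%
      dplyr::group_modify(~ glance(fit_steady_state(.x))) %>%
      ungroup()
    if (!is.null(config$wildtype)) {
      wt_kd <- kd_table$kd[kd_table$sample == config$wildtype]
      if (length(wt_kd) != 1) {
        abort(paste0("Wild-type sample '", config$wildtype,
                     "' not found in SPR table"))
      }
      kd_table <- dplyr::bind_cols(kd_table,
                                   classify_impact(kd_table$kd, wt_kd))
    }
    p <- file.path(out_dir, "kd_table.tsv")
    out_tab <- kd_table %>%
      mutate(dplyr::across(dplyr::where(is.numeric),
                           ~ signif(.x, 3)))
    utils::write.table(out_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$kd_table <- kd_table
    res$paths <- c(res$paths, p)
  }

  if (!is.null(config$fp_csv)) {
    fp <- read_assay_csv(config$fp_csv,
                         c("competitor_conc_uM", "normalized_binding"))
    if (!"sample" %in% names(fp)) fp$sample <- "sample"
    ic50_table <- fp %>%
      group_by(.data$sample) %>%
      dplyr::group_modify(~ glance(fit_competition(.x))) %>%
      ungroup()
    p <- file.path(out_dir, "ic50_table.tsv")
    out_tab <- ic50_table %>%
      mutate(dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 3)))
    utils::write.table(out_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$ic50_table <- ic50_table
    res$paths <- c(res$paths, p)
  }
  invisible(res)
}

read_assay_csv <- function(path, required) {
  if (!file.exists(path)) abort(paste0("CSV not found: ", path))
  df <- tryCatch(as_tibble(read.csv(path, stringsAsFactors = FALSE)),
                 error = function(e) {
                   abort(paste0("Cannot parse '", path, "': ",
                                conditionMessage(e)))
                 })
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV '", path, "' missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!complete.cases(df[required]))
  if (length(bad) > 0) {
    abort(paste0("CSV '", path, "' has malformed row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  df
}
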