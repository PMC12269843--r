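#' Buried surface area of the TCR-pMHC interface
#'
#' Computes the interface buried surface area as
#' `BSA = SASA(side A) + SASA(side B) - SASA(complex)`, i.e. the two-sided sum
#' of solvent-accessible area lost on complex formation. By default side A is
#' the TCR (alpha + beta chains) and side B the pMHC (MHC alpha + beta +
#' peptide). Burial is attributed to the residue that owns each atom; region
#' percentages are computed over the TCR-side burial, which is how CDR-loop
#' footprint contributions are conventionally reported.
#'
#' @param atoms Annotated atom tibble (roles assigned; regions recommended).
#' @param probe_radius,n_points,radii,overrides Passed to [compute_sasa()].
#' @param side_a_roles,side_b_roles Role sets defining the two interface
#'   sides.
#' @return A `bsa_breakdown` object: list with `total_bsa`, `side_a_bsa`
#'   (TCR), `side_b_bsa` (pMHC), `chain_share` (percent split of TCR-side
#'   burial by alpha/beta chain), `per_residue` and `per_region` tibbles, and
#'   the SASA parameters used.
#' @export
compute_bsa <- function(atoms, probe_radius = 1.4, n_points = 960,
                        radii = vdw_radii(), overrides = NULL,
                        side_a_roles = c("tcr_alpha", "tcr_beta"),
                        side_b_roles = c("mhc_alpha", "mhc_beta", "peptide")) {
  stopifnot("role" %in% names(atoms))
  atoms <- dplyr::filter(atoms, !.data$het)
  a_idx <- atoms$role %in% side_a_roles
  b_idx <- atoms$role %in% side_b_roles
  if (!any(a_idx) || !any(b_idx)) {
    abort("Interface error: both sides of the interface must contain atoms")
  }
  both <- atoms[a_idx | b_idx, ]
  sasa_cx <- compute_sasa(both, probe_radius, n_points, radii, overrides)$sasa
  side <- ifelse(both$role %in% side_a_roles, "A", "B")
  sasa_free <- rep(NA_real_, nrow(both))
  for (s in c("A", "B")) {
    sel <- side == s
    sasa_free[sel] <-
      compute_sasa(both[sel, ], probe_radius, n_points, radii, overrides)$sasa
  }
  burial <- pmax(sasa_free - sasa_cx, 0)
  both$burial <- burial
  both$side <- side

  per_residue <- both %>%
    group_by(.data$side, .data$role, .data$chain, .data$resno, .data$icode,
             .data$resname) %>%
    summarise(bsa = sum(.data$burial), .groups = "drop") %>%
    arrange(.data$side, .data$chain, .data$resno)

  side_a_bsa <- sum(burial[side == "A"])
  side_b_bsa <- sum(burial[side == "B"])

  chain_share <- both %>%
    filter(.data$side == "A") %>%
    group_by(.data$role) %>%
    summarise(bsa = sum(.data$burial), .groups = "drop") %>%
    mutate(pct = 100 * .data$bsa / sum(.data$bsa))

  per_region <- NULL
  if ("region" %in% names(both)) {
    per_region <- both %>%
      filter(.data$side == "A", !is.na(.data$region)) %>%
      mutate(label = region_label(.data$region, .data$role)) %>%
      group_by(.data$label) %>%
      summarise(bsa = sum(.data$burial), .groups = "drop") %>%
      mutate(pct = if (sum(.data$bsa) > 0) 100 * .data$bsa / sum(.data$bsa)
             else 0 * .data$bsa) %>%
      arrange(dplyr::desc(.data$pct))
  }

  structure(
    list(
      total_bsa = side_a_bsa + side_b_bsa,
      side_a_bsa = side_a_bsa,
      side_b_bsa = side_b_bsa,
      chain_share = chain_share,
      per_residue = per_residue,
      per_region = per_region,
      params = list(probe_radius = probe_radius, n_points = n_points,
                    side_a_roles = side_a_roles, side_b_roles = side_b_roles)
    ),
    class = "bsa_breakdown"
  )
}

# "CDR3" + tcr_alpha -> "CDR3a"; framework -> "FWa"/"FWb"
region_label <- function(region, role) {
  paste0(region, ifelse(role == "tcr_alpha", "a", "b"))
}

#' @export
print.bsa_breakdown <- function(x, ...) {
  cat("Buried surface area breakdown\n")
  cat(sprintf("  total BSA: %.1f A^2 (TCR side %.1f + pMHC side %.1f)\n",
              x$total_bsa, x$side_a_bsa, x$side_b_bsa))
  if (nrow(x$chain_share) > 0) {
    sh <- sprintf("%s %.1f%%", x$chain_share$role, x$chain_share$pct)
    cat("  TCR chain share:", paste(sh, collapse = ", "), "\n")
  }
  if (!is.null(x$per_region)) {
    cat("  region shares (% of TCR-side burial):\n")
    for (i in seq_len(nrow(x$per_region))) {
      cat(sprintf("    %-6s %5.1f%%\n", x$per_region$label[i],
                  x$per_region$pct[i]))
    }
  }
  invisible(x)
}

#' @describeIn compute_bsa Per-region tibble (label, buried area, percent of
#'   TCR-side burial).
#' @param x A `bsa_breakdown` object.
#' @param ... Unused.
#' @export
tidy.bsa_breakdown <- function(x, ...) {
  if (is.null(x$per_region)) return(tibble(label = character(),
                                           bsa = double(), pct = double()))
  x$per_region
}

#' @describeIn compute_bsa One-row summary (total, per-side and per-chain
#'   percentages).
#' @export
glance.bsa_breakdown <- function(x, ...) {
  alpha <- x$chain_share$pct[x$chain_share$role == "tcr_alpha"]
  beta <- x$chain_share$pct[x$chain_share$role == "tcr_beta"]
  tibble(
    total_bsa = x$total_bsa,
    tcr_side_bsa = x$side_a_bsa,
    pmhc_side_bsa = x$side_b_bsa,
    alpha_share_pct = if (length(alpha)) alpha else NA_real_,
    beta_share_pct = if (length(beta)) beta else NA_real_
  )
}
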