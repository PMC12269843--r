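#' TCR docking geometry over the peptide
#'
#' Computes the docking angle of the TCR over the MHC-bound peptide: the
#' angle between the line connecting the V-alpha and V-beta domain centroids
#' (centroids over variable-domain C-alpha atoms, IMGT positions within
#' `v_span`) and the total-least-squares axis through the peptide C-alpha
#' trace, folded to the range 0-90 degrees so the convention is
#' sign-independent. Flanking peptide residues (pocket label `flank`) are
#' excluded from the axis when a register is annotated.
#'
#' @param atoms Annotated atom tibble (roles assigned).
#' @param v_span Inclusive residue-number span of the variable domains.
#' @return A `docking_geometry` object: `v_alpha_centroid`,
#'   `v_beta_centroid`, `peptide_axis` (unit vector, N- to C-terminal),
#'   `docking_angle` (degrees in \[0, 90\]).
#' @export
docking_geometry <- function(atoms, v_span = c(1L, 129L)) {
  stopifnot("role" %in% names(atoms))
  ca <- atoms %>%
    filter(!.data$het, .data$atom == "CA", .data$element == "C")
  cen <- function(role) {
    sub <- ca %>% filter(.data$role == !!role,
                         .data$resno >= v_span[1], .data$resno <= v_span[2])
    if (nrow(sub) == 0) {
      abort(paste0("Geometry error: no variable-domain C-alpha for ", role))
    }
    colMeans(as.matrix(sub[, c("x", "y", "z")]))
  }
  va <- cen("tcr_alpha")
  vb <- cen("tcr_beta")
  pep <- ca %>% filter(.data$role == "peptide")
  if ("pocket" %in% names(atoms)) {
    core <- pep %>% filter(is.na(.data$pocket) | .data$pocket != "flank")
    if (nrow(core) >= 5) pep <- core
  }
  if (nrow(pep) < 5) {
    abort("Geometry error: need at least 5 peptide C-alpha atoms")
  }
  pm <- as.matrix(pep[, c("x", "y", "z")])
  axis <- prcomp(pm, center = TRUE)$rotation[, 1]
  ends <- pm[nrow(pm), ] - pm[1, ]
  if (sum(axis * ends) < 0) axis <- -axis
  u <- vb - va
  cosang <- abs(sum(u * axis)) / (sqrt(sum(u^2)) * sqrt(sum(axis^2)))
  structure(
    list(
      v_alpha_centroid = va,
      v_beta_centroid = vb,
      peptide_axis = axis / sqrt(sum(axis^2)),
      docking_angle = acos(pmin(1, cosang)) * 180 / pi
    ),
    class = "docking_geometry"
  )
}

#' @export
print.docking_geometry <- function(x, ...) {
  cat(sprintf("Docking angle: %.1f degrees\n", x$docking_angle))
  invisible(x)
}

#' @describeIn docking_geometry One-row tibble with the docking angle and
#'   centroid coordinates.
#' @param x A `docking_geometry` object.
#' @param ... Unused.
#' @export
glance.docking_geometry <- function(x, ...) {
  tibble(
    docking_angle = x$docking_angle,
    v_alpha_x = x$v_alpha_centroid[1], v_alpha_y = x$v_alpha_centroid[2],
    v_alpha_z = x$v_alpha_centroid[3],
    v_beta_x = x$v_beta_centroid[1], v_beta_y = x$v_beta_centroid[2],
    v_beta_z = x$v_beta_centroid[3]
  )
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  stopifnot(is.data.frame(x), all(c("x", "y", "z") %in% names(x)))
  unname(as.matrix(x[, c("x", "y", "z")]))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the r.m.s.d. between
#' two matched coordinate sets, via singular value decomposition of the
#' covariance matrix with the determinant sign corrected so reflections are
#' never returned.
#'
#' @param ref,mov Matched coordinate sets: n x 3 matrices or atom tibbles
#'   with `x`, `y`, `z` columns (n >= 3).
#' @param selection Optional integer indices of matched rows to use.
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (angstroms), `n`. The transformed mover
#'   is `mov %*% t(rotation) + translation` rowwise.
#' @export
superpose <- function(ref, mov, selection = NULL) {
  P <- as_coord_matrix(mov)
  Q <- as_coord_matrix(ref)
  if (!is.null(selection)) {
    P <- P[selection, , drop = FALSE]
    Q <- Q[selection, , drop = FALSE]
  }
  if (nrow(P) != nrow(Q)) {
    abort("Selection error: coordinate sets have different lengths")
  }
  if (nrow(P) < 3) abort("Need at least 3 matched atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  if (sum(sv$d > max(sv$d) * 1e-8) < 2) {
    warn("Rank-deficient (collinear) selection; rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(cq - R %*% cp),
      rmsd = rmsd,
      n = nrow(P)
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: r.m.s.d. %.2f A\n", x$n, x$rmsd))
  invisible(x)
}

#' @describeIn superpose One-row tibble with `rmsd` and `n`.
#' @param x A `superposition` object.
#' @param ... Unused.
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n = x$n)
}
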