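# shared fixture builders -- everything is generated in code, nothing binary

pdb_line <- function(resno, resname, atom, element, x, y, z,
                     chain = "A", occ = 1, alt = "", icode = "",
                     rectype = "ATOM", serial = 1) {
  name_field <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else atom
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, name_field, alt, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# random two-sided atom cloud for grid-vs-exhaustive contact checks
random_interface_atoms <- function(n = 500, seed = 1, box = 25) {
  withr::with_seed(seed, {
    half <- n %/% 2
    elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                       prob = c(0.6, 0.2, 0.15, 0.05))
    tibble::tibble(
      chain = rep(c("D", "C"), c(half, n - half)),
      resno = rep(seq_len(n)),
      icode = "", resname = "GLY",
      atom = ifelse(elements == "S", "SG", elements),
      element = elements, altloc = "", occ = 1,
      x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
      z = stats::runif(n, 0, box),
      het = FALSE,
      role = rep(c("tcr_alpha", "peptide"), c(half, n - half))
    )
  })
}

# attempt to fetch a deposited PDB entry; returns a local path or NA when the
# archive is unreachable
fetch_pdb <- function(id) {
  dest <- file.path(tempdir(), paste0(tolower(id), ".pdb"))
  if (file.exists(dest) && file.size(dest) > 1000) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch({
    withr::with_options(list(timeout = 60), {
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    })
    file.exists(dest) && file.size(dest) > 1000
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (ok) dest else NA_character_
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

rigid_move <- function(atoms, R = diag(3), t = c(0, 0, 0), rows = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(rows)) rows <- seq_len(nrow(atoms))
  moved <- xyz[rows, , drop = FALSE] %*% t(R)
  moved <- sweep(moved, 2, t, "+")
  atoms$x[rows] <- moved[, 1]
  atoms$y[rows] <- moved[, 2]
  atoms$z[rows] <- moved[, 3]
  atoms
}
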