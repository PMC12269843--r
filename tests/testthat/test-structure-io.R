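test_that("a minimal one-residue PDB round-trips with coordinates as written", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "ALA", "N", "N", 1.234, 2.345, 3.456, serial = 1),
    pdb_line(1, "ALA", "CA", "C", 2.468, 3.579, 4.680, serial = 2)
  ))
  atoms <- read_structure(path)
  expect_equal(nrow(atoms), 2)
  expect_equal(unique(atoms$chain), "A")
  expect_equal(unique(atoms$resno), 1L)
  expect_equal(atoms$x, c(1.234, 2.468))
  expect_equal(atoms$z, c(3.456, 4.680))
  expect_false(any(atoms$het))
})

test_that("writing and re-reading preserves the residue/atom inventory", {
  toy <- make_toy_complex()
  path <- tempfile(fileext = ".pdb")
  write_structure(toy$atoms, path)
  back <- read_structure(path)
  key <- function(a) dplyr::arrange(
    dplyr::select(a, chain, resno, resname, atom),
    chain, resno, atom
  )
  expect_equal(key(back), key(toy$atoms))
  orig <- dplyr::arrange(toy$atoms, chain, resno, atom)
  reread <- dplyr::arrange(back, chain, resno, atom)
  expect_equal(reread$x, orig$x, tolerance = 1e-3)
  expect_equal(reread$y, orig$y, tolerance = 1e-3)
})

test_that("citrulline survives parsing inside a polymer chain", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "ASP", "CA", "C", 0, 0, 0, serial = 1),
    pdb_line(2, "CIR", "CA", "C", 3.8, 0, 0, serial = 2,
             rectype = "HETATM"),
    pdb_line(2, "CIR", "O7", "O", 3.8, 0, 3.0, serial = 3,
             rectype = "HETATM"),
    pdb_line(3, "TYR", "CA", "C", 7.6, 0, 0, serial = 4)
  ))
  atoms <- read_structure(path)
  res <- residues(atoms)
  expect_equal(res$resname, c("ASP", "CIR", "TYR"))
  expect_false(any(atoms$het[atoms$resname == "CIR"]))
})

test_that("waters are flagged het while modified residues are not", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "GLY", "CA", "C", 0, 0, 0, serial = 1),
    pdb_line(2, "CIR", "CA", "C", 3.8, 0, 0, serial = 2, rectype = "HETATM"),
    pdb_line(90, "HOH", "O", "O", 20, 0, 0, serial = 3, rectype = "HETATM")
  ))
  atoms <- read_structure(path)
  expect_equal(atoms$het[atoms$resname == "HOH"], TRUE)
  expect_equal(atoms$het[atoms$resname == "CIR"], FALSE)
})

test_that("altloc policy keeps the highest-occupancy conformer, ties to A", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "SER", "OG", "O", 0, 0, 0, alt = "A", occ = 0.6, serial = 1),
    pdb_line(1, "SER", "OG", "O", 1, 0, 0, alt = "B", occ = 0.4, serial = 2),
    pdb_line(1, "SER", "CA", "C", 2, 0, 0, serial = 3),
    pdb_line(2, "VAL", "CB", "C", 9, 0, 0, alt = "B", occ = 0.5, serial = 4),
    pdb_line(2, "VAL", "CB", "C", 8, 0, 0, alt = "A", occ = 0.5, serial = 5),
    pdb_line(3, "THR", "OG1", "O", 5, 0, 0, alt = "A", occ = 0.3, serial = 6),
    pdb_line(3, "THR", "OG1", "O", 6, 0, 0, alt = "B", occ = 0.7, serial = 7)
  ))
  atoms <- read_structure(path)
  og <- atoms[atoms$atom == "OG", ]
  expect_equal(nrow(og), 1)
  expect_equal(og$altloc, "A")
  expect_equal(og$x, 0)
  cb <- atoms[atoms$atom == "CB", ]
  expect_equal(cb$altloc, "A")  # tie broken toward A
  expect_equal(cb$x, 8)
  og1 <- atoms[atoms$atom == "OG1", ]
  expect_equal(og1$altloc, "B")  # B wins on occupancy, not label
  expect_equal(og1$x, 6)
})

test_that("unreadable and empty inputs raise parse errors", {
  expect_error(read_structure(tempfile()), "not found")
  empty <- write_pdb_fixture(pdb_line(1, "HOH", "O", "O", 0, 0, 0,
                                      rectype = "HETATM"))
  expect_error(read_structure(empty), "polymer")
})

test_that("chain roles follow an explicit config map", {
  toy <- make_toy_complex()
  raw <- dplyr::select(toy$atoms, -role, -region, -pocket)
  ann <- assign_chain_roles(raw, roles = c(A = "mhc_alpha", B = "mhc_beta",
                                           C = "peptide", D = "tcr_alpha",
                                           E = "tcr_beta"))
  got <- dplyr::distinct(ann, chain, role)
  expect_equal(got$role[got$chain == "C"], "peptide")
  expect_equal(got$role[got$chain == "E"], "tcr_beta")
})

test_that("auto-detection assigns the single 9-25-mer chain as peptide", {
  toy <- make_toy_complex()
  raw <- dplyr::select(toy$atoms, -role, -region, -pocket)
  ann <- assign_chain_roles(raw, roles = c(A = "mhc_alpha", B = "mhc_beta",
                                           D = "tcr_alpha", E = "tcr_beta"))
  expect_equal(unique(ann$role[ann$chain == "C"]), "peptide")
})

test_that("role validation rejects duplicates and incomplete ternary input", {
  toy <- make_toy_complex()
  raw <- dplyr::select(toy$atoms, -role, -region, -pocket)
  expect_error(
    assign_chain_roles(raw, roles = c(A = "mhc_alpha", B = "mhc_alpha",
                                      C = "peptide", D = "tcr_alpha",
                                      E = "tcr_beta")),
    "same role"
  )
  apo <- dplyr::filter(raw, chain %in% c("D", "E"))
  expect_error(assign_chain_roles(apo, roles = c(D = "tcr_alpha",
                                                 E = "tcr_beta")),
               "unassigned role")
  expect_silent(assign_chain_roles(apo, roles = c(D = "tcr_alpha",
                                                  E = "tcr_beta"),
                                   mode = "apo"))
})

test_that("IMGT region labels follow the standard CDR intervals", {
  toy <- make_toy_complex()
  a <- toy$atoms
  reg <- function(ch, rn) unique(a$region[a$chain == ch & a$resno == rn])
  expect_equal(reg("D", 113), "CDR3")  # CDR3 105-117
  expect_equal(reg("D", 58), "CDR2")   # CDR2 56-65
  expect_equal(reg("D", 30), "CDR1")
  expect_equal(reg("D", 1), "FW")      # framework position 55-equivalents
  expect_true(all(is.na(a$region[!a$role %in% c("tcr_alpha", "tcr_beta")])))
})

test_that("region labels partition the variable domain exhaustively", {
  toy <- make_toy_complex()
  vres <- toy$atoms %>%
    dplyr::filter(role %in% c("tcr_alpha", "tcr_beta"),
                  resno >= 1, resno <= 129)
  expect_false(any(is.na(vres$region)))
  expect_true(all(vres$region %in% c("CDR1", "CDR2", "CDR3", "FW")))
  expect_error(
    assign_imgt_regions(toy$atoms,
                        ranges = list(CDR1 = c(27L, 60L), CDR2 = c(56L, 65L),
                                      CDR3 = c(105L, 117L))),
    "overlap"
  )
})

test_that("the pocket register anchors at P1 and flanks the overhang", {
  toy <- make_toy_complex()
  pep <- residues(dplyr::filter(toy$atoms, role == "peptide"))
  pocket <- toy$atoms %>%
    dplyr::filter(role == "peptide") %>%
    dplyr::distinct(resno, pocket)
  lab <- function(rn) pocket$pocket[pocket$resno == rn]
  # TNC register: P-2 = Asp1013, P-1 = Cit1014, P1 = Tyr1015, P2 = Cit1016,
  # P4 = Asn1018, P5 = Tyr1019, P8 = Pro1022, P9 = Thr1023
  expect_equal(lab(1013), "P-2")
  expect_equal(lab(1014), "P-1")
  expect_equal(lab(1015), "P1")
  expect_equal(lab(1016), "P2")
  expect_equal(lab(1018), "P4")
  expect_equal(lab(1019), "P5")
  expect_equal(lab(1022), "P8")
  expect_equal(lab(1023), "P9")
  expect_equal(lab(1024), "flank")
})

test_that("a register anchored at the first residue has no N-terminal pockets", {
  nine <- new_toy_peptide <- tibble::tibble(
    chain = "C", resno = 1:9, icode = "", resname = "GLY", atom = "CA",
    element = "C", altloc = "", occ = 1, x = 3.8 * (0:8), y = 0, z = 0,
    het = FALSE, role = "peptide"
  )
  ann <- assign_peptide_register(nine, p1_seq_id = 1)
  expect_equal(ann$pocket, paste0("P", 1:9))
  expect_error(assign_peptide_register(nine, p1_seq_id = 99), "Register error")
})

test_that("C-terminal solubility lysines are labelled flank", {
  pep <- tibble::tibble(
    chain = "C", resno = 1:14, icode = "",
    resname = c(rep("GLY", 12), "LYS", "LYS"),
    atom = "CA", element = "C", altloc = "", occ = 1,
    x = 3.8 * (0:13), y = 0, z = 0, het = FALSE, role = "peptide"
  )
  ann <- assign_peptide_register(pep, p1_seq_id = 3)
  expect_equal(ann$pocket[ann$resno %in% 13:14], c("flank", "flank"))
})

test_that("pocket labels increase strictly along fuzzed peptides", {
  pocket_rank <- function(p) {
    core <- match(p, c("P-2", "P-1", paste0("P", 1:9)))
    core
  }
  for (seed in 1:20) {
    len <- withr::with_seed(seed, sample(8:20, 1))
    p1 <- withr::with_seed(seed + 100, sample(seq_len(len), 1))
    pep <- tibble::tibble(
      chain = "C", resno = seq_len(len), icode = "", resname = "GLY",
      atom = "CA", element = "C", altloc = "", occ = 1,
      x = 3.8 * seq_len(len), y = 0, z = 0, het = FALSE, role = "peptide"
    )
    ann <- assign_peptide_register(pep, p1_seq_id = p1)
    expect_equal(sum(ann$pocket == "P1"), 1)
    ranks <- pocket_rank(ann$pocket)
    expect_true(all(diff(ranks[!is.na(ranks)]) > 0))
  }
})

test_that("shared-epitope detection matches the three risk motifs only", {
  base <- strrep("G", 80)
  with_window <- function(w) {
    paste0(substr(base, 1, 69), w, substr(base, 75, 80))
  }
  expect_true(detect_shared_epitope(with_window("QKRAA"))$positive)
  expect_true(detect_shared_epitope(with_window("QRRAA"))$positive)
  expect_true(detect_shared_epitope(with_window("RRRAA"))$positive)
  expect_equal(detect_shared_epitope(with_window("QKRAA"))$motif, "QKRAA")
  expect_false(detect_shared_epitope(with_window("DERAA"))$positive)
  expect_true(detect_shared_epitope(tolower(with_window("QRRAA")))$positive)
  expect_error(detect_shared_epitope("QKRAA"), "Coverage error")
})

test_that("SE detection depends only on the 70-74 window", {
  seqs <- purrr::map_chr(1:10, function(s) {
    withr::with_seed(s, paste(sample(LETTERS[1:20], 80, TRUE), collapse = ""))
  })
  results <- purrr::map_lgl(seqs, function(sq) {
    substr(sq, 70, 74) <- "QRRAA"
    detect_shared_epitope(sq)$positive
  })
  expect_true(all(results))
})
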