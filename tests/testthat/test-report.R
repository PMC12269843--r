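toy_config <- function(out_dir, docking_angle = 70) {
  toy <- make_toy_complex(docking_angle)
  pdb <- file.path(out_dir, "toy.pdb")
  write_structure(toy$atoms, pdb)
  list(
    structure = pdb,
    roles = list(A = "mhc_alpha", B = "mhc_beta", C = "peptide",
                 D = "tcr_alpha", E = "tcr_beta"),
    p1_seq_id = 1015,
    out_dir = file.path(out_dir, "report")
  )
}

test_that("run_interface writes the full bundle with planted values", {
  dir <- withr::local_tempdir()
  cfg <- toy_config(dir)
  res <- run_interface(cfg)
  expect_true(all(file.exists(file.path(cfg$out_dir, c(
    "bsa.json", "contacts.tsv", "footprint.tsv", "geometry.json",
    "se.json", "summary.txt"
  )))))
  geom <- jsonlite::read_json(file.path(cfg$out_dir, "geometry.json"))
  expect_equal(geom$docking_angle, 70, tolerance = 1e-6)
  contacts <- read.delim(file.path(cfg$out_dir, "contacts.tsv"))
  expect_true(any(contacts$resno_a == 113 & contacts$kind == "hbond"))
  se <- jsonlite::read_json(file.path(cfg$out_dir, "se.json"))
  expect_false(se$positive)  # toy MHC beta is polyglycine
  summary_txt <- readLines(file.path(cfg$out_dir, "summary.txt"))
  expect_true(any(grepl("Docking angle: 70.0 degrees", summary_txt)))
  expect_true(any(grepl("two-sided sum", summary_txt)))
})

test_that("identical config and inputs give byte-identical outputs", {
  dir <- withr::local_tempdir()
  cfg <- toy_config(dir)
  run_interface(cfg)
  first <- purrr::map(list.files(cfg$out_dir, full.names = TRUE), readLines)
  run_interface(cfg)
  second <- purrr::map(list.files(cfg$out_dir, full.names = TRUE), readLines)
  expect_identical(first, second)
})

test_that("config validation happens before any computation", {
  dir <- withr::local_tempdir()
  cfg <- toy_config(dir)
  cfg$not_a_key <- 1
  expect_error(run_interface(cfg), "Unknown config key")
  cfg2 <- toy_config(dir)
  cfg2$roles <- NULL
  expect_error(run_interface(cfg2), "`roles` map missing")
  cfg3 <- toy_config(dir)
  cfg3$p1_seq_id <- NULL
  expect_error(run_interface(cfg3), "p1_seq_id")
})

test_that("a YAML config file is accepted", {
  dir <- withr::local_tempdir()
  cfg <- toy_config(dir)
  yml <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, yml)
  res <- run_interface(yml)
  # PDB serialization truncates coordinates to 3 decimals
  expect_equal(res$geometry$docking_angle, 70, tolerance = 1e-3)
})

test_that("apo mode superposes the TCR onto a holo reference", {
  dir <- withr::local_tempdir()
  toy <- make_toy_complex()
  holo_pdb <- file.path(dir, "holo.pdb")
  write_structure(toy$atoms, holo_pdb)
  # apo form: the TCR chains alone, rigidly moved -- r.m.s.d. must be 0
  apo_atoms <- toy$atoms %>%
    dplyr::filter(role %in% c("tcr_alpha", "tcr_beta")) %>%
    rigid_move(rotation_z(25), t = c(4, 4, 4))
  apo_pdb <- file.path(dir, "apo.pdb")
  write_structure(apo_atoms, apo_pdb)
  res <- run_interface(list(
    structure = apo_pdb, mode = "apo",
    roles = list(A = "mhc_alpha", B = "mhc_beta", C = "peptide",
                 D = "tcr_alpha", E = "tcr_beta"),
    holo_reference = holo_pdb,
    out_dir = file.path(dir, "apo_report")
  ))
  expect_equal(res$superposition$rmsd, 0, tolerance = 1e-3)
  expect_true(file.exists(file.path(dir, "apo_report",
                                    "superposition.json")))
})

test_that("run_binding fits SPR panels and classifies against wild type", {
  dir <- withr::local_tempdir()
  panel <- dplyr::bind_rows(
    dplyr::mutate(simulate_spr(kd = 25.8, seed = 1), sample = "WT"),
    dplyr::mutate(simulate_spr(kd = 50, seed = 2), sample = "mutA"),
    dplyr::mutate(simulate_spr(kd = 400, top_conc = 800, seed = 3),
                  sample = "mutB")
  )
  csv <- file.path(dir, "spr.csv")
  write.csv(panel, csv, row.names = FALSE)
  res <- run_binding(list(spr_csv = csv, wildtype = "WT", out_dir = dir))
  kd <- res$kd_table
  expect_equal(nrow(kd), 3)
  expect_true(all(!is.na(kd$label)))
  expect_equal(as.character(kd$label[kd$sample == "WT"]), "no_effect")
  expect_equal(as.character(kd$label[kd$sample == "mutB"]), "deleterious")
  expect_true(file.exists(file.path(dir, "kd_table.tsv")))
})

test_that("run_binding reports unresolved IC50s as above the tested range", {
  dir <- withr::local_tempdir()
  fp <- dplyr::bind_rows(
    dplyr::mutate(simulate_fp(ic50 = 1.1, seed = 1), sample = "DRB1_0401"),
    dplyr::mutate(simulate_fp(ic50 = 5000, top_conc = 300, seed = 2),
                  sample = "DRB1_0404")
  )
  csv <- file.path(dir, "fp.csv")
  write.csv(fp, csv, row.names = FALSE)
  res <- run_binding(list(fp_csv = csv, out_dir = dir))
  tab <- res$ic50_table
  expect_equal(tab$ic50_label[tab$sample == "DRB1_0404"], "> 300")
  expect_false(tab$ic50_gt_max[tab$sample == "DRB1_0401"])
})

test_that("malformed CSV input names the offending rows", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "bad.csv")
  writeLines(c("concentration_uM,response", "1,5", "2,", "4,12"), csv)
  expect_error(run_binding(list(spr_csv = csv, out_dir = dir)),
               "malformed row")
  csv2 <- file.path(dir, "cols.csv")
  writeLines(c("conc,resp", "1,5"), csv2)
  expect_error(run_binding(list(spr_csv = csv2, out_dir = dir)),
               "missing column")
})

test_that("plot methods return ggplot objects", {
  fit <- fit_steady_state(simulate_spr(kd = 20, seed = 5))
  expect_s3_class(autoplot(fit), "ggplot")
  fp_fit <- fit_competition(simulate_fp(ic50 = 1.1, seed = 5))
  expect_s3_class(autoplot(fp_fit), "ggplot")
  toy <- make_toy_complex()
  bsa <- compute_bsa(toy$atoms)
  expect_s3_class(autoplot(bsa), "ggplot")
  foot <- summarize_footprint(detect_contacts(toy$atoms), toy$atoms, bsa)
  expect_s3_class(plot_footprint(foot), "ggplot")
})
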