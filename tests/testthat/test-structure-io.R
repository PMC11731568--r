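test_that("a minimal inline PDB parses into one residue of three atoms", {
  txt <- paste(
    tsrkeys:::pdb_atom_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    tsrkeys:::pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 1, 1.5, 0, 0, 1, "C"),
    tsrkeys:::pdb_atom_line("ATOM", 3, "C", "ALA", "A", 1, 2, 1.2, 0, 1, "C"),
    "END", sep = "\n")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(unique(m$atoms$res_seq), 1)
  expect_equal(m$atoms$atom_name, c("N", "CA", "C"))
  expect_equal(m$atoms$element, c("N", "C", "C"))
})

test_that("toy protein fixture yields one CA per residue", {
  m <- read_structure(make_toy_protein(5))
  expect_equal(length(unique(m$atoms$res_seq)), 5)
  sel <- select_calpha(m, "A")
  expect_equal(n_atoms(sel), 5)
  expect_true(all(sel$atoms$atom_name == "CA"))
  expect_equal(sel$mode, "CA")
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  base <- tsrkeys:::pdb_atom_line("ATOM", 1, "N", "ALA", "A", 1,
                                  0, 0, 0, 1, "N")
  mk <- function(alt, occ, x, serial = 2) {
    ln <- tsrkeys:::pdb_atom_line("ATOM", serial, "CA", "ALA", "A", 1,
                                  x, 0, 0, occ, "C")
    substr(ln, 17, 17) <- alt
    ln
  }
  txt <- paste(base, mk("A", 0.6, 1.0), mk("B", 0.4, 9.0, serial = 3),
               "END", sep = "\n")
  m <- read_structure(txt)
  ca <- m$atoms[m$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)
  # occupancy tie -> alphabetically first altloc
  txt2 <- paste(base, mk("B", 0.5, 9.0), mk("A", 0.5, 1.0, serial = 3),
                "END", sep = "\n")
  ca2 <- read_structure(txt2)$atoms
  ca2 <- ca2[ca2$atom_name == "CA", ]
  expect_equal(ca2$x, 1.0)
  # higher-occupancy B conformer wins over A
  txt3 <- paste(base, mk("A", 0.3, 1.0), mk("B", 0.7, 9.0, serial = 3),
                "END", sep = "\n")
  ca3 <- read_structure(txt3)$atoms
  ca3 <- ca3[ca3$atom_name == "CA", ]
  expect_equal(nrow(ca3), 1)
  expect_equal(ca3$x, 9.0)
})

test_that("malformed coordinate lines and empty models are rejected", {
  good <- tsrkeys:::pdb_atom_line("ATOM", 1, "CA", "GLY", "A", 1,
                                  0, 0, 0, 1, "C")
  bad <- paste0(substr(good, 1, 30), "  badnum", substr(good, 39, 80))
  expect_error(read_structure(paste(good, bad, "END", sep = "\n")),
               "line 2")
  expect_error(read_structure("REMARK nothing here\nEND"), "empty model")
})

test_that("residue selection returns the heavy-atom inventory", {
  trp <- select_residue(read_structure(toy_trp_pdb()), "A", 42)
  expect_equal(n_atoms(trp), 14)
  expect_setequal(trp$atoms$atom_name,
                  c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                    "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  gly <- select_residue(read_structure(toy_gly_pdb()), "A", 7)
  expect_equal(n_atoms(gly), 4)
  expect_error(select_residue(read_structure(toy_gly_pdb()), "A", 99),
               "not found")
  # hetero residue is redirected to the cofactor selector
  m <- read_structure(make_toy_cofactor())
  expect_error(select_residue(m, "A", 1011), "select_cofactor")
})

test_that("cofactor selection follows the annotation and drops nothing", {
  m <- read_structure(make_toy_cofactor(with_tail = TRUE))
  ann <- list(pdb_id = "TOY", role = "P700_A", chain = "A",
              res_seq = 1011, res_name = "CLA")
  sel <- select_cofactor(m, ann)
  expect_equal(n_atoms(sel), 40)
  expect_equal(sel$mode, "COFACTOR")
  expect_equal(sel$provenance$role, "P700_A")
  bad <- ann; bad$res_seq <- 999
  expect_error(select_cofactor(m, bad), "P700_A")
  wrong <- ann; wrong$res_name <- "PQN"
  expect_error(select_cofactor(m, wrong), "expected PQN")
})

test_that("atom filtering removes named atoms, is idempotent, errors on empty", {
  sel <- toy_cofactor_selection(with_tail = TRUE)
  ring <- filter_atoms(sel, atom_filter_preset("phytol_tail"))
  expect_equal(n_atoms(ring), 25)
  expect_identical(filter_atoms(ring, atom_filter_preset("phytol_tail")),
                   ring)
  expect_identical(filter_atoms(sel, character(0)), sel)
  expect_error(filter_atoms(sel, unique(sel$atoms$atom_name)),
               "every atom")
})

test_that("selections round-trip through PDB writing", {
  sel <- toy_cofactor_selection()
  path <- tempfile(fileext = ".pdb")
  write_selection_pdb(sel, path)
  m2 <- read_structure(path)
  expect_equal(m2$atoms$atom_name, sel$atoms$atom_name)
  expect_equal(m2$atoms$res_seq, sel$atoms$res_seq)
  expect_equal(m2$atoms$x, sel$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$element, sel$atoms$element)
})

test_that("packaged annotation table replicates the nine-entry table", {
  ann <- cofactor_annotations()
  expect_equal(nrow(ann), 72)  # 9 entries x 8 chlorophyll roles
  expect_setequal(unique(ann$pdb_id),
                  c("1JB0", "5OY0", "6HQB", "6JO6", "6KMW", "6KMX",
                    "6PNJ", "7COY", "5ZJI"))
  r <- cofactor_annotations("1JB0", "P700_A")
  expect_equal(r$chain, "A")
  expect_equal(r$res_seq, 1011)
  expect_equal(r$res_name, "CLA")
  expect_equal(r$axial_res, 680)
  r2 <- cofactor_annotations("5OY0", "A_0A")
  expect_equal(r2$res_seq, 1013)
  expect_equal(r2$res_name, "CLA")
  expect_equal(r2$chain, "A")
})

test_that("a chain with a residue missing its CA warns and skips it", {
  lines <- unlist(lapply(1:4, function(i) {
    c(tsrkeys:::pdb_atom_line("ATOM", 2 * i - 1, "N", "GLY", "A", i,
                              i, 0, 0, 1, "N"),
      if (i != 3) tsrkeys:::pdb_atom_line("ATOM", 2 * i, "CA", "GLY",
                                          "A", i, i, 1, 0, 1, "C"))
  }))
  m <- read_structure(paste(c(lines, "END"), collapse = "\n"))
  expect_warning(sel <- select_calpha(m, "A"), "without a CA")
  expect_equal(n_atoms(sel), 3)
  expect_error(select_calpha(m, "Z"), "chain Z")
})
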