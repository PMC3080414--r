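test_that("empty coordinate files give empty models", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", tf)
  m <- read_structure(tf)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 0)
})

test_that("write/read round trip preserves the model to printed precision", {
  m <- build_dipeptide(omega = 63.5, residue_names = c("LEU", "CYS"))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tf)
  m2 <- read_structure(tf)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(length(unique(m2$atoms$chain)), 1)
  expect_equal(nrow(dplyr::distinct(m2$atoms, res_seq)), 2)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$y, m$atoms$y, tolerance = 1e-3)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 1e-3)
  expect_equal(m2$atoms$atom, m$atoms$atom)
  expect_equal(m2$atoms$res_name, m$atoms$res_name)
})

test_that("malformed coordinate lines are reported by line number", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      xx.xxx   6.071  -5.147  1.00 11.00           C"
  ), tf)
  expect_error(read_structure(tf), "line 2", class = "cnbdkit_parse_error")
  expect_error(read_structure("/no/such/file.pdb"), class = "cnbdkit_io_error")
})

test_that("CRYST1 metadata is parsed and bad space groups are dropped", {
  m <- build_dipeptide(omega = 0)
  m$crystal <- crystal_info(107, 107, 171, 90, 90, 120, "P 62 2 2")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tf)
  m2 <- read_structure(tf)
  expect_equal(m2$crystal$a, 107)
  expect_equal(m2$crystal$gamma, 120)
  expect_equal(m2$crystal$asu_multiplicity, 12L)
  txt <- readLines(tf)
  txt[1] <- sub("P 62 2 2", "Q 9 9 9 ", txt[1])
  writeLines(txt, tf)
  expect_warning(m3 <- read_structure(tf), "space group")
  expect_null(m3$crystal)
})

test_that("mmCIF atom_site and cell items are read", {
  lines <- c(
    "data_fixture",
    "_cell.length_a    20.000",
    "_cell.length_b    21.000",
    "_cell.length_c    22.000",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 10.00 ? 5 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 11.00 ? 5 ALA A CA 1"
  )
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, tf)
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[1], 11.104)
  expect_equal(m$atoms$atom, c("N", "CA"))
  expect_equal(m$crystal$b, 21)
  expect_equal(m$crystal$asu_multiplicity, 1L)
})

test_that("atom selection filters compose and normalize names", {
  m <- build_polypeptide(136, res_start = 92L)
  expect_equal(nrow(select_atoms(m, atom = "CA", hetero = FALSE)), 136)
  expect_equal(nrow(select_atoms(m)), nrow(m$atoms))
  # contradictory criteria: empty result, not an error
  expect_equal(nrow(select_atoms(m, res_name = "GLY", atom = "SG")), 0)
  sel <- select_atoms(m, res_seq = 193, atom = "ca")
  expect_equal(nrow(sel), 1)
  nt <- build_purine_nucleotide(chi = 30, base = "guanine")
  expect_equal(nrow(select_atoms(nt, atom = "O2*")), 1)
  expect_true(all(select_atoms(m, atom = "CA")$serial %in% m$atoms$serial))
})

test_that("alternate locations collapse to the dominant conformer", {
  rows <- list(
    atom_row("CA", c(0, 0, 0), alt = "A", occ = 0.6),
    atom_row("CA", c(1, 0, 0), alt = "B", occ = 0.4),
    atom_row("CB", c(0, 1, 0), alt = "A", occ = 0.5),
    atom_row("CB", c(0, 2, 0), alt = "B", occ = 0.5)
  )
  m <- collapse_alt_locs(make_model(rows))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 0) # highest occupancy
  expect_equal(m$atoms$y[m$atoms$atom == "CB"], 1) # tie -> alphabetical
})

test_that("Matthews coefficient and solvent content follow the cell formula", {
  cubic <- crystal_info(100, 100, 100, 90, 90, 90, "P 1")
  res <- matthews_solvent(cubic, 1, 406504)
  expect_equal(res$cell_volume, 1e6)
  expect_equal(res$solvent_fraction, 0.5, tolerance = 1e-3)

  hexa <- crystal_info(107, 107, 171, 90, 90, 120, "P 62 2 2")
  # hand-evaluated hexagonal volume sqrt(3)/2 * a^2 * c
  expect_equal(cell_volume(hexa), sqrt(3) / 2 * 107^2 * 171, tolerance = 1e-9)
  sol <- matthews_solvent(hexa, 2, protein_mw(n_residues = 136))
  expect_gt(sol$solvent_fraction, 0.70)
  expect_lt(sol$solvent_fraction, 0.78)

  # relabeling a and b leaves the volume unchanged when a = b
  swapped <- crystal_info(107, 107, 171, 90, 90, 120, "P 62 2 2")
  expect_equal(cell_volume(swapped), cell_volume(hexa))

  # strict monotonicity in load
  mw <- protein_mw(n_residues = 136)
  expect_lt(
    matthews_solvent(hexa, 2, 2 * mw)$solvent_fraction,
    sol$solvent_fraction
  )
  expect_lt(
    matthews_solvent(hexa, 4, mw)$solvent_fraction,
    sol$solvent_fraction
  )
  expect_error(matthews_solvent(hexa, 0, mw), class = "cnbdkit_domain_error")
})

test_that("space-group multiplicities resolve and unknown groups error", {
  expect_equal(space_group_multiplicity("P 62 2 2"), 12L)
  expect_equal(space_group_multiplicity("P 43"), 4L)
  expect_equal(space_group_multiplicity("p212121"), 4L)
  expect_error(space_group_multiplicity("X 99"), class = "cnbdkit_domain_error")
})

test_that("protein molecular weight adds residue masses plus water", {
  expect_equal(protein_mw("G"), 57.0519 + 18.0153, tolerance = 1e-6)
  expect_equal(protein_mw("GG"), 2 * 57.0519 + 18.0153, tolerance = 1e-6)
  expect_gt(protein_mw(n_residues = 136), 15000)
  expect_error(protein_mw("GXZ"), class = "cnbdkit_domain_error")
})
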