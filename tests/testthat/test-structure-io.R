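test_that("PDB and mmCIF round-trips preserve identity and coordinates", {
  h <- make_helical_filament(60, 23.05, 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(h, pdb)
  write_structure(h, cif)
  r_pdb <- read_structure(pdb)
  r_cif <- read_structure(cif)
  expect_identical(nrow(r_pdb$atoms), nrow(h$atoms))
  expect_identical(r_pdb$atoms$atom, h$atoms$atom)
  expect_identical(r_pdb$atoms$chain, h$atoms$chain)
  expect_lt(max(abs(coords(h) - coords(r_pdb))), 1e-3)
  expect_lt(max(abs(coords(h) - coords(r_cif))), 1e-5)
})

test_that("reading a small hand-written PDB yields the expected hierarchy", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mini_pdb_lines(), pdb)
  m <- read_structure(pdb)
  expect_identical(chain_ids(m), "A")
  expect_identical(n_residues(m), 2L)
  expect_identical(m$atoms$element, c("N", "C", "N", "C"))
  expect_equal(m$cell$a, 60)
})

test_that("degenerate inputs error informatively", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("", empty)
  expect_error(read_structure(empty), "empty|parse")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  one_atom <- make_helical_filament(60, 20, 1)
  bad <- one_atom
  bad$atoms <- bad$atoms[0, , drop = FALSE]
  expect_error(write_structure(structure(bad, class = "ftsz_structure"),
                               tempfile(fileext = ".pdb")), "no atoms")
  expect_error(expand_filament(one_atom, make_crystal_fixture(100)$cell,
                               n_copies = 0), "positive integer")
})

test_that("PDB writing remaps >1-character chain ids and caps at 62 chains", {
  fx <- make_crystal_fixture(138.3)
  fil <- expand_filament(fx$subunit, fx$cell, n_copies = 24)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  w <- write_structure(fil, pdb)
  map <- attr(w, "chain_map")
  expect_identical(unname(map), ftszlat:::PDB_CHAIN_ALPHABET[1:24])
  r <- read_structure(pdb)
  expect_identical(length(chain_ids(r)), 24L)
  big <- make_helical_filament(5, 5, 62)
  big$atoms$chain <- paste0(big$atoms$chain, "x")  # force 63 via duplication
  big63 <- merge_structures(big, {
    one <- make_helical_filament(5, 5, 1); one$atoms$chain <- "zz"; one
  })
  expect_error(write_structure(big63, tempfile(fileext = ".pdb")), "mmCIF")
})

test_that("occupancy, water and hydrogen filtering follow the defaults", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       1.500   2.100   3.100  1.00  0.00           H",
    "ATOM      3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "ATOM      4  CA  ALA A   1       2.000   2.500   3.500  0.00  0.00           C",
    "END"), pdb)
  m <- read_structure(pdb)
  expect_identical(nrow(m$atoms), 1L)      # H, water, zero-occupancy dropped
  m2 <- read_structure(pdb, keep_hydrogens = TRUE, keep_waters = TRUE)
  expect_identical(nrow(m2$atoms), 3L)
})

test_that("alternate conformers keep the highest-occupancy copy", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), pdb)
  m <- read_structure(pdb)
  expect_identical(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 2)
})

test_that("the P6522 operator set closes under composition", {
  expect_true(isTRUE(ftszlat:::sym_ops_closed(p6522_operators())))
  # dropping one operator breaks closure
  expect_type(ftszlat:::sym_ops_closed(p6522_operators()[-2]), "character")
})

test_that("apply_symmetry reproduces closed-form screw geometry", {
  fx <- make_crystal_fixture(c_edge = 138.3)
  m <- fx$subunit
  # identity, zero shift: unchanged
  m_id <- apply_symmetry(m, ftszlat:::identity_op(), fx$cell)
  expect_equal(coords(m_id), coords(m), tolerance = 1e-12)
  # pure half-cell translation along c
  op_t <- sym_op(diag(3), c(0, 0, 1 / 2))
  cell100 <- crystal_frame(60, 60, 100, spacegroup = "P 1")
  m_t <- apply_symmetry(m, op_t, cell100)
  expect_equal(coords(m_t)[, 3] - coords(m)[, 3], rep(50, nrow(m$atoms)))
  # 6_5 screw applied six times = full turn plus one c repeat
  gen <- fx$cell$operators[[2]]
  shift <- ftszlat:::reduce_generator_shift(gen, fx$cell)
  m6 <- m
  for (k in 1:6) m6 <- apply_symmetry(m6, gen, fx$cell, lattice_shift = shift)
  expect_equal(unname(coords(m6) - coords(m)),
               matrix(c(0, 0, -138.3), nrow(m$atoms), 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("symmetry application is rigid: intra-subunit distances preserved", {
  fx <- make_crystal_fixture(123.4)
  d0 <- dist(coords(fx$subunit))
  for (op in fx$cell$operators[c(2, 7, 12)]) {
    m <- apply_symmetry(fx$subunit, op, fx$cell, lattice_shift = c(1, 0, -1))
    expect_lt(max(abs(dist(coords(m)) - d0)), 1e-6)
  }
})

test_that("expand_filament produces compact helical filaments", {
  fx <- make_crystal_fixture(c_edge = 138.3)
  expect_identical(expand_filament(fx$subunit, fx$cell, n_copies = 1),
                   fx$subunit)
  fil <- expand_filament(fx$subunit, fx$cell, n_copies = 24)
  expect_identical(length(chain_ids(fil)), 24L)
  # 24 subunits at c/6 rise span 23 steps ~ 4 cell repeats along c
  z_span <- diff(range(coords(fil)[, 3]))
  expect_equal(z_span, 23 * 138.3 / 6 + diff(range(coords(fx$subunit)[, 3])),
               tolerance = 1e-6)
  # a pure rotation generator (axis through the subunit centroid) has zero rise
  cubic <- crystal_frame(60, 60, 60, spacegroup = "P 1")
  op_rot <- sym_op(ftszlat:::rot_z(60), c(0, 0, 0))
  centered <- subset_chains(make_helical_filament(60, 20, 1), "A")
  centered$atoms$x <- centered$atoms$x - mean(centered$atoms$x)
  centered$atoms$y <- centered$atoms$y - mean(centered$atoms$y)
  expect_error(expand_filament(centered, cubic, op_rot), "zero rise")
})
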