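test_that("extract_lateral_dimer returns the planted crystal contact", {
  m <- planted_lattice()
  dim1 <- extract_lateral_dimer(m, interface_id = 1)
  expect_identical(dim1$interface_id, 1L)
  expect_equal(dim1$min_face_distance, 2.8, tolerance = 1e-6)
  sb <- salt_bridges(dim1$structure, dim1$chain_a, dim1$chain_b)
  expect_identical(nrow(sb), 2L)   # the two-fold doubles the Arg-Asp bridge
  expect_setequal(sb$basic_resno, 229L)
  expect_setequal(sb$acidic_resno, 301L)
  # the generating transform really maps subunit a onto subunit b
  moved <- apply_transform(dim1$generating_transform,
                           coords(dim1$structure, dim1$chain_a))
  expect_lt(max(abs(moved - coords(dim1$structure, dim1$chain_b))), 1e-9)
})

test_that("extract_lateral_dimer errors without a cell or a contact", {
  m <- planted_lattice()
  no_cell <- m
  no_cell$cell <- NULL
  expect_error(extract_lateral_dimer(no_cell), "crystal frame")
  # push the subunit away from the two-fold: no mate in contact range
  shifted <- m
  shifted$atoms$x <- shifted$atoms$x - 20
  expect_error(extract_lateral_dimer(shifted, interface_id = 1),
               "no symmetry mate")
})

test_that("grafting onto the dimer's own subunit reproduces the crystal", {
  dim1 <- extract_lateral_dimer(planted_lattice(), interface_id = 1)
  template <- subset_chains(dim1$structure, dim1$chain_a)
  grafted <- graft_by_superposition(dim1, template, dim1$chain_a)
  placed <- coords(grafted, "Ag")
  expect_lt(max(abs(placed - coords(dim1$structure, dim1$chain_b))), 1e-6)
})

test_that("grafting follows transform composition on synthetic templates", {
  dim1 <- extract_lateral_dimer(planted_lattice(), interface_id = 1)
  # template: subunit a moved by a known rigid transform
  tr <- rigid_transform(ftszlat:::rot_z(25), c(4, -7, 12))
  template <- transform_structure(subset_chains(dim1$structure, dim1$chain_a),
                                  tr)
  template$atoms$chain <- "T"
  grafted <- graft_by_superposition(dim1, template, "T")
  expected <- apply_transform(tr, coords(dim1$structure, dim1$chain_b))
  expect_lt(max(abs(coords(grafted, "Ag") - expected)), 1e-6)
})

test_that("grafting onto an unrelated structure fails pairing", {
  dim1 <- extract_lateral_dimer(planted_lattice(), interface_id = 1)
  unrelated <- make_contact_dimer(data.frame(res_a = "LEU", res_b = "LEU",
                                             distance = 4.0))
  expect_error(graft_by_superposition(dim1, unrelated, "A"),
               "pairing failed")
})

test_that("assemble_sheet builds the antiparallel 4 x 6 sheet", {
  subunit <- subset_chains(make_helical_filament(60, 23.05, 1), "A")
  lon <- rigid_transform(ftszlat:::rot_z(60), c(0, 0, 23.05))
  lat <- rigid_transform(diag(c(1, -1, -1)), c(16, 0, 0))
  sheet <- assemble_sheet(subunit, lon, lat, 4L, 6L)
  expect_identical(length(chain_ids(sheet)), 24L)
  s <- sheet$metadata$sheet
  expect_identical(s$orientations, c(1L, -1L, 1L, -1L))
  # consecutive protofilament axes point in opposite directions
  ax <- lapply(s$protofilaments, function(ch)
    filament_pitch(sheet, subunit_order = ch)$axis)
  for (i in 1:3) expect_lt(sum(ax[[i]] * ax[[i + 1]]), 0)
  expect_identical(nrow(clash_check(sheet)), 0L)
})

test_that("sheet placement equals the transform-algebra oracle", {
  subunit <- subset_chains(make_helical_filament(60, 23.05, 1), "A")
  lon <- rigid_transform(ftszlat:::rot_z(60), c(0, 0, 23.05))
  lat <- rigid_transform(diag(c(1, -1, -1)), c(16, 0, 0))
  sheet <- assemble_sheet(subunit, lon, lat, 3L, 4L)
  # subunit (1, j): j powers of the longitudinal screw
  for (j in 0:3) {
    expected <- oracle_rotz_apply(coords(subunit), 60 * j, c(0, 0, 23.05 * j))
    expect_lt(max(abs(coords(sheet, sprintf("P1S%d", j + 1)) - expected)),
              1e-9)
  }
  # subunit (2, 0): one lateral flip
  flipped <- coords(subunit) %*% diag(c(1, -1, -1)) +
    matrix(c(16, 0, 0), nrow(coords(subunit)), 3, byrow = TRUE)
  expect_lt(max(abs(coords(sheet, "P2S1") - flipped)), 1e-9)
})

test_that("sheet provenance replays to bit-identical coordinates", {
  subunit <- subset_chains(make_helical_filament(60, 23.05, 1), "A")
  lon <- rigid_transform(ftszlat:::rot_z(60), c(0, 0, 23.05))
  lat <- rigid_transform(diag(c(1, -1, -1)), c(16, 0, 0))
  sheet <- assemble_sheet(subunit, lon, lat, 2L, 3L)
  prov <- sheet$metadata$sheet$provenance
  for (id in names(prov)) {
    replayed <- apply_transform(prov[[id]], coords(subunit))
    expect_identical(unname(replayed), unname(coords(sheet, id)))
  }
})

test_that("degenerate sheets and clashing assemblies are handled", {
  subunit <- subset_chains(make_helical_filament(60, 23.05, 1), "A")
  lon <- rigid_transform(ftszlat:::rot_z(60), c(0, 0, 23.05))
  expect_identical(assemble_sheet(subunit, lon, lon, 1L, 1L), subunit)
  # a lateral transform that superimposes protofilaments clashes everywhere
  lat_zero <- rigid_transform(diag(c(1, -1, -1)), c(0, 0, 0))
  expect_error(suppressWarnings(
    assemble_sheet(subunit, lon, lat_zero, 2L, 2L)), "clash")
})

test_that("clash_check lists exactly the close inter-chain pairs", {
  d <- make_contact_dimer(data.frame(res_a = "ALA", res_b = "ALA",
                                     distance = 2.0))
  hits <- clash_check(d, cutoff = 2.2)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$distance, 2.0, tolerance = 1e-9)
  expect_identical(nrow(clash_check(d, cutoff = 1.9)), 0L)
  # two coincident chains: every atom meets its duplicate at distance zero
  one <- subset_chains(make_helical_filament(60, 23.05, 1), "A")
  dup <- one
  dup$atoms$chain <- "B"
  co <- merge_structures(one, dup)
  hits_co <- clash_check(co, cutoff = 0.5)
  expect_identical(nrow(hits_co), nrow(one$atoms))
  expect_true(all(hits_co$distance == 0))
  # well-separated chains are clean
  far <- make_contact_dimer(data.frame(res_a = "ALA", res_b = "ALA",
                                       distance = 30), spacing = 12)
  expect_identical(nrow(clash_check(far)), 0L)
})
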