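single_atom <- function(element = "C", x = 0) {
  ftsz_structure(data.frame(chain = "A", resno = 1, resname = "ALA",
                            atom = "CB", element = element,
                            x = x, y = 0, z = 0, occ = 1))
}

test_that("SASA matches the closed form for isolated spheres", {
  # r = 1.7 carbon, probe 1.4: area = 4 pi (3.1)^2
  s <- sasa(single_atom())
  expect_equal(attr(s, "total"), 4 * pi * 3.1^2, tolerance = 1e-6)
  # two atoms beyond solvent-extended contact stay isolated spheres
  far <- ftsz_structure(data.frame(chain = c("A", "B"), resno = 1,
                                   resname = "ALA", atom = "CB",
                                   element = "C", x = c(0, 6.5), y = 0, z = 0,
                                   occ = 1))
  s2 <- sasa(far)
  expect_equal(as.numeric(s2), rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
})

test_that("SASA of a linear triatomic agrees with band quadrature", {
  xyz <- rbind(c(-2.6, 0, 0), c(0, 0, 0), c(2.6, 0, 0))
  radii_vec <- c(1.52, 1.70, 1.55)        # O, C, N
  m <- ftsz_structure(data.frame(chain = "A", resno = 1:3,
                                 resname = c("ASP", "ALA", "LYS"),
                                 atom = c("OD1", "CB", "NZ"),
                                 element = c("O", "C", "N"),
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 occ = 1))
  mine <- sasa(m, n_sphere_points = 9600L)
  ref <- oracle_sasa(xyz, radii_vec)
  expect_lt(max(abs(mine - ref) / ref), 0.01)
})

test_that("SASA converges: 960 vs 9600 test points within 1%", {
  for (fixture in list(make_contact_dimer(data.frame(res_a = "ARG",
                                                     res_b = "ASP",
                                                     distance = 2.8)),
                       make_helical_filament(60, 9, 3),
                       make_interface1_fixture())) {
    lo <- attr(sasa(fixture, n_sphere_points = 960L), "total")
    hi <- attr(sasa(fixture, n_sphere_points = 9600L), "total")
    expect_lt(abs(lo - hi) / hi, 0.01)
  }
})

test_that("adding an atom never increases any other atom's SASA", {
  base <- make_contact_dimer(data.frame(res_a = "ARG", res_b = "GLU",
                                        distance = 3.2))
  s0 <- sasa(base)
  added <- base
  extra <- data.frame(chain = "A", resno = 99L, resname = "ALA", atom = "CB",
                      element = "C", x = 0, y = 3, z = 1, occ = 1,
                      serial = nrow(base$atoms) + 1L)
  added$atoms <- rbind(added$atoms, extra)
  s1 <- sasa(added)
  expect_true(all(s1[seq_along(s0)] <= s0 + 1e-9))
})

test_that("unknown elements error unless a fallback radius is given", {
  m <- single_atom(element = "XX")
  expect_error(sasa(m), "XX")
  expect_silent(sasa(m, radius_set(fallback = 1.7)))
})

test_that("buried area matches the analytic two-sphere overlap", {
  two <- ftsz_structure(data.frame(chain = c("A", "B"), resno = 1,
                                   resname = "ALA", atom = "CB",
                                   element = "C", x = c(-1.7, 1.7), y = 0,
                                   z = 0, occ = 1))
  ba <- buried_area(two, "A", "B", n_sphere_points = 9600L)
  analytic <- 2 * oracle_cap_area(3.1, 3.1, 3.4)
  expect_equal(attr(ba, "total"), analytic, tolerance = 0.02 * analytic)
  expect_equal(as.numeric(ba), attr(ba, "total") / 2, tolerance = 1e-12)
})

test_that("buried area is symmetric and zero for distant chains", {
  d <- make_contact_dimer(data.frame(res_a = "LYS", res_b = "GLU",
                                     distance = 2.8))
  ab <- buried_area(d, "A", "B")
  ba <- buried_area(d, "B", "A")
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-9)
  far <- d
  far$atoms$x <- far$atoms$x + ifelse(far$atoms$chain == "B", 50, 0)
  expect_equal(as.numeric(buried_area(far, "A", "B")), 0, tolerance = 1e-9)
  expect_error(buried_area(d, "A", "A"), "disjoint")
})

test_that("interface residues report planted contacts and nest with cutoff", {
  d <- make_contact_dimer(data.frame(res_a = c("ARG", "LYS"),
                                     res_b = c("ASP", "GLU"),
                                     distance = c(4.0, 6.0)))
  r45 <- interface_residues(d, "A", "B", cutoff = 4.5)
  expect_identical(r45$a$resname, "ARG")
  expect_identical(r45$b$resname, "ASP")
  far <- interface_residues(d, "A", "B", cutoff = 0.5)
  expect_identical(nrow(far$a), 0L)
  # nesting: smaller cutoff set contained in larger
  r30 <- interface_residues(d, "A", "B", cutoff = 3.0)
  r70 <- interface_residues(d, "A", "B", cutoff = 7.0)
  key <- function(x) paste(x$chain, x$resno)
  expect_true(all(key(r30$a) %in% key(r45$a)))
  expect_true(all(key(r45$a) %in% key(r70$a)))
  expect_identical(nrow(r70$a), 2L)
})

test_that("salt bridges find planted pairs and ignore apolar contacts", {
  d <- make_contact_dimer(data.frame(res_a = "LYS", res_b = "GLU",
                                     distance = 2.8))
  sb <- salt_bridges(d, "A", "B")
  expect_identical(nrow(sb), 1L)
  expect_identical(sb$basic_resname, "LYS")
  expect_identical(sb$acidic_resname, "GLU")
  expect_equal(sb$distance, 2.8, tolerance = 0.01)
  # planted pair beyond the 4 A default cutoff is absent
  d6 <- make_contact_dimer(data.frame(res_a = "ARG", res_b = "ASP",
                                      distance = 6.0))
  expect_identical(nrow(salt_bridges(d6, "A", "B")), 0L)
  expect_equal(residue_pair_distance(d6, c("A", 1), c("B", 1),
                                     mode = "charged_group"), 6.0,
               tolerance = 0.01)
  # all-apolar dimer yields none
  leu <- make_contact_dimer(data.frame(res_a = "LEU", res_b = "LEU",
                                       distance = 3.6))
  expect_identical(nrow(salt_bridges(leu, "A", "B")), 0L)
  # two planted bridges are both recovered
  d2 <- make_contact_dimer(data.frame(res_a = c("ARG", "LYS"),
                                      res_b = c("ASP", "GLU"),
                                      distance = c(2.8, 3.0)))
  expect_identical(nrow(salt_bridges(d2, "A", "B")), 2L)
})

test_that("residue pair distances follow their mode", {
  d <- make_contact_dimer(data.frame(res_a = "ARG", res_b = "ASP",
                                     distance = 5.0))
  expect_equal(residue_pair_distance(d, c("A", 1), c("B", 1),
                                     mode = "charged_group"), 5.0,
               tolerance = 0.01)
  expect_equal(residue_pair_distance(d, c("A", 1), c("A", 1)), 0)
  expect_lte(residue_pair_distance(d, c("A", 1), c("B", 1), mode = "min_heavy"),
             5.0 + 0.01)
  expect_error(residue_pair_distance(d, c("A", 1), c("Q", 9)), "not found")
})

test_that("charge complementarity counts the interface-2 residue set", {
  # the H3/H4/H5 face carries Arg76, Lys77, Lys83, Arg119, Lys120 (basic)
  # and Glu80, Glu87, Glu153 (acidic) on each side
  res <- data.frame(
    chain = "A",
    resno = c(76L, 77L, 80L, 83L, 87L, 119L, 120L, 153L),
    resname = c("ARG", "LYS", "GLU", "LYS", "GLU", "ARG", "LYS", "GLU"),
    stringsAsFactors = FALSE)
  res_b <- res
  res_b$chain <- "B"
  rep <- structure(list(side_a = "A", side_b = "B", buried_area = 435,
                        buried_area_total = 870, residues_a = res,
                        residues_b = res_b,
                        salt_bridges = data.frame()[0, ],
                        contact_cutoff = 4.5, salt_bridge_cutoff = 4),
                   class = "interface_report")
  cc <- charge_complementarity(rep)
  expect_identical(cc$basic_a, 5L)
  expect_identical(cc$acidic_a, 3L)
  expect_identical(cc$basic_b, 5L)
  expect_identical(cc$acidic_b, 3L)
  expect_identical(cc$matched_pairs, 0L)
})

test_that("interface_report ties areas, contacts and bridges together", {
  fx <- make_interface1_fixture()
  rep <- interface_report(fx, "A", "D")
  expect_gt(rep$buried_area, 0)
  expect_equal(rep$buried_area_total, 2 * rep$buried_area, tolerance = 1e-9)
  expect_identical(nrow(rep$salt_bridges), 2L)
  # every salt-bridge residue appears in the contact lists
  key_a <- paste(rep$residues_a$chain, rep$residues_a$resno)
  key_b <- paste(rep$residues_b$chain, rep$residues_b$resno)
  for (i in seq_len(nrow(rep$salt_bridges))) {
    sb <- rep$salt_bridges[i, ]
    kb <- paste(sb$basic_chain, sb$basic_resno)
    ka <- paste(sb$acidic_chain, sb$acidic_resno)
    expect_true(all(c(kb, ka) %in% c(key_a, key_b)))
  }
  expect_true(all(rep$salt_bridges$distance <= rep$salt_bridge_cutoff))
  cc <- charge_complementarity(rep)
  expect_identical(cc$matched_pairs, 2L)
})
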