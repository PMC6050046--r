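# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: SASA by band quadrature instead of test points,
# optimal rotation by direct search instead of SVD.

# Quadrature SASA: integrate each atom's solvent-extended sphere over
# latitude bands (rectangle rule in cos(theta) x phi), testing band points
# against all neighbour spheres.  n_band^2/2 points per atom.
oracle_sasa <- function(xyz, radii, probe = 1.4, n_band = 400L) {
  n <- nrow(xyz)
  r <- radii + probe
  areas <- numeric(n)
  cth <- seq(-1 + 1 / n_band, 1 - 1 / n_band, length.out = n_band)
  phi <- seq(0, 2 * pi, length.out = 2L * n_band + 1L)[-1L]
  sth <- sqrt(1 - cth^2)
  for (i in seq_len(n)) {
    acc_frac <- 0
    for (b in seq_along(cth)) {
      px <- xyz[i, 1] + r[i] * sth[b] * cos(phi)
      py <- xyz[i, 2] + r[i] * sth[b] * sin(phi)
      pz <- xyz[i, 3] + r[i] * cth[b]
      ok <- rep(TRUE, length(phi))
      for (j in seq_len(n)[-i]) {
        ok <- ok & ((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 +
                      (pz - xyz[j, 3])^2 >= r[j]^2)
      }
      acc_frac <- acc_frac + sum(ok)
    }
    areas[i] <- acc_frac / (n_band * 2 * n_band) * 4 * pi * r[i]^2
  }
  areas
}

# Closed-form SASA loss for two overlapping solvent-extended spheres:
# spherical-cap area buried on sphere 1 by sphere 2.
oracle_cap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  2 * pi * r1 * (r1 - x1)
}

# Brute-force optimal-rotation RMSD: random-restart direct search over
# axis-angle parameters polished with Nelder-Mead.  Independent of the
# Kabsch/SVD route.
oracle_min_rmsd <- function(mobile, target, n_starts = 60L, seed = 1L) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  tc <- sweep(target, 2, colMeans(target))
  rot_from_par <- function(p) {
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    a <- p / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  obj <- function(p) {
    R <- rot_from_par(p)
    sqrt(mean(rowSums((mc %*% t(R) - tc)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::runif(3, -pi, pi)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Compose a rotation about z by `deg` with a translation, as a plain
# function on coordinates (transform-algebra oracle for sheet assembly).
oracle_rotz_apply <- function(xyz, deg, t) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  sweep(xyz %*% t(R), 2, t, `+`)
}

# Tiny hand-written PDB fixture text (1 chain, 2 residues).
mini_pdb_lines <- function() {
  c("CRYST1   60.000   60.000   60.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       4.000   4.200   5.100  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       5.000   4.900   5.600  1.00  0.00           C",
    "END")
}

# Draw one composition vector under the config's seed.
with_seed_draw <- function(cfg) {
  set.seed(cfg$seed)
  sample_compositions(cfg)
}

# A small lattice with one planted lateral contact: chain A carries the
# Arg229/Asp301 face at x ~ 0 and the cell's second operator is the
# two-fold that regenerates the facing subunit.
planted_lattice <- function(bridge = 2.8, cell_edge = 60) {
  sub <- rbind(
    ftszlat:::place_fragment("ARG", 229L, "A", c(-bridge / 2, 0, 0), c(1, 0, 0)),
    ftszlat:::place_fragment("ASP", 301L, "A", c(-bridge / 2, 14, 0), c(1, 0, 0)),
    within(ftszlat:::default_subunit_template(), {
      x <- x - 12
      y <- y + 7
    }))
  sub$serial <- seq_len(nrow(sub))
  op2 <- sym_op(diag(c(-1, -1, 1)), c(0, 14 / cell_edge, 0))
  cell <- crystal_frame(cell_edge, cell_edge, cell_edge, spacegroup = "P 1",
                        operators = list(ftszlat:::identity_op(), op2))
  ftsz_structure(sub, cell = cell)
}
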