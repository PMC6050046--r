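# Synthetic fixtures.  These generators produce small pseudo-atom models
# whose geometry is known by construction (planted distances, exact screw
# parameters, analytically sized contacts), so every downstream module can
# be tested without external coordinate files.

# Fixed, non-coplanar 8-atom pseudo-subunit (single-CA "residues").
default_subunit_template <- function() {
  xyz <- matrix(c(
     3.0,  0.0, 0.0,
     0.0,  3.0, 0.5,
    -3.0,  0.5, 1.0,
     0.0, -3.0, 1.5,
     2.0,  2.0, 3.0,
    -2.0, -2.0, 3.5,
     1.5, -2.0, 5.0,
    -1.0,  2.5, 5.5), ncol = 3, byrow = TRUE)
  data.frame(chain = "A", resno = seq_len(nrow(xyz)), resname = "GLY",
             atom = "CA", element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, stringsAsFactors = FALSE)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

#' Generate an idealized helical filament
#'
#' Subunit j (j = 0, 1, ...) is the template rotated by `j * twist` about
#' the z axis and translated by `j * rise` along z, optionally with
#' isotropic Gaussian coordinate jitter.  The derived pitch is
#' `rise * 360 / twist`.
#'
#' @param twist rotation per subunit, degrees (non-zero).
#' @param rise translation per subunit along z, Angstrom.
#' @param n_subunits number of subunits (>= 1).
#' @param template atom data frame for one subunit (default: a fixed
#'   8-atom non-coplanar pseudo-subunit).
#' @param jitter_sigma standard deviation of added coordinate noise,
#'   Angstrom (default 0).
#' @param seed optional seed for the jitter.
#' @return an [ftsz_structure()]; chains are labelled `A`, `B`, ... in
#'   polymer order.
#' @export
make_helical_filament <- function(twist, rise, n_subunits = 6L,
                                  template = default_subunit_template(),
                                  jitter_sigma = 0, seed = NULL) {
  if (!is.numeric(twist) || abs(twist) < 1e-9)
    stopf("`twist` must be non-zero (a pure translation has no pitch)")
  if (!is_count(n_subunits)) stopf("`n_subunits` must be a positive integer")
  if (jitter_sigma < 0) stopf("`jitter_sigma` must be non-negative")
  if (n_subunits > length(PDB_CHAIN_ALPHABET))
    stopf("at most %d subunits supported", length(PDB_CHAIN_ALPHABET))
  with_preserved_seed(seed, {
    parts <- lapply(seq_len(n_subunits) - 1L, function(j) {
      a <- template
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot_z(j * twist))
      xyz[, 3] <- xyz[, 3] + j * rise
      if (jitter_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma),
                            ncol = 3)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      a$chain <- PDB_CHAIN_ALPHABET[j + 1L]
      a
    })
    atoms <- do.call(rbind, parts)
    atoms$serial <- seq_len(nrow(atoms))
    ftsz_structure(atoms, entry = "synthetic_helix",
                   metadata = list(twist = twist, rise = rise,
                                   pitch = rise * 360 / twist,
                                   jitter_sigma = jitter_sigma))
  })
}

#' Generate a P6522-style crystal fixture
#'
#' One pseudo-subunit placed off the 6_5 screw axis of a hexagonal
#' P6522 cell, so that [expand_filament()] over the screw generator yields
#' a compact helical filament whose pitch equals the cell edge `c`.
#'
#' @param c_edge cell c edge in Angstrom (also the generated filament's
#'   pitch).
#' @param a_edge cell a (= b) edge in Angstrom.
#' @param radius distance of the subunit centroid from the screw axis.
#' @return list with `subunit` (an [ftsz_structure()]) and `cell` (a
#'   [crystal_frame()] carrying the 12 P6522 operators).
#' @export
make_crystal_fixture <- function(c_edge = 138.3, a_edge = 100.5,
                                 radius = 25) {
  if (c_edge <= 0 || a_edge <= 0) stopf("cell edges must be positive")
  cell <- crystal_frame(a_edge, a_edge, c_edge, 90, 90, 120,
                        spacegroup = "P 65 2 2")
  a <- default_subunit_template()
  a$x <- a$x + radius
  subunit <- ftsz_structure(a, cell = cell, entry = "synthetic_p6522")
  list(subunit = subunit, cell = cell)
}

# Side-chain fragment templates: head atom at the origin, fragment body
# extending along -x, so the head is the closest atom to a partner placed
# down +x.  Bond geometry is idealized but realistically scaled.
residue_fragment <- function(resname) {
  frag <- switch(resname,
    ARG = data.frame(
      atom = c("NH1", "CZ", "NH2", "NE", "CD"),
      element = c("N", "C", "N", "N", "C"),
      x = c(0, -1.33, -1.99, -1.99, -3.40),
      y = c(0, 0, 1.15, -1.15, -1.25),
      z = c(0, 0, 0, 0, 0.35)),
    ASP = data.frame(
      atom = c("OD1", "CG", "OD2", "CB"),
      element = c("O", "C", "O", "C"),
      x = c(0, -1.25, -1.87, -2.05),
      y = c(0, 0, 1.08, -1.15),
      z = c(0, 0, 0, 0.40)),
    GLU = data.frame(
      atom = c("OE1", "CD", "OE2", "CG"),
      element = c("O", "C", "O", "C"),
      x = c(0, -1.25, -1.87, -2.05),
      y = c(0, 0, 1.08, -1.15),
      z = c(0, 0, 0, 0.40)),
    LYS = data.frame(
      atom = c("NZ", "CE", "CD"),
      element = c("N", "C", "C"),
      x = c(0, -1.49, -2.95),
      y = c(0, 0, 0.45),
      z = c(0, 0, 0.30)),
    ALA = data.frame(atom = "CB", element = "C", x = 0, y = 0, z = 0),
    GLY = data.frame(atom = "CA", element = "C", x = 0, y = 0, z = 0),
    LEU = data.frame(
      atom = c("CD1", "CG", "CD2"),
      element = c("C", "C", "C"),
      x = c(0, -1.30, -1.95),
      y = c(0, 0.75, 2.05),
      z = c(0, 0, 0)),
    stopf("no fragment template for residue type '%s'", resname))
  frag$resname <- resname
  frag
}

place_fragment <- function(resname, resno, chain, head_at, facing = c(1, 0, 0)) {
  frag <- residue_fragment(resname)
  facing <- facing / sqrt(sum(facing^2))
  # rotate the -x fragment axis onto -facing (head points along +facing)
  xax <- c(1, 0, 0)
  v <- c(xax[2] * facing[3] - xax[3] * facing[2],
         xax[3] * facing[1] - xax[1] * facing[3],
         xax[1] * facing[2] - xax[2] * facing[1])
  cth <- sum(xax * facing)
  if (sqrt(sum(v^2)) < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(-1, -1, 1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx / (1 + cth)
  }
  xyz <- as.matrix(frag[, c("x", "y", "z")]) %*% t(R)
  data.frame(chain = chain, resno = resno, resname = frag$resname,
             atom = frag$atom, element = frag$element,
             x = xyz[, 1] + head_at[1], y = xyz[, 2] + head_at[2],
             z = xyz[, 3] + head_at[3], occ = 1, stringsAsFactors = FALSE)
}

#' Generate a two-chain dimer with planted contacts
#'
#' Builds chains `A` and `B` facing each other across the x = 0 plane.
#' Each planted pair is a residue on either side whose functional head
#' atoms meet at the requested minimum distance (exact by construction);
#' pairs are spaced far enough apart not to interact.
#'
#' @param pairs data frame (or list coercible to one) with columns `res_a`,
#'   `res_b` (residue type names) and `distance` (target head-to-head
#'   minimum distance, Angstrom).
#' @param spacing separation between planted pairs along y (Angstrom);
#'   must exceed twice the largest solvent-extended radius so pairs stay
#'   independent.
#' @return an [ftsz_structure()] with chains `A` and `B`; residues are
#'   numbered 1, 2, ... on each side in pair order.
#' @export
make_contact_dimer <- function(pairs, spacing = 12) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) stopf("at least one planted pair is required")
  if (any(pairs$distance < 2))
    stopf("infeasible contact spec: planted distance below 2.0 A would clash")
  if (spacing < 10) stopf("pair spacing below 10 A would couple the pairs")
  parts <- lapply(seq_len(nrow(pairs)), function(i) {
    y <- (i - 1) * spacing
    d <- pairs$distance[i]
    rbind(place_fragment(pairs$res_a[i], i, "A", c(-d / 2, y, 0), c(1, 0, 0)),
          place_fragment(pairs$res_b[i], i, "B", c(d / 2, y, 0), c(-1, 0, 0)))
  })
  atoms <- do.call(rbind, parts)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  ftsz_structure(atoms, entry = "synthetic_dimer",
                 metadata = list(planted = pairs))
}

#' Synthetic emulation of the double-stranded GDP-protofilament lattice
#'
#' A fully synthetic stand-in for the antiparallel double filament that
#' displays lateral interface 1: two three-subunit strands (chains
#' `A, B, C` and `D, E, F`, the second strand antiparallel) in which the
#' `A|D` and `B|E` subunit pairs each form the two symmetric
#' Arg229-Asp301 salt bridges at `bridge_distance`, the third pair `C|F`
#' has its Arg229/Asp301 charged groups separated by `broken_distance`
#' (the broken contact), and the `A|D` interface carries an additional
#' apolar contact patch of isolated carbon-carbon contacts sized so the
#' pair buries approximately the per-side area reported for this
#' interface (about 210 A^2).  All geometry is planted; no experimental
#' coordinates enter.
#'
#' @param bridge_distance N-O distance of the intact salt bridges
#'   (Angstrom, default 2.8).
#' @param broken_distance charged-group separation of the broken third
#'   contact (default 6.0).
#' @param n_patch number of isolated C-C patch contacts added across the
#'   `A|D` interface (default 6, the calibrated value).
#' @param patch_distance C-C distance of each patch contact (default 3.4,
#'   van der Waals contact).
#' @param rise longitudinal spacing of subunits within a strand.
#' @return an [ftsz_structure()] with chains `A`-`F`.
#' @export
make_interface1_fixture <- function(bridge_distance = 2.8,
                                    broken_distance = 6.0,
                                    n_patch = 6L, patch_distance = 3.4,
                                    rise = 43) {
  half <- bridge_distance / 2
  # one subunit of strand 1, interface face toward +x at x = 0:
  #   Arg229 head at (-half, 0, 0), Asp301 head at (-half, dy, 0);
  #   the strand-2 mate is the 180-degree rotation about the z line through
  #   (0, dy/2), which regenerates both salt bridges symmetrically.
  dy <- 14
  subunit_a <- function(chain, z0, x_extra = 0) {
    core <- default_subunit_template()
    core$chain <- chain
    core$resno <- core$resno + 100L
    core$x <- core$x - 12 - x_extra; core$y <- core$y + dy / 2
    core$z <- core$z + z0
    rbind(core,
          place_fragment("ARG", 229L, chain, c(-half - x_extra, 0, z0),
                         c(1, 0, 0)),
          place_fragment("ASP", 301L, chain, c(-half - x_extra, dy, z0),
                         c(1, 0, 0)))
  }
  flip <- function(a) {                    # 180 deg about z through (0, dy/2)
    a$x <- -a$x
    a$y <- dy - a$y
    a
  }
  s1 <- list(subunit_a("A", 0), subunit_a("B", rise), subunit_a("C", 2 * rise,
             x_extra = (broken_distance - bridge_distance) / 2))
  s2 <- lapply(seq_along(s1), function(i) {
    a <- flip(s1[[i]])
    a$chain <- c("D", "E", "F")[i]
    a
  })
  atoms <- do.call(rbind, c(s1, s2))
  # apolar patch across the A|D interface: isolated CB-CB contacts, spaced
  # so each is an independent two-sphere overlap of known buried area
  if (n_patch > 0) {
    patch_y <- seq(-10, by = -8, length.out = n_patch)
    patch <- do.call(rbind, lapply(seq_len(n_patch), function(k) {
      rbind(place_fragment("ALA", 400L + k, "A",
                           c(-patch_distance / 2, patch_y[k], 10), c(1, 0, 0)),
            place_fragment("ALA", 400L + k, "D",
                           c(patch_distance / 2, patch_y[k], 10), c(-1, 0, 0)))
    }))
    atoms <- rbind(atoms, patch)
  }
  atoms <- atoms[order(match(atoms$chain, LETTERS), atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  ftsz_structure(atoms, entry = "synthetic_interface1",
                 metadata = list(bridge_distance = bridge_distance,
                                 broken_distance = broken_distance,
                                 n_patch = n_patch,
                                 patch_distance = patch_distance))
}

#' Named simulation fixtures
#'
#' `"paper_default"` is the full-scale configuration (200 protofilaments
#' of 50 subunits, 10,000 replicates); `"tiny_oracle"` is the enumerable
#' desk configuration (2 protofilaments of 3 subunits, 1e6 replicates)
#' used for comparison against [exact_statistic_small()].
#'
#' @param name `"paper_default"` or `"tiny_oracle"`.
#' @param f disruptive proportion (default 0.4).
#' @param threshold tolerance threshold (default 10 for `paper_default`,
#'   1 for `tiny_oracle`).
#' @param seed optional seed.
#' @return a [zring_config()].
#' @export
make_sim_fixture <- function(name = c("paper_default", "tiny_oracle"),
                             f = 0.4, threshold = NULL, seed = NULL) {
  name <- match.arg(name)
  if (name == "paper_default") {
    zring_config(f = f, threshold = threshold %||% 10L,
                 n_protofilaments = 200L, subunits_per_protofilament = 50L,
                 n_reps = 10000L, seed = seed)
  } else {
    zring_config(f = f, threshold = threshold %||% 1L,
                 n_protofilaments = 2L, subunits_per_protofilament = 3L,
                 n_reps = 1000000L, seed = seed)
  }
}
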