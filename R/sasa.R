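#' Van der Waals radius set
#'
#' Bondi-style element radii used for solvent-accessible surface area.
#' Defaults: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Angstrom with a
#' 1.4 Angstrom water probe.
#'
#' @param radii named numeric vector, element -> radius (Angstrom).
#' @param probe_radius solvent probe radius (Angstrom).
#' @param fallback optional radius for elements missing from `radii`;
#'   `NULL` (default) makes unknown elements an error.
#' @return object of class `radius_set`.
#' @export
radius_set <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                 H = 1.20, P = 1.80),
                       probe_radius = 1.4, fallback = NULL) {
  if (any(radii <= 0)) stopf("all radii must be positive")
  if (probe_radius < 0) stopf("probe radius must be non-negative")
  structure(list(radii = radii, probe_radius = probe_radius,
                 fallback = fallback),
            class = "radius_set")
}

atom_radii <- function(model, radii) {
  r <- unname(radii$radii[model$atoms$element])
  miss <- is.na(r)
  if (any(miss)) {
    if (is.null(radii$fallback)) {
      a <- model$atoms[which(miss)[1L], ]
      stopf("no van der Waals radius for element '%s' (atom %s of %s %d, chain %s)",
            a$element, a$atom, a$resname, a$resno, a$chain)
    }
    r[miss] <- radii$fallback
  }
  r
}

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley test-point method: each atom's
#' solvent-extended sphere (radius + probe) is sampled with a deterministic
#' quasi-uniform point set, and the accessible fraction is the fraction of
#' test points outside every neighbouring extended sphere.
#'
#' @param model an [ftsz_structure()].
#' @param radii a [radius_set()].
#' @param n_sphere_points number of test points per atom (>= 100;
#'   default 960).
#' @return numeric vector of per-atom areas (Angstrom^2), in atom-table
#'   order, with attribute `total`.
#' @export
sasa <- function(model, radii = radius_set(), n_sphere_points = 960L) {
  if (!is_count(n_sphere_points) || n_sphere_points < 100)
    stopf("`n_sphere_points` must be an integer >= 100")
  xyz <- coords(model)
  n <- nrow(xyz)
  r_ext <- atom_radii(model, radii) + radii$probe_radius
  pts <- sphere_points(n_sphere_points)
  # neighbour lists from the pairwise contact condition d < r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    p_i <- pts * r_ext[i]
    p_i <- sweep(p_i, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(accessible)) break
      dx <- p_i[accessible, 1] - xyz[j, 1]
      dy <- p_i[accessible, 2] - xyz[j, 2]
      dz <- p_i[accessible, 3] - xyz[j, 3]
      accessible[accessible] <- (dx * dx + dy * dy + dz * dz) >= r_ext[j]^2
    }
    areas[i] <- sum(accessible) / n_sphere_points * 4 * pi * r_ext[i]^2
  }
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried interface area between two chain sets
#'
#' Computes the solvent-accessible surface area lost on complex formation,
#' `dSASA = SASA(A) + SASA(B) - SASA(A+B)`.  The conventional per-side
#' interface area is `dSASA / 2`; both conventions are returned (the value
#' follows `convention`, the other is in the attributes).
#'
#' @param model an [ftsz_structure()] containing both sides.
#' @param side_a,side_b disjoint chain-id sets.
#' @param radii a [radius_set()].
#' @param n_sphere_points test points per atom for [sasa()].
#' @param convention `"per_side"` (default, dSASA/2) or `"total"` (dSASA).
#' @param include_ligands keep nucleotide/ion/buffer residues (default they
#'   are excluded so the area is protein-protein only).
#' @return numeric scalar (Angstrom^2) with attributes `per_side`, `total`.
#' @export
buried_area <- function(model, side_a, side_b, radii = radius_set(),
                        n_sphere_points = 960L,
                        convention = c("per_side", "total"),
                        include_ligands = FALSE) {
  convention <- match.arg(convention)
  if (length(intersect(side_a, side_b)))
    stopf("side_a and side_b must be disjoint chain sets")
  if (!include_ligands) {
    keep <- !(model$atoms$resname %in% c(ligand_resnames, water_resnames))
    model <- ftsz_structure(model$atoms[keep, , drop = FALSE], cell = model$cell,
                            entry = model$entry, metadata = model$metadata)
  }
  a <- subset_chains(model, side_a)
  b <- subset_chains(model, side_b)
  ab <- merge_structures(a, b)
  total <- attr(sasa(a, radii, n_sphere_points), "total") +
    attr(sasa(b, radii, n_sphere_points), "total") -
    attr(sasa(ab, radii, n_sphere_points), "total")
  total <- max(total, 0)
  out <- if (convention == "per_side") total / 2 else total
  attr(out, "per_side") <- total / 2
  attr(out, "total") <- total
  out
}

cross_side_pairs <- function(model, side_a, side_b, cutoff) {
  at <- model$atoms[!(model$atoms$element %in% c("H", "D")), , drop = FALSE]
  ia <- which(at$chain %in% side_a)
  ib <- which(at$chain %in% side_b)
  if (!length(ia) || !length(ib)) stopf("both sides must be present in the model")
  xa <- as.matrix(at[ia, c("x", "y", "z")])
  xb <- as.matrix(at[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  df <- data.frame(a_row = ia[hit[, 1]], b_row = ib[hit[, 2]],
                   distance = sqrt(pmax(0, d2[hit])),
                   stringsAsFactors = FALSE)
  list(pairs = df, atoms = at)
}

#' Contact residues across an interface
#'
#' Residues with any heavy-atom pair across the two sides within `cutoff`.
#'
#' @param model an [ftsz_structure()].
#' @param side_a,side_b chain-id sets.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return list with data frames `a` and `b` (columns `chain`, `resno`,
#'   `resname`), each sorted by residue number.
#' @export
interface_residues <- function(model, side_a, side_b, cutoff = 4.5) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  cp <- cross_side_pairs(model, side_a, side_b, cutoff)
  empty <- data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), stringsAsFactors = FALSE)
  if (is.null(cp)) return(list(a = empty, b = empty))
  at <- cp$atoms
  res_of <- function(rows) {
    d <- unique(at[rows, c("chain", "resno", "resname")])
    d <- d[order(d$resno, d$chain), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(a = res_of(cp$pairs$a_row), b = res_of(cp$pairs$b_row))
}

BASIC_N_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
ACIDIC_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

is_charged_atom <- function(at, table) {
  keep <- logical(nrow(at))
  for (res in names(table)) {
    keep <- keep | (at$resname == res & at$atom %in% table[[res]])
  }
  keep
}

#' Salt bridges across an interface
#'
#' Pairs where a basic side-chain nitrogen (Arg NH1/NH2/NE, Lys NZ, His
#' ND1/NE2) lies within `cutoff` of an acidic side-chain oxygen (Asp
#' OD1/OD2, Glu OE1/OE2), across the two sides, in either direction.
#' Deduplicated to one row per (basic residue, acidic residue) pair at the
#' minimum N-O distance.
#'
#' @inheritParams interface_residues
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0).
#' @return data frame with columns `basic_chain`, `basic_resno`,
#'   `basic_resname`, `acidic_chain`, `acidic_resno`, `acidic_resname`,
#'   `distance`, sorted by distance.
#' @export
salt_bridges <- function(model, side_a, side_b, cutoff = 4.0) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  at <- model$atoms
  empty <- data.frame(basic_chain = character(0), basic_resno = integer(0),
                      basic_resname = character(0), acidic_chain = character(0),
                      acidic_resno = integer(0), acidic_resname = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  one_direction <- function(basic_side, acidic_side) {
    bi <- which(at$chain %in% basic_side & is_charged_atom(at, BASIC_N_ATOMS))
    ai <- which(at$chain %in% acidic_side & is_charged_atom(at, ACIDIC_O_ATOMS))
    if (!length(bi) || !length(ai)) return(NULL)
    xb <- as.matrix(at[bi, c("x", "y", "z")])
    xa <- as.matrix(at[ai, c("x", "y", "z")])
    d2 <- outer(rowSums(xb^2), rowSums(xa^2), `+`) - 2 * xb %*% t(xa)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(basic_chain = at$chain[bi[hit[, 1]]],
               basic_resno = at$resno[bi[hit[, 1]]],
               basic_resname = at$resname[bi[hit[, 1]]],
               acidic_chain = at$chain[ai[hit[, 2]]],
               acidic_resno = at$resno[ai[hit[, 2]]],
               acidic_resname = at$resname[ai[hit[, 2]]],
               distance = sqrt(pmax(0, d2[hit])),
               stringsAsFactors = FALSE)
  }
  res <- rbind(one_direction(side_a, side_b), one_direction(side_b, side_a))
  if (is.null(res) || !nrow(res)) return(empty)
  key <- paste(res$basic_chain, res$basic_resno, res$acidic_chain, res$acidic_resno)
  res <- res[order(key, res$distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$basic_chain, res$basic_resno,
                               res$acidic_chain, res$acidic_resno)), , drop = FALSE]
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Distance between two residues
#'
#' Minimum pairwise distance between the selected atom sets of two
#' residues: all heavy atoms (`"min_heavy"`) or the charged functional
#' groups only (`"charged_group"`: guanidinium/amino nitrogens of Arg, Lys,
#' His versus carboxylate oxygens of Asp, Glu, whichever applies per
#' residue).
#'
#' @param model an [ftsz_structure()].
#' @param res_a,res_b length-2 vectors `c(chain, seq_id)`.
#' @param mode `"min_heavy"` or `"charged_group"`.
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(model, res_a, res_b,
                                  mode = c("min_heavy", "charged_group")) {
  mode <- match.arg(mode)
  get_res <- function(spec) {
    at <- model$atoms
    sel <- at$chain == as.character(spec[1L]) & at$resno == as.integer(spec[2L])
    if (!any(sel))
      stopf("residue %s/%s not found in model", spec[1L], spec[2L])
    at[sel, , drop = FALSE]
  }
  pick <- function(res) {
    res <- res[!(res$element %in% c("H", "D")), , drop = FALSE]
    if (mode == "charged_group") {
      charged <- is_charged_atom(res, BASIC_N_ATOMS) |
        is_charged_atom(res, ACIDIC_O_ATOMS)
      if (!any(charged))
        stopf("residue %s %d has no charged-group atoms", res$resname[1L],
              res$resno[1L])
      res <- res[charged, , drop = FALSE]
    }
    as.matrix(res[, c("x", "y", "z")])
  }
  xa <- pick(get_res(res_a)); xb <- pick(get_res(res_b))
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Full interface report
#'
#' Combines buried area (both conventions), contact residues, salt bridges
#' and per-side charge composition into one report object.
#'
#' @inheritParams buried_area
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom).
#' @param salt_bridge_cutoff N-O salt-bridge cutoff (Angstrom).
#' @return object of class `interface_report`.
#' @export
interface_report <- function(model, side_a, side_b, radii = radius_set(),
                             n_sphere_points = 960L, contact_cutoff = 4.5,
                             salt_bridge_cutoff = 4.0,
                             include_ligands = FALSE) {
  ba <- buried_area(model, side_a, side_b, radii, n_sphere_points,
                    include_ligands = include_ligands)
  contacts <- interface_residues(model, side_a, side_b, contact_cutoff)
  sb <- salt_bridges(model, side_a, side_b, salt_bridge_cutoff)
  structure(list(side_a = side_a, side_b = side_b,
                 buried_area = as.numeric(ba),
                 buried_area_total = attr(ba, "total"),
                 residues_a = contacts$a, residues_b = contacts$b,
                 salt_bridges = sb,
                 contact_cutoff = contact_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface %s | %s\n", paste(x$side_a, collapse = ","),
              paste(x$side_b, collapse = ",")))
  cat(sprintf("  buried area: %.1f A^2 per side (%.1f A^2 total dSASA)\n",
              x$buried_area, x$buried_area_total))
  cat(sprintf("  contact residues: %d | %d (cutoff %.1f A)\n",
              nrow(x$residues_a), nrow(x$residues_b), x$contact_cutoff))
  cat(sprintf("  salt bridges (cutoff %.1f A): %d\n", x$salt_bridge_cutoff,
              nrow(x$salt_bridges)))
  if (nrow(x$salt_bridges)) {
    sb <- x$salt_bridges
    for (i in seq_len(nrow(sb)))
      cat(sprintf("    %s%d(%s) -- %s%d(%s)  %.2f A\n",
                  sb$basic_resname[i], sb$basic_resno[i], sb$basic_chain[i],
                  sb$acidic_resname[i], sb$acidic_resno[i], sb$acidic_chain[i],
                  sb$distance[i]))
  }
  invisible(x)
}

BASIC_RESNAMES <- c("ARG", "LYS", "HIS")
ACIDIC_RESNAMES <- c("ASP", "GLU")

#' Charge complementarity of an interface
#'
#' Counts basic (Arg, Lys, His) and acidic (Asp, Glu) residues on each side
#' of an interface report, from residue identities alone, and reports the
#' number of matched (salt-bridged) pairs.  Histidine is counted as basic
#' but flagged separately since its protonation state is unknown at
#' crystallographic resolution.
#'
#' @param report an [interface_report()].
#' @return list with `basic_a`, `acidic_a`, `basic_b`, `acidic_b`,
#'   `his_a`, `his_b`, `matched_pairs`.
#' @export
charge_complementarity <- function(report) {
  if (!inherits(report, "interface_report"))
    stopf("`report` must be an interface_report")
  count <- function(res, set) sum(res$resname %in% set)
  list(basic_a = count(report$residues_a, BASIC_RESNAMES),
       acidic_a = count(report$residues_a, ACIDIC_RESNAMES),
       basic_b = count(report$residues_b, BASIC_RESNAMES),
       acidic_b = count(report$residues_b, ACIDIC_RESNAMES),
       his_a = count(report$residues_a, "HIS"),
       his_b = count(report$residues_b, "HIS"),
       matched_pairs = nrow(report$salt_bridges))
}
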