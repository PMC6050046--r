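# Interface-defining residue sets (MtbFtsZ author numbering).
# Interface 1 sits on the S7/S10 face (Arg229-Asp301 salt bridges);
# interface 2 on the H3/H4/H5 face (Arg76...Glu153 charged patch).
INTERFACE_RESIDUES <- list(`1` = c(229L, 301L),
                           `2` = c(76L, 77L, 80L, 83L, 87L, 119L, 120L, 153L))

#' Extract a lateral dimer from a crystal lattice
#'
#' Scans symmetry mates (all cell operators combined with lattice shifts)
#' of each chain for a mate that contacts the reference chain through the
#' residues that define the requested lateral interface, and returns the
#' contacting pair together with the generating transform.  When several
#' mates qualify, the one with the closest approach between the
#' interface-defining residues is taken.
#'
#' @param model an [ftsz_structure()] with a populated `$cell` (or `cell`
#'   given explicitly).
#' @param cell a [crystal_frame()]; defaults to `model$cell`.
#' @param interface_id 1 (S7/S10 face, Arg229/Asp301) or 2 (H3/H4/H5 face).
#' @param contact_cutoff heavy-atom contact cutoff in Angstrom.
#' @param shift_range integer lattice shifts scanned in each direction.
#' @return object of class `lateral_dimer`: a two-chain structure
#'   (`$structure`, chains `$chain_a` and `$chain_b`), the generating
#'   Cartesian [rigid_transform()] and `$interface_id`.
#' @export
extract_lateral_dimer <- function(model, cell = NULL, interface_id = 1,
                                  contact_cutoff = 4.5, shift_range = 1L) {
  cell <- cell %||% model$cell
  if (is.null(cell)) stopf("no crystal frame: supply `cell` or a model with one")
  interface_id <- as.character(interface_id)
  if (!interface_id %in% names(INTERFACE_RESIDUES))
    stopf("interface_id must be 1 or 2")
  face_res <- INTERFACE_RESIDUES[[interface_id]]
  shifts <- expand.grid(s1 = -shift_range:shift_range,
                        s2 = -shift_range:shift_range,
                        s3 = -shift_range:shift_range)
  best <- NULL
  for (ref_chain in chain_ids(model)) {
    ref <- subset_chains(model, ref_chain)
    ref_face <- ref$atoms[ref$atoms$resno %in% face_res, , drop = FALSE]
    if (!nrow(ref_face)) next
    ref_xyz <- as.matrix(ref_face[, c("x", "y", "z")])
    for (oi in seq_along(cell$operators)) {
      for (si in seq_len(nrow(shifts))) {
        shift <- as.numeric(shifts[si, ])
        if (oi == 1L && all(shift == 0)) next   # identity copy
        for (mate_chain in chain_ids(model)) {
          mate <- subset_chains(model, mate_chain)
          mate_m <- apply_symmetry(mate, cell$operators[[oi]], cell,
                                   lattice_shift = shift)
          mate_face <- mate_m$atoms[mate_m$atoms$resno %in% face_res, , drop = FALSE]
          if (!nrow(mate_face)) next
          mate_xyz <- as.matrix(mate_face[, c("x", "y", "z")])
          d2 <- outer(rowSums(ref_xyz^2), rowSums(mate_xyz^2), `+`) -
            2 * ref_xyz %*% t(mate_xyz)
          dmin <- sqrt(max(0, min(d2)))
          if (dmin < contact_cutoff && (is.null(best) || dmin < best$dmin)) {
            ct <- sym_op_to_cartesian(cell$operators[[oi]], cell, shift)
            best <- list(ref_chain = ref_chain, mate_chain = mate_chain,
                         mate = mate_m, dmin = dmin,
                         transform = rigid_transform(ct$R, ct$t))
          }
        }
      }
    }
  }
  if (is.null(best))
    stopf("no symmetry mate buries contacts on the interface-%s face within %.1f A",
          interface_id, contact_cutoff)
  mate <- best$mate
  mate$atoms$chain <- paste0(best$mate_chain, "'")
  dimer <- merge_structures(subset_chains(model, best$ref_chain), mate)
  dimer$cell <- cell
  structure(list(structure = dimer, chain_a = best$ref_chain,
                 chain_b = paste0(best$mate_chain, "'"),
                 generating_transform = best$transform,
                 interface_id = as.integer(interface_id),
                 min_face_distance = best$dmin),
            class = "lateral_dimer")
}

#' @export
print.lateral_dimer <- function(x, ...) {
  cat(sprintf("lateral_dimer (interface %d): chains %s | %s, closest face contact %.2f A\n",
              x$interface_id, x$chain_a, x$chain_b, x$min_face_distance))
  invisible(x)
}

# Pair main-chain atoms of two chains allowing a constant residue-number
# offset (scanned to maximize pairs); returns matched coordinate matrices.
pair_by_offset <- function(mob, tar, selection = MAIN_CHAIN_ATOMS) {
  pick <- function(m) {
    a <- m$atoms
    sel <- a$atom %in% selection
    if (any(sel)) a[sel, , drop = FALSE] else a
  }
  am <- pick(mob); at <- pick(tar)
  key <- function(a, off) paste(a$resno + off, a$atom)
  offsets <- sort(unique(outer(unique(at$resno), unique(am$resno), `-`)))
  best_off <- NULL; best_n <- 0L
  for (off in offsets) {
    n <- length(intersect(key(am, off), key(at, 0L)))
    if (n > best_n) { best_n <- n; best_off <- off }
  }
  if (best_n < 3L || best_n < 0.5 * min(nrow(am), nrow(at)))
    stopf("residue pairing failed: best offset matches %d of %d atoms",
          best_n, min(nrow(am), nrow(at)))
  km <- key(am, best_off); kt <- key(at, 0L)
  shared <- intersect(km, kt)
  am <- am[match(shared, km), , drop = FALSE]
  at <- at[match(shared, kt), , drop = FALSE]
  list(mobile = as.matrix(am[, c("x", "y", "z")]),
       target = as.matrix(at[, c("x", "y", "z")]),
       offset = best_off, n = best_n)
}

#' Graft a lateral dimer onto a template protofilament
#'
#' Superposes the dimer's first subunit onto an anchor subunit of the
#' template filament (main-chain atoms, residue pairing by constant
#' sequence-number offset), applies the same transform to the whole dimer,
#' and returns the template plus the laterally paired partner in its
#' grafted position.  This realizes iterative sheet construction: each
#' graft adds one laterally contacting subunit to a growing model.
#'
#' @param dimer a [extract_lateral_dimer()] result (or a list with
#'   `structure`, `chain_a`, `chain_b`).
#' @param template_filament an [ftsz_structure()].
#' @param anchor_subunit chain id in the template to superpose onto.
#' @param selection atom-name filter for the superposition.
#' @param rmsd_warn warn when the anchoring superposition RMSD exceeds this
#'   (Angstrom); crystal-contact grafts are approximate by construction.
#' @return an [ftsz_structure()]: template plus the placed partner chain
#'   (renamed `<chain_b>g`), with the graft transform in metadata.
#' @export
graft_by_superposition <- function(dimer, template_filament, anchor_subunit,
                                   selection = MAIN_CHAIN_ATOMS,
                                   rmsd_warn = 5) {
  anchor <- subset_chains(template_filament, anchor_subunit)
  sub_a <- subset_chains(dimer$structure, dimer$chain_a)
  pc <- pair_by_offset(sub_a, anchor, selection)
  sp <- superpose(pc$mobile, pc$target)
  if (sp$rmsd > rmsd_warn)
    warnf("graft anchor superposition RMSD %.2f A exceeds %.2f A", sp$rmsd,
          rmsd_warn)
  partner <- subset_chains(dimer$structure, dimer$chain_b)
  placed <- transform_structure(partner, sp$transform)
  placed$atoms$chain <- paste0(sub("'$", "", dimer$chain_b), "g")
  out <- merge_structures(template_filament, placed)
  out$metadata$graft <- list(transform = sp$transform, rmsd = sp$rmsd,
                             anchor = anchor_subunit,
                             pair_offset = pc$offset, n_paired = pc$n)
  out
}

#' Assemble an antiparallel protofilament sheet
#'
#' Places subunit (i, j) of an `n_protofilaments x n_subunits` sheet by
#' composing the lateral transform i times with the longitudinal transform
#' j times: `T_ij = lateral^i o longitudinal^j`.  For an antiparallel
#' sheet the lateral transform must reverse the filament axis, so that
#' orientation flags alternate between adjacent protofilaments; this is
#' checked and recorded.  All applied transforms are recorded in the
#' provenance so the sheet can be replayed exactly.
#'
#' @param subunit single-subunit [ftsz_structure()].
#' @param longitudinal [rigid_transform()] between successive subunits
#'   along a protofilament.
#' @param lateral [rigid_transform()] between adjacent protofilaments.
#' @param n_protofilaments,n_subunits sheet dimensions (>= 1).
#' @param clash_cutoff heavy-atom clash distance (Angstrom).
#' @param max_clash_fraction tolerated fraction of clashing atom pairs
#'   before an error (crystal-contact grafts are approximate).
#' @return an `ftsz_sheet` (also `ftsz_structure`): chains named
#'   `P<i>S<j>`, with `$metadata$sheet` holding protofilament chain lists,
#'   orientation flags and per-chain transforms.
#' @export
assemble_sheet <- function(subunit, longitudinal, lateral,
                           n_protofilaments = 4L, n_subunits = 6L,
                           clash_cutoff = 2.2, max_clash_fraction = 0.005) {
  if (!is_count(n_protofilaments) || !is_count(n_subunits))
    stopf("sheet dimensions must be positive integers")
  if (n_protofilaments == 1L && n_subunits == 1L) return(subunit)
  # orientation: does the lateral transform flip the longitudinal axis?
  long_screw <- tryCatch(screw_parameters(longitudinal), error = function(e) NULL)
  axis <- if (!is.null(long_screw)) long_screw$axis else {
    v <- longitudinal$translation
    if (sqrt(sum(v^2)) < 1e-9) stopf("longitudinal transform is the identity")
    v / sqrt(sum(v^2))
  }
  flipped <- sum((lateral$rotation %*% axis) * axis) < 0
  if (n_protofilaments >= 2L && !flipped)
    warnf("lateral transform does not reverse the filament axis; sheet will not be antiparallel")
  copies <- list(); provenance <- list(); orientations <- integer(0)
  protos <- vector("list", n_protofilaments)
  lat_pow <- rigid_transform(diag(3))
  for (i in seq_len(n_protofilaments) - 1L) {
    lon_pow <- rigid_transform(diag(3))
    proto_chains <- character(0)
    for (j in seq_len(n_subunits) - 1L) {
      tr <- compose_transform(lat_pow, lon_pow)
      copy <- transform_structure(subunit, tr)
      id <- sprintf("P%dS%d", i + 1L, j + 1L)
      copy$atoms$chain <- id
      copies[[length(copies) + 1L]] <- copy
      provenance[[id]] <- tr
      proto_chains <- c(proto_chains, id)
      lon_pow <- compose_transform(longitudinal, lon_pow)
    }
    protos[[i + 1L]] <- proto_chains
    orientations <- c(orientations,
                      if (flipped && i %% 2L == 1L) -1L else 1L)
    lat_pow <- compose_transform(lateral, lat_pow)
  }
  sheet <- do.call(merge_structures, copies)
  clashes <- clash_check(sheet, cutoff = clash_cutoff)
  n_atoms <- nrow(sheet$atoms)
  n_pairs <- n_atoms * (n_atoms - 1) / 2
  if (nrow(clashes) > max_clash_fraction * n_pairs)
    stopf("sheet assembly produced %d clashing atom pairs (> %.2f%% of %d pairs)",
          nrow(clashes), 100 * max_clash_fraction, n_pairs)
  sheet$metadata$sheet <- list(protofilaments = protos,
                               orientations = orientations,
                               provenance = provenance,
                               clashes = clashes)
  class(sheet) <- c("ftsz_sheet", class(sheet))
  sheet
}

#' @export
print.ftsz_sheet <- function(x, ...) {
  s <- x$metadata$sheet
  cat(sprintf("ftsz_sheet: %d protofilaments x %d subunits (%d atoms)\n",
              length(s$protofilaments), length(s$protofilaments[[1L]]),
              nrow(x$atoms)))
  cat("  orientations:", paste(ifelse(s$orientations > 0, "+", "-"),
                               collapse = " "), "\n")
  invisible(x)
}

#' Inter-chain steric clashes
#'
#' All heavy-atom pairs from different chains closer than `cutoff`, found
#' with a spatial hash (cell lists) and returned in deterministic
#' (serial-sorted) order.
#'
#' @param model an [ftsz_structure()].
#' @param cutoff clash distance in Angstrom (default 2.2).
#' @return data frame `serial_i`, `serial_j`, `chain_i`, `chain_j`,
#'   `distance`.
#' @export
clash_check <- function(model, cutoff = 2.2) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  at <- model$atoms[!(model$atoms$element %in% c("H", "D")), , drop = FALSE]
  empty <- data.frame(serial_i = integer(0), serial_j = integer(0),
                      chain_i = character(0), chain_j = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(at)
  if (n < 2L) return(empty)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cellkey <- floor(xyz / cutoff)
  keystr <- paste(cellkey[, 1], cellkey[, 2], cellkey[, 3])
  buckets <- split(seq_len(n), keystr)
  ukeys <- do.call(rbind, strsplit(names(buckets), " "))
  ukeys <- matrix(as.numeric(ukeys), ncol = 3)
  key_index <- stats::setNames(seq_along(buckets), names(buckets))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  hits <- list()
  for (b in seq_along(buckets)) {
    i_idx <- buckets[[b]]
    nb_keys <- sweep(offs, 2, ukeys[b, ], `+`)
    nb_str <- paste(nb_keys[, 1], nb_keys[, 2], nb_keys[, 3])
    j_idx <- unlist(buckets[nb_str[nb_str %in% names(buckets)]], use.names = FALSE)
    for (i in i_idx) {
      j <- j_idx[j_idx > i]
      j <- j[at$chain[j] != at$chain[i]]
      if (!length(j)) next
      d2 <- (xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
        (xyz[j, 3] - xyz[i, 3])^2
      hit <- j[d2 < cutoff^2]
      if (length(hit))
        hits[[length(hits) + 1L]] <- data.frame(
          serial_i = at$serial[i], serial_j = at$serial[hit],
          chain_i = at$chain[i], chain_j = at$chain[hit],
          distance = sqrt(d2[d2 < cutoff^2]), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$serial_i, out$serial_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
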