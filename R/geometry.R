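#' Rigid-body transform
#'
#' A proper rotation plus translation acting on Cartesian coordinates
#' (`x' = R x + t`).
#'
#' @param rotation 3x3 proper rotation matrix (det +1, orthonormal to 1e-9).
#' @param translation length-3 numeric, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stopf("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stopf("rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stopf("rotation must be proper (det +1), got det = %.9f", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation |t| = %.3f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' @rdname rigid_transform
#' @param t2,t1 transforms; the result applies `t1` first, then `t2`.
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' @rdname rigid_transform
#' @param tr a `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), as.numeric(-t(tr$rotation) %*% tr$translation))
}

#' @rdname rigid_transform
#' @param xyz n x 3 coordinate matrix.
#' @export
apply_transform <- function(tr, xyz) {
  xyz <- rbind(xyz)
  xyz %*% t(tr$rotation) + matrix(tr$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Transform all coordinates of a structure
#'
#' @param model an [ftsz_structure()].
#' @param tr a [rigid_transform()].
#' @return the transformed structure.
#' @export
transform_structure <- function(model, tr) {
  xyz <- apply_transform(tr, coords(model))
  atoms <- model$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  ftsz_structure(atoms, cell = model$cell, entry = model$entry,
                 source = model$source, metadata = model$metadata)
}

rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# Default main-chain selection; the reported pitches are insensitive to the
# exact backbone subset for rigid subunits.
MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O")

# Extract paired coordinate matrices from two structures by matching
# (chain-order, residue, atom name) after an atom-name selection.
paired_coords <- function(mobile, target, selection = MAIN_CHAIN_ATOMS) {
  pick <- function(m) {
    a <- m$atoms
    if (!is.null(selection)) {
      sel <- a$atom %in% selection
      if (!any(sel)) a else a[sel, , drop = FALSE]   # pseudo-atom fallback
    } else a
  }
  am <- pick(mobile); at <- pick(target)
  if (nrow(am) != nrow(at))
    stopf("superposition needs equal atom counts after selection (%d vs %d)",
          nrow(am), nrow(at))
  mism <- which(am$atom != at$atom)
  if (length(mism))
    stopf("mismatched atom pairing at position %d: %s %d/%s vs %s %d/%s",
          mism[1L], am$resname[mism[1L]], am$resno[mism[1L]], am$atom[mism[1L]],
          at$resname[mism[1L]], at$resno[mism[1L]], at$atom[mism[1L]])
  list(mobile = as.matrix(am[, c("x", "y", "z")]),
       target = as.matrix(at[, c("x", "y", "z")]))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinates, via singular value decomposition of the covariance
#' matrix with the usual determinant correction that excludes reflections.
#'
#' @param mobile,target either n x 3 coordinate matrices or
#'   [ftsz_structure()]s (paired by atom order after `selection`).
#' @param selection atom-name filter applied when structures are given;
#'   default main-chain atoms `N, CA, C, O` (structures without any such
#'   atoms, e.g. pseudo-atom fixtures, fall back to all atoms).
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   target) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target, selection = MAIN_CHAIN_ATOMS) {
  if (inherits(mobile, "ftsz_structure") && inherits(target, "ftsz_structure")) {
    pc <- paired_coords(mobile, target, selection)
    m <- pc$mobile; x <- pc$target
  } else {
    m <- rbind(mobile); x <- rbind(target)
    if (nrow(m) != nrow(x)) stopf("coordinate sets must pair 1:1")
  }
  if (nrow(m) < 3L) stopf("superposition requires at least 3 atom pairs")
  cm <- colMeans(m); cx <- colMeans(x)
  mm <- sweep(m, 2, cm); xx <- sweep(x, 2, cx)
  sv <- svd(crossprod(mm, xx))            # H = t(m_c) %*% x_c
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stopf("superposition underdetermined: points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cx - as.numeric(R %*% cm)
  fitted <- mm %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - xx)^2)))
  list(transform = rigid_transform(R, t_vec), rmsd = rmsd)
}

#' Screw-axis parameters of a rigid transform
#'
#' Decomposes a rigid transform into its screw description: rotation axis,
#' rotation angle, axial rise, and pitch (`rise * 360 / angle`).  The axis
#' is oriented so the rise is non-negative; the angle is reported as a
#' magnitude in (0, 180], with the handedness (sign of the rotation about
#' the oriented axis) in `$handedness`.  Pitch is therefore always
#' non-negative.
#'
#' @param tr a [rigid_transform()].
#' @param angle_tolerance minimum rotation angle in degrees below which the
#'   transform is treated as a pure translation (no screw axis; error).
#' @return object of class `screw_parameters` with fields `axis`, `angle`
#'   (degrees), `rise` (Angstrom), `pitch` (Angstrom), `point_on_axis`,
#'   `handedness`.
#' @export
screw_parameters <- function(tr, angle_tolerance = 0.1) {
  R <- tr$rotation
  angle <- rotation_angle(R)
  if (angle < angle_tolerance)
    stopf("no screw axis: rotation angle %.4f deg below tolerance %.4f deg",
          angle, angle_tolerance)
  if (angle > 180 - 1e-9) {
    # axis from the +1 eigenvector of R
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
    signed <- 180
  } else {
    # axis from the skew-symmetric part: (R - t(R)) encodes sin(angle)*axis
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- w / sqrt(sum(w^2))
    signed <- angle
  }
  rise <- sum(tr$translation * axis)
  handedness <- "right"
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
    handedness <- "left"
  }
  # point on axis: solve (I - R) p = t_perp in the plane perpendicular to axis
  t_perp <- tr$translation - sum(tr$translation * axis) * axis
  A <- diag(3) - R
  p <- tryCatch(as.numeric(MASS_ginv(A) %*% t_perp), error = function(e) c(0, 0, 0))
  pitch <- rise * 360 / angle
  structure(list(axis = axis, angle = angle, rise = rise, pitch = pitch,
                 point_on_axis = p, handedness = handedness),
            class = "screw_parameters")
}

# Moore-Penrose pseudo-inverse (small, avoids a MASS dependency).
MASS_ginv <- function(A, tol = 1e-9) {
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1]
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
print.screw_parameters <- function(x, ...) {
  cat(sprintf("screw: angle %.4f deg, rise %.4f A, pitch %.4f A (%s-handed)\n",
              x$angle, x$rise, x$pitch, x$handedness))
  cat(sprintf("  axis: [%.4f %.4f %.4f]\n", x$axis[1], x$axis[2], x$axis[3]))
  if (!is.null(x$n_pairs))
    cat(sprintf("  averaged over %d consecutive pairs (pitch sd %.2e A)\n",
                x$n_pairs, x$pitch_sd))
  invisible(x)
}

#' Helical parameters of a filament by consecutive superposition
#'
#' Superposes each consecutive pair of subunits (main-chain atoms by
#' default), extracts screw parameters per pair, and averages them after
#' flipping all axes into a common hemisphere.  The dispersion of the
#' per-pair pitch estimates is reported.
#'
#' @param filament an [ftsz_structure()] with >= 2 subunit chains.
#' @param subunit_order chain ids in polymer order; defaults to the order of
#'   appearance.
#' @param selection atom-name filter for superposition.
#' @return a [screw_parameters()] object with extra fields `n_pairs`,
#'   `pitch_sd`, `rmsd` (mean superposition RMSD).
#' @export
filament_pitch <- function(filament, subunit_order = NULL,
                           selection = MAIN_CHAIN_ATOMS) {
  subunit_order <- subunit_order %||% chain_ids(filament)
  if (length(subunit_order) < 2L)
    stopf("filament must contain at least 2 subunits")
  subs <- lapply(subunit_order, function(ch) subset_chains(filament, ch))
  # residue-content compatibility check
  key <- function(s) paste(s$atoms$resno, s$atoms$resname, s$atoms$atom)
  k1 <- key(subs[[1L]])
  for (s in subs[-1L]) {
    shared <- length(intersect(key(s), k1)) / max(length(k1), length(key(s)))
    if (shared < 0.5)
      stopf("subunits share fewer than 50%% of their residues; not a filament of identical subunits")
  }
  pairs <- lapply(seq_len(length(subs) - 1L), function(i) {
    sp <- superpose(subs[[i]], subs[[i + 1L]], selection = selection)
    list(screw = screw_parameters(sp$transform), rmsd = sp$rmsd)
  })
  screws <- lapply(pairs, `[[`, "screw")
  axes <- t(vapply(screws, `[[`, numeric(3), "axis"))
  ref <- axes[1L, ]
  flip <- drop(axes %*% ref) < 0
  axes[flip, ] <- -axes[flip, ]
  axis <- colMeans(axes)
  axis <- axis / sqrt(sum(axis^2))
  angle <- mean(vapply(screws, `[[`, numeric(1), "angle"))
  rise <- mean(vapply(screws, `[[`, numeric(1), "rise"))
  pitches <- vapply(screws, `[[`, numeric(1), "pitch")
  out <- screws[[1L]]
  out$axis <- axis; out$angle <- angle; out$rise <- rise
  out$pitch <- rise * 360 / angle
  out$n_pairs <- length(screws)
  out$pitch_sd <- if (length(pitches) > 1L) stats::sd(pitches) else 0
  out$rmsd <- mean(vapply(pairs, `[[`, numeric(1), "rmsd"))
  out
}

#' Helical pitch implied by a crystallographic screw axis
#'
#' For an n-fold screw axis n_m along c, successive subunits are rotated by
#' 360/n degrees and translated by (m/n) c; reducing the translation by
#' lattice repeats gives the compact helix, whose pitch is
#' `|c * r * n|` where `r` is `m/n` wrapped into (-1/2, 1/2].  For all
#' six-fold screws this equals `c`, so the crystal c axis directly reports
#' the filament pitch.
#'
#' @param cell a [crystal_frame()].
#' @param screw_fold the fold n of the screw axis (2, 3, 4, or 6).
#' @param screw_translation_fraction m/n, the fractional translation of the
#'   screw (default 5/6, the 6_5 screw of P6522).
#' @return pitch in Angstrom.
#' @export
pitch_from_screw_symmetry <- function(cell, screw_fold = 6L,
                                      screw_translation_fraction = 5 / 6) {
  if (!screw_fold %in% c(2L, 3L, 4L, 6L))
    stopf("unsupported screw fold %s (crystallographic folds are 2, 3, 4, 6)",
          as.character(screw_fold))
  fr <- screw_translation_fraction
  if (!is.numeric(fr) || fr <= 0 || fr >= 1)
    stopf("screw translation fraction must lie in (0, 1)")
  m <- round(fr * screw_fold)       # screw index: n_m has fraction m/n
  if (abs(m - fr * screw_fold) > 1e-9)
    stopf("screw translation fraction must be a multiple of 1/%d", screw_fold)
  k <- m %% screw_fold              # reduce by lattice repeats (integer exact)
  if (k > screw_fold / 2) k <- k - screw_fold
  if (k == 0) stopf("screw with zero reduced translation has no pitch")
  cell$c * abs(k)
}
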