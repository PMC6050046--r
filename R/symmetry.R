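#' Symmetry operator in fractional coordinates
#'
#' @param rotation 3x3 matrix acting on fractional coordinates.
#' @param translation length-3 fractional translation.
#' @return object of class `sym_op`.
#' @export
sym_op <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stopf("translation must have length 3")
  if (abs(abs(det(rotation)) - 1) > 1e-9)
    stopf("symmetry rotation must have determinant +/-1 (got %.6f)", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "sym_op")
}

identity_op <- function() sym_op(diag(3), c(0, 0, 0))

#' @export
print.sym_op <- function(x, ...) {
  cat("sym_op:", sym_op_triplet(x), "\n")
  invisible(x)
}

# Human-readable triplet like "-y,x-y,z+2/3" (for printing only).
sym_op_triplet <- function(op) {
  axes <- c("x", "y", "z")
  comp <- vapply(1:3, function(i) {
    terms <- character(0)
    for (j in 1:3) {
      cf <- op$rotation[i, j]
      if (abs(cf) > 1e-9) {
        s <- if (cf > 0 && length(terms)) "+" else if (cf < 0) "-" else ""
        terms <- c(terms, paste0(s, axes[j]))
      }
    }
    tr <- op$translation[i]
    if (abs(tr) > 1e-9) {
      fr <- round(tr * 12)
      terms <- c(terms, sprintf("%+d/12", as.integer(fr)))
    }
    paste(terms, collapse = "")
  }, character(1))
  paste(comp, collapse = ",")
}

# The 12 general-position operators of space group P6522 (no. 179),
# hard-coded and validated by closure (see p6522_check_closure).
#' P6522 symmetry operators
#'
#' The twelve general-position operators of the hexagonal space group
#' P6522, in fractional coordinates.  This is the only space group needed
#' for the MtbFtsZ lattices handled here; other groups are accepted via an
#' explicit operator list in [crystal_frame()].
#'
#' @return list of [sym_op()] (the first is the identity; the second is the
#'   6_5 screw generator `x-y, x, z+5/6`).
#' @export
p6522_operators <- function() {
  trip <- list(
    list(r = c( 1, 0, 0,  0, 1, 0,  0, 0, 1), t = c(0, 0, 0)),      # x,y,z
    list(r = c( 1,-1, 0,  1, 0, 0,  0, 0, 1), t = c(0, 0, 5/6)),    # x-y,x,z+5/6
    list(r = c( 0,-1, 0,  1,-1, 0,  0, 0, 1), t = c(0, 0, 2/3)),    # -y,x-y,z+2/3
    list(r = c(-1, 0, 0,  0,-1, 0,  0, 0, 1), t = c(0, 0, 1/2)),    # -x,-y,z+1/2
    list(r = c(-1, 1, 0, -1, 0, 0,  0, 0, 1), t = c(0, 0, 1/3)),    # -x+y,-x,z+1/3
    list(r = c( 0, 1, 0, -1, 1, 0,  0, 0, 1), t = c(0, 0, 1/6)),    # y,-x+y,z+1/6
    list(r = c( 0,-1, 0, -1, 0, 0,  0, 0,-1), t = c(0, 0, 1/6)),    # -y,-x,-z+1/6
    list(r = c(-1, 0, 0, -1, 1, 0,  0, 0,-1), t = c(0, 0, 1/3)),    # -x,-x+y,-z+1/3
    list(r = c(-1, 1, 0,  0, 1, 0,  0, 0,-1), t = c(0, 0, 1/2)),    # -x+y,y,-z+1/2
    list(r = c( 0, 1, 0,  1, 0, 0,  0, 0,-1), t = c(0, 0, 2/3)),    # y,x,-z+2/3
    list(r = c( 1, 0, 0,  1,-1, 0,  0, 0,-1), t = c(0, 0, 5/6)),    # x,x-y,-z+5/6
    list(r = c( 1,-1, 0,  0,-1, 0,  0, 0,-1), t = c(0, 0, 0)))      # x-y,-y,-z
  lapply(trip, function(e) sym_op(matrix(e$r, 3, 3, byrow = TRUE), e$t))
}

normalize_spacegroup <- function(sg) {
  gsub("[ _()]", "", toupper(sg))
}

#' Crystal frame: unit cell plus symmetry operators
#'
#' Builds the geometric description of a crystal: cell edges (Angstrom),
#' cell angles (degrees), Hermann-Mauguin space-group symbol, and the list
#' of symmetry operators in fractional coordinates.  For P6522 the
#' operator list is built in; any other group must supply `operators`
#' explicitly (general symbol parsing is out of scope).
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spacegroup Hermann-Mauguin symbol.
#' @param operators list of [sym_op()]; defaults to the built-in P6522 set
#'   for that group, or the identity for `"P 1"`.
#' @return object of class `crystal_frame` with precomputed
#'   orthogonalization (`$orth`) and fractionalization (`$frac`) matrices.
#' @export
crystal_frame <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                          spacegroup = "P 1", operators = NULL) {
  if (any(!is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    stopf("cell edges must be positive and finite")
  sgn <- normalize_spacegroup(spacegroup)
  if (is.null(operators)) {
    operators <- if (sgn == "P6522") p6522_operators()
    else if (sgn == "P1") list(identity_op())
    else stopf("no built-in operators for space group '%s'; supply `operators`",
               spacegroup)
  }
  if (sgn == "P6522") {
    if (length(operators) != 12L)
      stopf("P6522 requires 12 operators, got %d", length(operators))
    if (abs(gamma - 120) > 1e-6) stopf("P6522 requires gamma = 120 degrees")
    if (abs(a - b) > 1e-6) stopf("P6522 requires a = b")
  }
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  cz_sq <- 1 - cos(br)^2 -
    ((cos(ar) - cos(br) * cos(gr)) / sin(gr))^2
  if (cz_sq <= 1e-12) stopf("degenerate cell: zero volume")
  # standard PDB orthogonalization (a along x, b in xy plane)
  orth <- matrix(c(
    a, b * cos(gr), c * cos(br),
    0, b * sin(gr), c * (cos(ar) - cos(br) * cos(gr)) / sin(gr),
    0, 0,           c * sqrt(cz_sq)), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, spacegroup = spacegroup,
                 operators = operators, orth = orth, frac = solve(orth)),
            class = "crystal_frame")
}

#' @export
print.crystal_frame <- function(x, ...) {
  cat(sprintf("crystal_frame: a=%.3f b=%.3f c=%.3f  alpha=%.1f beta=%.1f gamma=%.1f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("  %s (%d operators)\n", x$spacegroup, length(x$operators)))
  invisible(x)
}

# Compose two fractional operators: (op2 o op1)(x) = R2 (R1 x + t1) + t2.
compose_sym_ops <- function(op2, op1) {
  sym_op(op2$rotation %*% op1$rotation,
         as.numeric(op2$rotation %*% op1$translation) + op2$translation)
}

# Check closure of an operator list modulo lattice translations.
# Returns TRUE or a description of the first failure.
sym_ops_closed <- function(ops, tol = 1e-9) {
  key <- function(op) {
    t_mod <- op$translation - floor(op$translation + tol)
    t_mod[t_mod > 1 - 1e-6] <- 0
    paste(c(round(op$rotation, 6), round(t_mod, 6)), collapse = ",")
  }
  keys <- vapply(ops, key, character(1))
  for (i in seq_along(ops)) for (j in seq_along(ops)) {
    k <- key(compose_sym_ops(ops[[i]], ops[[j]]))
    if (!(k %in% keys))
      return(sprintf("product of operators %d and %d leaves the set", i, j))
  }
  TRUE
}

# Convert a fractional operator (plus lattice shift) to a Cartesian rigid
# transform: x' = M (R f(x) + t + s) with f(x) = M^-1 x.
sym_op_to_cartesian <- function(op, cell, lattice_shift = c(0, 0, 0)) {
  R <- cell$orth %*% op$rotation %*% cell$frac
  t <- as.numeric(cell$orth %*% (op$translation + lattice_shift))
  list(R = R, t = t)
}

#' Apply a crystallographic symmetry operator to a structure
#'
#' Transforms all coordinates by `x' = orth(R * frac(x) + t + shift)` where
#' `R`, `t` act in fractional coordinates and `shift` is an integer lattice
#' translation.  Chain ids can be remapped deterministically by appending a
#' tag; the applied operator is recorded in the result's metadata.
#'
#' @param model an [ftsz_structure()].
#' @param op a [sym_op()].
#' @param cell a [crystal_frame()].
#' @param lattice_shift integer 3-vector of unit-cell translations.
#' @param chain_tag optional string appended to every chain id of the copy.
#' @return transformed [ftsz_structure()].
#' @export
apply_symmetry <- function(model, op, cell, lattice_shift = c(0, 0, 0),
                           chain_tag = NULL) {
  if (!inherits(cell, "crystal_frame")) stopf("`cell` must be a crystal_frame")
  if (!inherits(op, "sym_op")) stopf("`op` must be a sym_op")
  if (length(lattice_shift) != 3L || any(lattice_shift != round(lattice_shift)))
    stopf("`lattice_shift` must be an integer 3-vector")
  ct <- sym_op_to_cartesian(op, cell, lattice_shift)
  xyz <- coords(model)
  new_xyz <- xyz %*% t(ct$R) + matrix(ct$t, nrow(xyz), 3, byrow = TRUE)
  atoms <- model$atoms
  atoms$x <- new_xyz[, 1]; atoms$y <- new_xyz[, 2]; atoms$z <- new_xyz[, 3]
  if (!is.null(chain_tag)) atoms$chain <- paste0(atoms$chain, chain_tag)
  md <- model$metadata
  md$applied_ops <- c(md$applied_ops,
                      list(list(op = op, lattice_shift = lattice_shift)))
  ftsz_structure(atoms, cell = model$cell, entry = model$entry,
                 source = model$source, metadata = md)
}

# Reduce the axial translation of a Cartesian screw generator by integer
# c-lattice shifts so that successive copies form the most compact helix.
reduce_generator_shift <- function(op, cell) {
  tz_frac <- op$translation[3]
  k <- -round(tz_frac)
  c(0, 0, k)
}

#' Expand one subunit into a helical filament by a screw generator
#'
#' Applies successive powers of a symmetry operator to a subunit, producing
#' `n_copies` chains related by the screw.  The generator's axial
#' translation is first reduced modulo the c lattice translation so the
#' resulting helix is the compact one (e.g. the 6_5 screw of P6522 steps by
#' c/6 per subunit and closes one turn per cell repeat).  Copies are named
#' `<chain><k>` for copy k; provenance is recorded in metadata.
#'
#' @param model single-subunit [ftsz_structure()].
#' @param cell a [crystal_frame()].
#' @param generator a [sym_op()]; defaults to the second operator of the
#'   cell (for P6522, the 6_5 screw).
#' @param n_copies number of subunits in the filament (>= 1).
#' @return an [ftsz_structure()] with `n_copies` chains per input chain.
#' @export
expand_filament <- function(model, cell, generator = NULL, n_copies = 6L) {
  if (!is_count(n_copies)) stopf("`n_copies` must be a positive integer")
  if (!inherits(cell, "crystal_frame")) stopf("`cell` must be a crystal_frame")
  generator <- generator %||% cell$operators[[min(2L, length(cell$operators))]]
  if (n_copies == 1L) return(model)
  shift <- reduce_generator_shift(generator, cell)
  ct <- sym_op_to_cartesian(generator, cell, shift)
  # zero-rise guard: the reduced generator must displace the subunit
  cen <- colMeans(coords(model))
  disp <- as.numeric(ct$R %*% cen + ct$t) - cen
  if (sqrt(sum(disp^2)) < 1e-6)
    stopf("generator superimposes the subunit on itself (zero rise)")
  copies <- vector("list", n_copies)
  copies[[1L]] <- model
  current <- model
  for (k in seq_len(n_copies - 1L)) {
    current <- apply_symmetry(current, generator, cell, lattice_shift = shift)
    copy <- current
    copy$atoms$chain <- paste0(model$atoms$chain, k)
    copies[[k + 1L]] <- copy
  }
  out <- do.call(merge_structures, copies)
  out$cell <- cell
  out$metadata$filament <- list(generator = generator, lattice_shift = shift,
                                n_copies = n_copies)
  out
}
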