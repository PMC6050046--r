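#' Atomic structure container
#'
#' `ftsz_structure()` builds the package's coordinate container from a flat
#' atom table.  The container is deliberately simple: one data frame with one
#' row per atom (columns `serial`, `chain`, `resno`, `resname`, `atom`,
#' `element`, `x`, `y`, `z`, `occ`), an optional [crystal_frame()] describing
#' the unit cell, and free-form metadata.  All coordinates are Cartesian
#' Angstroms; fractional coordinates exist only transiently inside symmetry
#' application.
#'
#' @param atoms data frame with the columns listed above (`serial` and `occ`
#'   are filled in when missing).
#' @param cell optional [crystal_frame()].
#' @param entry optional entry identifier (e.g. a PDB id or fixture name).
#' @param source optional source path.
#' @param metadata optional named list of extra metadata.
#' @return An object of class `ftsz_structure`.
#' @export
ftsz_structure <- function(atoms, cell = NULL, entry = NA_character_,
                           source = NA_character_, metadata = list()) {
  required <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stopf("structure must contain at least one atom")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$atom <- as.character(atoms$atom)
  atoms$resname <- as.character(atoms$resname)
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("non-finite coordinates in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stopf("occupancies must lie in [0, 1]")
  dup <- duplicated(atoms[, c("chain", "resno", "atom")])
  if (any(dup)) {
    d <- atoms[which(dup)[1L], ]
    stopf("duplicated atom name '%s' in residue %s %d of chain %s",
          d$atom, d$resname, d$resno, d$chain)
  }
  rownames(atoms) <- NULL
  if (!is.null(cell) && !inherits(cell, "crystal_frame"))
    stopf("`cell` must be a crystal_frame")
  structure(list(atoms = atoms, cell = cell, entry = entry, source = source,
                 metadata = metadata),
            class = "ftsz_structure")
}

#' @export
print.ftsz_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("ftsz_structure", if (!is.na(x$entry)) sprintf("[%s]", x$entry), "\n")
  cat(sprintf("  %d atoms, %d residues, %d chain(s): %s\n",
              nrow(x$atoms), n_residues(x), length(ch),
              paste(utils::head(ch, 12), collapse = " ")))
  if (!is.null(x$cell))
    cat(sprintf("  cell: a=%.2f b=%.2f c=%.2f  %s (%d ops)\n",
                x$cell$a, x$cell$b, x$cell$c, x$cell$spacegroup,
                length(x$cell$operators)))
  invisible(x)
}

#' @rdname ftsz_structure
#' @param x an `ftsz_structure`.
#' @export
chain_ids <- function(x) unique(x$atoms$chain)

#' @rdname ftsz_structure
#' @export
n_residues <- function(x) {
  nrow(unique(x$atoms[, c("chain", "resno")]))
}

#' Coordinate matrix of a structure
#'
#' @param x an `ftsz_structure`.
#' @param chains optional chain ids to restrict to.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x, chains = NULL) {
  a <- x$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Subset a structure by chain
#'
#' @param x an `ftsz_structure`.
#' @param chains chain ids to keep.
#' @return an `ftsz_structure` containing only the requested chains.
#' @export
subset_chains <- function(x, chains) {
  keep <- x$atoms$chain %in% chains
  if (!any(keep)) stopf("no atoms in chain(s) %s", paste(chains, collapse = ","))
  ftsz_structure(x$atoms[keep, , drop = FALSE], cell = x$cell,
                 entry = x$entry, source = x$source, metadata = x$metadata)
}

# Combine structures, requiring disjoint chain ids.
merge_structures <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  all_chains <- unlist(lapply(parts, chain_ids))
  if (anyDuplicated(all_chains))
    stopf("cannot merge structures with shared chain id(s): %s",
          paste(unique(all_chains[duplicated(all_chains)]), collapse = ","))
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  ftsz_structure(atoms, cell = parts[[1L]]$cell, entry = parts[[1L]]$entry,
                 metadata = parts[[1L]]$metadata)
}

water_resnames <- c("HOH", "WAT", "DOD", "H2O")
ligand_resnames <- c("GTP", "GDP", "GNP", "GSP", "MG", "CA", "NA", "CL", "SO4",
                     "GOL", "EDO", "PO4", "CIT")

guess_element <- function(elety) {
  e <- toupper(trimws(elety))
  two <- substr(e, 1, 2)
  out <- substr(e, 1, 1)
  out[two %in% c("FE", "MG", "ZN", "MN", "CL", "BR", "SE")] <-
    two[two %in% c("FE", "MG", "ZN", "MN", "CL", "BR", "SE")]
  # numeric-prefixed hydrogens like 1HB
  out[grepl("^[0-9]", e)] <- substr(sub("^[0-9]+", "", e), 1, 1)[grepl("^[0-9]", e)]
  out
}

# Parse a CRYST1 record / mmCIF _cell items into a crystal_frame (or NULL).
parse_cell_from_lines <- function(lines, format) {
  if (format == "pdb") {
    ln <- grep("^CRYST1", lines, value = TRUE)
    if (!length(ln)) return(NULL)
    ln <- ln[1L]
    vals <- suppressWarnings(as.numeric(c(
      substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
      substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
    sg <- trimws(substr(ln, 56, 66))
    if (any(is.na(vals))) return(NULL)
  } else {
    grab <- function(key) {
      ln <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
      if (!length(ln)) return(NA_real_)
      suppressWarnings(as.numeric(strsplit(trimws(ln[1L]), "\\s+")[[1L]][2L]))
    }
    vals <- c(grab("_cell.length_a"), grab("_cell.length_b"),
              grab("_cell.length_c"), grab("_cell.angle_alpha"),
              grab("_cell.angle_beta"), grab("_cell.angle_gamma"))
    sgl <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
    sg <- if (length(sgl)) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sgl[1L])))
          else "P 1"
    if (any(is.na(vals))) return(NULL)
  }
  ops <- if (normalize_spacegroup(sg) == "P6522") NULL else list(identity_op())
  crystal_frame(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
                spacegroup = sg, operators = ops)
}

#' Read a macromolecular structure
#'
#' Reads atomic coordinates from PDB or mmCIF files (parsing is delegated to
#' \pkg{bio3d}; the unit-cell record is read alongside).  By default
#' hydrogens and waters are dropped and, where alternate conformers are
#' present, only the highest-occupancy conformer of each atom is kept, so
#' that downstream interface areas are single-conformer quantities.  Atoms
#' with zero occupancy are dropped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param keep_hydrogens,keep_waters logical; retain H atoms / water residues.
#' @return an [ftsz_structure()]; `$cell` is populated when the file carries
#'   a cell record.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_hydrogens = FALSE, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", mmcif = "cif", pdb = "pdb", ent = "pdb",
                     stopf("cannot infer format from extension '.%s'; pass `format`", ext))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || !any(nzchar(trimws(lines))))
    stopf("parse error: %s is empty", path)
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) stopf("parse error: no atom records in %s", path)
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(serial = at$eleno, chain = as.character(at$chain),
                      resno = at$resno, resname = at$resid, atom = at$elety,
                      element = toupper(trimws(element)),
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      alt = if (is.null(at$alt)) NA_character_ else at$alt,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms <- atoms[atoms$occ > 0, , drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (!keep_waters) atoms <- atoms[!(atoms$resname %in% water_resnames), , drop = FALSE]
  # highest-occupancy alternate conformer per atom
  if (any(!is.na(atoms$alt) & nzchar(atoms$alt))) {
    ord <- order(atoms$chain, atoms$resno, atoms$atom, -atoms$occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "atom")]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$alt <- NULL
  if (!nrow(atoms)) stopf("no atoms left after filtering in %s", path)
  cell <- parse_cell_from_lines(lines, format)
  entry <- sub("\\.[^.]+$", "", basename(path))
  ftsz_structure(atoms, cell = cell, entry = entry, source = path)
}

format_pdb_atom_line <- function(serial, name, resname, chain, resno,
                                 x, y, z, occ, element) {
  name_fmt <- ifelse(nchar(name) >= 4L, substr(name, 1, 4),
                     sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_fmt, substr(resname, 1, 3), chain, resno,
          x, y, z, occ, 0, element)
}

#' Write a macromolecular structure
#'
#' Writes PDB (fixed-column ATOM/CRYST1 records, coordinates to 3 decimals)
#' or mmCIF (`atom_site` loop at full precision, with `cell` and `symmetry`
#' categories when the structure carries a crystal frame).  PDB chain ids
#' must be single characters; structures with more than one character per id
#' are remapped to `A-Z a-z 0-9` in order of first appearance (the mapping is
#' returned in the `chain_map` attribute), and more than 62 chains is an
#' error advising mmCIF.
#'
#' @param model an [ftsz_structure()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return `path`, invisibly, with attribute `chain_map` for PDB output.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!inherits(model, "ftsz_structure")) stopf("`model` must be an ftsz_structure")
  if (!nrow(model$atoms)) stopf("refusing to write a structure with no atoms")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", mmcif = "cif", pdb = "pdb",
                     stopf("cannot infer format from extension '.%s'; pass `format`", ext))
  }
  a <- model$atoms
  if (format == "pdb") {
    ch <- unique(a$chain)
    if (length(ch) > 62L)
      stopf("%d chains exceed the 62 single-character PDB chain ids; write mmCIF instead",
            length(ch))
    map <- ch
    if (any(nchar(ch) != 1L) || anyDuplicated(substr(ch, 1, 1))) {
      map <- PDB_CHAIN_ALPHABET[seq_along(ch)]
    }
    names(map) <- ch
    lines <- character(0)
    if (!is.null(model$cell)) {
      cl <- model$cell
      lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                       cl$spacegroup)
    }
    lines <- c(lines,
               format_pdb_atom_line(seq_len(nrow(a)), a$atom, a$resname,
                                    map[a$chain], a$resno, a$x, a$y, a$z,
                                    a$occ, a$element),
               "END")
    writeLines(lines, path)
    out <- path
    attr(out, "chain_map") <- map
    return(invisible(out))
  }
  # mmCIF
  lines <- c(sprintf("data_%s", ifelse(is.na(model$entry), "model", model$entry)))
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- c(lines,
               sprintf("_cell.length_a    %.4f", cl$a),
               sprintf("_cell.length_b    %.4f", cl$b),
               sprintf("_cell.length_c    %.4f", cl$c),
               sprintf("_cell.angle_alpha %.2f", cl$alpha),
               sprintf("_cell.angle_beta  %.2f", cl$beta),
               sprintf("_cell.angle_gamma %.2f", cl$gamma),
               sprintf("_symmetry.space_group_name_H-M  '%s'", cl$spacegroup))
  }
  lines <- c(lines, "loop_",
             "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
             "_atom_site.label_atom_id", "_atom_site.label_alt_id",
             "_atom_site.label_comp_id", "_atom_site.label_asym_id",
             "_atom_site.label_entity_id", "_atom_site.label_seq_id",
             "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num",
             sprintf("ATOM %d %s %s . %s %s 1 %d ? %.6f %.6f %.6f %.2f 0.00 %d %s %s %s 1",
                     seq_len(nrow(a)), a$element, a$atom, a$resname, a$chain,
                     a$resno, a$x, a$y, a$z, a$occ, a$resno, a$resname,
                     a$chain, a$atom),
             "#")
  writeLines(lines, path)
  invisible(path)
}
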