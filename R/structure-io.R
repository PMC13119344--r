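#' Read a VHH domain structure into an atom table
#'
#' Parses a single-chain VHH structure from PDB or mmCIF into a tidy atom
#' table keyed by AHo position. Parsing is delegated to bio3d; this function
#' adds the curation policy used throughout the package: hydrogens are
#' discarded, alternate locations are resolved to the highest occupancy
#' (ties: first in file), and residue numbers are taken as AHo positions
#' unless a `numbering` map is supplied. Insertion codes are rejected unless
#' the numbering map resolves them.
#'
#' @param source Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param chain Chain identifier; required when the file has several chains.
#' @param numbering Optional residue-number map: a data frame with columns
#'   `author` (author residue id, character; insertion codes appended, e.g.
#'   `"100A"`) and `aho` (AHo position), or a path to a two-column TSV with
#'   those columns. Residues absent from the map are dropped.
#' @param id Structure identifier stored in the `id` column (defaults to the
#'   file base name).
#' @return A tibble with columns `id`, `aho`, `aa` (one-letter), `atom`
#'   (PDB atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @export
read_vhh_structure <- function(source, format = c("auto", "pdb", "mmcif"),
                               chain = NULL, numbering = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", source, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(source))
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(source, rm.alt = FALSE, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(source, verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      rlang::abort(sprintf(
        "file has %d chains (%s); supply `chain`",
        length(chains), paste(chains, collapse = ", ")
      ))
    }
  } else {
    if (!chain %in% chains) {
      rlang::abort(sprintf("chain '%s' not present (have: %s)", chain,
                           paste(chains, collapse = ", ")))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  # drop hydrogens
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- guess_element(at$elety)
  }
  elem <- toupper(trimws(elem))
  keep <- !elem %in% c("H", "D")
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  # altloc: highest occupancy, first-in-file tiebreak
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  akey <- paste(at$resno, at$insert, at$elety, sep = "|")
  sel <- unlist(lapply(split(seq_len(nrow(at)), akey), function(i) {
    i[which.max(occ[i])]
  }), use.names = FALSE)
  sel <- sort(sel)
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  author <- paste0(at$resno, ins)
  if (is.null(numbering)) {
    if (any(nzchar(ins))) {
      rlang::abort("insertion codes present; supply a `numbering` map to resolve them")
    }
    aho <- at$resno
  } else {
    map <- load_numbering_map(numbering)
    aho <- map$aho[match(author, map$author)]
    drop <- is.na(aho)
    at <- at[!drop, , drop = FALSE]
    elem <- elem[!drop]
    aho <- aho[!drop]
    author <- author[!drop]
  }
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    rlang::abort("non-finite coordinates in structure")
  }
  out <- tibble::tibble(
    id = id,
    aho = as.integer(aho),
    aa = suppressWarnings(bio3d::aa321(at$resid)),
    atom = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z
  )
  # AHo position collision: same slot claimed by different author residues
  by_aho <- tapply(author, out$aho, function(a) length(unique(a)))
  if (any(by_aho > 1L)) {
    rlang::abort(sprintf(
      "AHo position collision at: %s",
      paste(names(by_aho)[by_aho > 1L], collapse = ", ")
    ))
  }
  validate_atoms(out)
  out
}

load_numbering_map <- function(numbering) {
  if (is.character(numbering) && length(numbering) == 1L) {
    numbering <- utils::read.table(numbering, header = TRUE, sep = "\t",
                                   colClasses = c("character", "integer"))
  }
  numbering <- as.data.frame(numbering)
  if (!all(c("author", "aho") %in% names(numbering))) {
    rlang::abort("numbering map needs columns `author` and `aho`")
  }
  numbering$author <- as.character(numbering$author)
  numbering$aho <- as.integer(numbering$aho)
  numbering
}

guess_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  el <- substr(nm, 1L, 1L)
  el[grepl("^[0-9]", nm)] <- substr(nm[grepl("^[0-9]", nm)], 2L, 2L)
  el
}

validate_atoms <- function(atoms) {
  need <- c("id", "aho", "aa", "atom", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    rlang::abort(sprintf("atom table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    rlang::abort("atom table has non-finite coordinates")
  }
  invisible(atoms)
}

#' Write an atom table as a minimal PDB file
#'
#' Coordinates are written at the standard three-decimal PDB precision, so a
#' read/write round trip preserves them to 1e-3 Angstrom.
#'
#' @param atoms Atom tibble (see [read_vhh_structure()]); must hold a single
#'   structure.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vhh_pdb <- function(atoms, path) {
  validate_atoms(atoms)
  if (length(unique(atoms$id)) > 1L) {
    rlang::abort("write_vhh_pdb() writes one structure at a time")
  }
  aa3 <- vapply(atoms$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r)) "UNK" else r
  }, character(1), USE.NAMES = FALSE)
  name4 <- vapply(atoms$atom, function(a) {
    if (nchar(a) >= 4L) substr(a, 1, 4) else sprintf(" %-3s", a)
  }, character(1), USE.NAMES = FALSE)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, aa3, "A", atoms$aho,
    atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Derive the AHo-aligned sequence of a structure
#'
#' @param atoms Atom tibble for one or more structures.
#' @return A tibble with columns `id`, `seq`: the 149-slot aligned sequence
#'   with `-` at AHo positions lacking residues.
#' @export
structure_sequence <- function(atoms) {
  validate_atoms(atoms)
  res <- dplyr::distinct(atoms, .data$id, .data$aho, .data$aa)
  out <- lapply(split(res, res$id), function(r) {
    slots <- rep("-", AHO_LENGTH)
    aa <- r$aa
    aa[is.na(aa) | !aa %in% AA1] <- "X"
    slots[r$aho] <- aa
    paste(slots, collapse = "")
  })
  tibble::tibble(id = names(out), seq = unlist(out, use.names = FALSE))
}

# split an atom table into per-structure pieces, preserving order
split_structures <- function(atoms) {
  split(atoms, factor(atoms$id, levels = unique(atoms$id)))
}
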