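#' Atomic structures as tidy tibbles
#'
#' An `rna_structure` is a tibble with one row per atom and columns
#' `chain`, `resno`, `insert`, `resname`, `atom`, `element`, `x`, `y`, `z`,
#' `occupancy`, `b` (isotropic B-factor, square-Angstrom) plus an `eleno`
#' atom serial that preserves file order. Coordinates are in Angstrom and
#' residues are addressed by author numbering throughout, matching the
#' convention used for intron nucleotides such as G75 or U238.
#'
#' @param atoms data frame of atom records.
#' @param id structure identifier string.
#' @param source_format one of `"pdb"`, `"mmcif"`, `"internal"`.
#' @return A tibble of class `rna_structure`.
#' @export
new_structure <- function(atoms, id = "structure", source_format = "internal") {
  required <- c("chain", "resno", "insert", "resname", "atom",
                "element", "x", "y", "z", "occupancy", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("structure is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  if (nrow(atoms) == 0) abort("structure must contain at least one residue")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("all atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$atom))) abort("atom names must be non-empty")
  dup <- duplicated(atoms[, c("chain", "resno", "insert", "atom")])
  if (any(dup)) {
    abort("atom names must be unique within a residue (after altloc resolution)")
  }
  attr(atoms, "id") <- id
  attr(atoms, "source_format") <- source_format
  class(atoms) <- c("rna_structure", class(atoms))
  atoms
}

#' @export
print.rna_structure <- function(x, ...) {
  nres <- nrow(unique(as.data.frame(x)[, c("chain", "resno", "insert")]))
  cat(sprintf("<rna_structure '%s'> %d atoms, %d residues (%s)\n",
              structure_id(x), nrow(x), nres, attr(x, "source_format")))
  NextMethod()
}

#' @rdname new_structure
#' @param s an `rna_structure`.
#' @export
structure_id <- function(s) attr(s, "id") %||% "structure"

`%||%` <- function(a, b) if (is.null(a)) b else a

standard_nucleotides <- c("A", "U", "G", "C", "I",
                          "DA", "DT", "DG", "DC", "DU",
                          "ADE", "URA", "GUA", "CYT", "THY")

water_names <- c("HOH", "WAT", "H2O", "DOD")

is_nucleic_residue <- function(resname, atom_names) {
  toupper(resname) %in% standard_nucleotides ||
    any(atom_names %in% c("C1'", "O4'", "P")) && !(toupper(resname) %in% water_names)
}

guess_element <- function(atom, element = NULL) {
  if (!is.null(element) && nzchar(element)) return(element)
  substr(gsub("[^A-Za-z].*$", "", atom), 1, 1)
}

#' Read an RNA coordinate file
#'
#' Parses ATOM/HETATM records of a PDB or mmCIF file into an
#' [new_structure()] tibble. Hydrogens and waters are dropped; for alternate
#' locations only the highest-occupancy conformer is kept; only the first
#' model of a multi-model file is read (use [read_ensemble()] for ensembles).
#' Metal ions are retained in the table but excluded from geometry selections
#' by the default backbone/base atom filters.
#'
#' @param path file path; format inferred from the extension (`.pdb`, `.ent`
#'   vs `.cif`, `.mmcif`) when `format` is `NULL`.
#' @param format optional explicit format tag, `"pdb"` or `"mmcif"`.
#' @param id structure identifier; defaults to the file base name.
#' @return An `rna_structure` tibble.
#' @export
read_structure <- function(path, format = NULL, id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read structure file: ", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = , ent = , pdb1 = "pdb",
      cif = , mmcif = "mmcif",
      abort(paste0("cannot infer format from extension '", ext,
                   "'; pass format = 'pdb' or 'mmcif'"))
    )
  }
  id <- id %||% tools::file_path_sans_ext(basename(path))
  atoms <- switch(format,
    pdb = read_pdb_atoms(path),
    mmcif = read_mmcif_atoms(path),
    abort(paste0("unknown format tag: ", format))
  )
  atoms <- clean_atom_table(atoms)
  if (nrow(atoms) == 0) {
    abort(paste0("no nucleic-acid residues found in ", path))
  }
  new_structure(atoms, id = id, source_format = format)
}

read_pdb_atoms <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  tibble(
    chain = ifelse(is.na(a$chain), "A", as.character(a$chain)),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resname = trimws(as.character(a$resid)),
    atom = trimws(as.character(a$elety)),
    element = trimws(ifelse(is.na(a$elesy), "", as.character(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
    eleno = as.integer(a$eleno)
  )
}

# Minimal mmCIF atom_site reader (no installed R package parses mmCIF).
# Handles the standard loop_ layout with quoted tokens such as "C1'".
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0) abort(paste0("no _atom_site loop in ", path))
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_[A-Za-z])", ln)) break
    body <- c(body, ln)
  }
  toks <- lapply(body, function(ln) {
    scan(text = ln, what = character(), quiet = TRUE)
  })
  keep <- vapply(toks, length, integer(1)) == length(tags)
  toks <- toks[keep]
  if (length(toks) == 0) abort(paste0("no parsable atom_site rows in ", path))
  m <- do.call(rbind, toks)
  colnames(m) <- tags
  col <- function(nm, default = NA_character_) {
    if (nm %in% tags) m[, nm] else rep(default, nrow(m))
  }
  model <- col("pdbx_PDB_model_num", "1")
  first_model <- model == model[1]
  m <- m[first_model, , drop = FALSE]
  col2 <- function(nm, default = NA_character_) {
    if (nm %in% tags) m[, nm] else rep(default, nrow(m))
  }
  chain <- col2("auth_asym_id")
  if (all(is.na(chain))) chain <- col2("label_asym_id", "A")
  resno <- col2("auth_seq_id")
  if (all(is.na(resno))) resno <- col2("label_seq_id", "0")
  atomnm <- col2("auth_atom_id")
  if (all(is.na(atomnm))) atomnm <- col2("label_atom_id")
  resname <- col2("auth_comp_id")
  if (all(is.na(resname))) resname <- col2("label_comp_id")
  ins <- col2("pdbx_PDB_ins_code", "")
  ins[ins %in% c("?", ".")] <- ""
  alt <- col2("label_alt_id", "")
  alt[alt %in% c("?", ".")] <- ""
  occ <- suppressWarnings(as.numeric(col2("occupancy", "1")))
  tibble(
    chain = as.character(chain),
    resno = as.integer(as.numeric(resno)),
    insert = as.character(ins),
    resname = as.character(resname),
    atom = as.character(atomnm),
    element = toupper(as.character(col2("type_symbol", ""))),
    x = as.numeric(col2("Cartn_x")),
    y = as.numeric(col2("Cartn_y")),
    z = as.numeric(col2("Cartn_z")),
    occupancy = ifelse(is.na(occ), 1, occ),
    b = suppressWarnings(as.numeric(col2("B_iso_or_equiv", "0"))),
    alt = as.character(alt),
    eleno = seq_len(nrow(m))
  )
}

clean_atom_table <- function(atoms) {
  atoms$element <- mapply(guess_element, atoms$atom, atoms$element,
                          USE.NAMES = FALSE)
  atoms <- atoms[toupper(atoms$element) != "H" &
                   !grepl("^[0-9]*H", atoms$atom), , drop = FALSE]
  atoms <- atoms[!(toupper(atoms$resname) %in% water_names), , drop = FALSE]
  if (nrow(atoms) == 0) return(atoms)
  # highest-occupancy altloc per atom, ties broken by file order
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert,
                       atoms$atom, -atoms$occupancy, atoms$eleno), ]
  atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "insert", "atom")]), ]
  atoms <- atoms[order(atoms$eleno), ]
  # keep nucleic-acid residues and single-atom ions; drop protein/ligands
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    res <- atoms[i, ]
    nuc <- is_nucleic_residue(res$resname[1], res$atom)
    ion <- nrow(res) == 1 && !nuc
    if (nuc || ion) i else integer(0)
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  nuc_rows <- vapply(split(seq_len(nrow(atoms)),
                           paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")),
                     function(i) is_nucleic_residue(atoms$resname[i[1]], atoms$atom[i]),
                     logical(1))
  if (!any(nuc_rows)) return(atoms[0, , drop = FALSE])
  atoms$alt <- NULL
  atoms
}

#' Write a structure to a PDB file
#'
#' Emits standards-conformant ATOM records via [bio3d::write.pdb()];
#' round-tripping through [read_structure()] preserves residue identity and
#' coordinates to the 1e-3 Angstrom precision of the PDB format.
#'
#' @param s an `rna_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  if (!inherits(s, "rna_structure")) abort("s must be an rna_structure")
  if (nrow(s) == 0) abort("cannot write an empty structure")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(s)),
      resno = s$resno,
      resid = s$resname,
      eleno = seq_len(nrow(s)),
      elety = s$atom,
      chain = s$chain,
      insert = ifelse(nzchar(s$insert), s$insert, NA),
      o = s$occupancy,
      b = s$b,
      elesy = s$element
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write structure to ", path,
                                ": ", conditionMessage(ok)))
  invisible(path)
}

#' Summarise residues of a structure
#'
#' @param s an `rna_structure`.
#' @return Tibble with one row per residue: chain, resno, insert, resname,
#'   and the atom count.
#' @export
residue_table <- function(s) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(s), .data$chain, .data$resno,
                    .data$insert, .data$resname),
    n_atoms = dplyr::n(), .groups = "drop"
  )
}

#' Coordinate matrix of a structure or atom table
#'
#' @param atoms data frame with x, y, z columns.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(atoms) {
  m <- as.matrix(as.data.frame(atoms)[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

set_coords <- function(s, m) {
  s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
  s
}
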