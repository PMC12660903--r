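#' Residue-range atom selections
#'
#' A selection names inclusive author-numbered residue ranges on one or more
#' chains, optionally restricted to a set of atom names. Selections drive all
#' geometry operations: helix-axis fits, displacement profiles, path
#' milestones, and ensemble reports.
#'
#' @param ranges list of `c(start, end)` integer pairs (inclusive), or a
#'   single pair; residue numbers use author numbering.
#' @param chain chain identifier applied to every range (recycled), or a
#'   character vector parallel to `ranges`.
#' @param atoms optional character vector of atom names to keep (e.g. `"P"`
#'   or the backbone set); `NULL` keeps all atoms.
#' @param name optional label used in error messages and reports.
#' @return An object of class `atom_selection`.
#' @export
selection <- function(ranges, chain = "A", atoms = NULL, name = NULL) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || r[1] > r[2]) {
      abort("each range must be c(start, end) with start <= end")
    }
    r
  })
  chain <- rep_len(as.character(chain), length(ranges))
  structure(
    list(ranges = ranges, chain = chain, atoms = atoms, name = name),
    class = "atom_selection"
  )
}

#' @export
print.atom_selection <- function(x, ...) {
  rng <- paste(vapply(seq_along(x$ranges), function(i) {
    sprintf("%s:%d-%d", x$chain[i], x$ranges[[i]][1], x$ranges[[i]][2])
  }, character(1)), collapse = ", ")
  cat(sprintf("<atom_selection%s> %s%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"), rng,
              if (is.null(x$atoms)) "" else
                paste0(" [", paste(x$atoms, collapse = ","), "]")))
  invisible(x)
}

#' Resolve a selection against a structure
#'
#' Returns the selected atoms in deterministic order: by chain, residue
#' number, insertion code, then file atom order within the residue. Residues
#' named by the selection but absent from the model are silently skipped and
#' counted in the `n_missing_residues` attribute (`selection_report()` shows
#' the tally); a range that references a chain not present in the structure
#' is an error.
#'
#' @param s an `rna_structure`.
#' @param sel an [selection()].
#' @return Tibble of selected atom rows, with attributes
#'   `n_missing_residues` and `missing_residues`.
#' @export
resolve_selection <- function(s, sel) {
  stopifnot(inherits(sel, "atom_selection"))
  tbl <- as_tibble(s)
  bad_chain <- setdiff(unique(sel$chain), unique(tbl$chain))
  if (length(bad_chain) > 0) {
    abort(paste0("selection references chain(s) not in structure: ",
                 paste(bad_chain, collapse = ", ")))
  }
  pieces <- lapply(seq_along(sel$ranges), function(i) {
    r <- sel$ranges[[i]]
    hit <- tbl[tbl$chain == sel$chain[i] &
                 tbl$resno >= r[1] & tbl$resno <= r[2], , drop = FALSE]
    requested <- tibble(chain = sel$chain[i], resno = seq(r[1], r[2]))
    list(atoms = hit, requested = requested)
  })
  atoms <- dplyr::bind_rows(lapply(pieces, `[[`, "atoms"))
  requested <- dplyr::bind_rows(lapply(pieces, `[[`, "requested"))
  requested <- dplyr::distinct(requested)
  if (!is.null(sel$atoms)) {
    atoms <- atoms[atoms$atom %in% sel$atoms, , drop = FALSE]
  }
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert, atoms$eleno), ]
  present <- dplyr::distinct(atoms[, c("chain", "resno")])
  missing <- dplyr::anti_join(requested, present, by = c("chain", "resno"))
  attr(atoms, "n_missing_residues") <- nrow(missing)
  attr(atoms, "missing_residues") <- missing
  atoms
}

#' @rdname resolve_selection
#' @param resolved result of `resolve_selection()`.
#' @export
selection_report <- function(resolved) {
  tibble(
    n_atoms = nrow(resolved),
    n_missing_residues = attr(resolved, "n_missing_residues") %||% 0L
  )
}

#' Backbone and base atom-name sets
#'
#' `backbone_atoms()` returns the default sugar-phosphate backbone set used
#' for helical-axis fitting; `extended = TRUE` adds the sugar-ring atoms.
#' `base_ring_atoms()` returns the nucleobase ring atom names (purine 9-ring
#' or pyrimidine 6-ring) used for flip classification centroids.
#'
#' @param extended add sugar-ring atoms C1', C2', O4' to the backbone set.
#' @export
backbone_atoms <- function(extended = FALSE) {
  core <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
  if (extended) c(core, "C1'", "C2'", "O4'") else core
}

#' @rdname backbone_atoms
#' @param resname residue name used to pick purine vs pyrimidine ring.
#' @export
base_ring_atoms <- function(resname) {
  purines <- c("A", "G", "ADE", "GUA", "DA", "DG", "I")
  if (toupper(resname) %in% purines) {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}

#' Subdomain registries
#'
#' A registry maps subdomain labels to [selection()]s, names the two gate
#' atoms, and defines which subdomain pair each inter-helical angle compares.
#' The packaged registry (`default_registry()`) encodes the
#' *Oceanobacillus iheyensis* group II intron D1 scaffold: core D1c
#' (66-75/112-121), peripheral D1c (80-102), D1d1 (124-133/230-242),
#' i1-i2 (6-23/250-267), the two hinge motifs, and the G75/U238 C1' gate.
#' Two hinge-1 variants are recorded (115-116 vs 114-116) because the source
#' literature uses both; the registry flags rather than resolves the
#' discrepancy.
#'
#' @param path YAML registry file; see `inst/extdata/oiheyensis_d1.yaml` for
#'   the schema (keys: subdomains with chain/ranges/atoms, gate, angles,
#'   hinges, atom_set).
#' @return A list of class `subdomain_registry` with elements `subdomains`
#'   (named list of selections), `gate` (two `(chain, resno, atom)` triples),
#'   `angles` (named list of subdomain-label pairs), `hinges`, and
#'   `atom_set` (backbone atom names used for axis fits).
#' @export
read_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  subdomains <- lapply(cfg$subdomains, function(sd) {
    selection(ranges = lapply(sd$ranges, unlist),
              chain = sd$chain %||% "A",
              atoms = sd$atoms,
              name = sd$name)
  })
  names(subdomains) <- vapply(cfg$subdomains, `[[`, character(1), "name")
  gate <- lapply(cfg$gate, function(g) {
    list(chain = g$chain %||% "A", resno = as.integer(g$resno),
         atom = g$atom %||% "C1'")
  })
  angles <- lapply(cfg$angles, function(a) c(a$between[[1]], a$between[[2]]))
  names(angles) <- vapply(cfg$angles, `[[`, character(1), "name")
  registry <- list(
    subdomains = subdomains,
    gate = gate,
    angles = angles,
    hinges = cfg$hinges,
    atom_set = cfg$atom_set %||% backbone_atoms()
  )
  bad <- setdiff(unlist(angles), names(subdomains))
  if (length(bad) > 0) {
    abort(paste0("angle definitions reference unregistered subdomains: ",
                 paste(bad, collapse = ", ")))
  }
  class(registry) <- "subdomain_registry"
  registry
}

#' @rdname read_registry
#' @export
default_registry <- function() {
  path <- system.file("extdata", "oiheyensis_d1.yaml", package = "rnagate")
  if (!nzchar(path)) abort("packaged registry not found")
  read_registry(path)
}

#' @export
print.subdomain_registry <- function(x, ...) {
  cat("<subdomain_registry>\n")
  for (nm in names(x$subdomains)) {
    cat(" -", nm, ": ")
    print(x$subdomains[[nm]])
  }
  cat(sprintf(" gate: %s%d:%s -- %s%d:%s\n",
              x$gate[[1]]$chain, x$gate[[1]]$resno, x$gate[[1]]$atom,
              x$gate[[2]]$chain, x$gate[[2]]$resno, x$gate[[2]]$atom))
  for (nm in names(x$angles)) {
    cat(sprintf(" angle %s: %s vs %s\n", nm, x$angles[[nm]][1], x$angles[[nm]][2]))
  }
  invisible(x)
}
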