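#' Conformational ensembles
#'
#' An ensemble is an ordered list of structures (e.g. models refined into the
#' twenty 3D-variability sub-states of a cryo-EM data set) with unique frame
#' labels.
#'
#' @param frames list of `rna_structure` objects (>= 2).
#' @param labels character labels aligned to frames; default
#'   `"sub-state 1"`, `"sub-state 2"`, ...
#' @return Object of class `rna_ensemble`.
#' @export
ensemble <- function(frames, labels = NULL) {
  if (length(frames) < 2) abort("an ensemble needs >= 2 frames")
  if (!all(vapply(frames, inherits, logical(1), "rna_structure"))) {
    abort("all frames must be rna_structure objects")
  }
  labels <- labels %||% paste("sub-state", seq_along(frames))
  if (length(labels) != length(frames) || anyDuplicated(labels)) {
    abort("labels must be unique and aligned to frames")
  }
  structure(list(frames = frames, labels = as.character(labels)),
            class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("<rna_ensemble> %d frames (%s ... %s)\n", length(x$frames),
              x$labels[1], x$labels[length(x$labels)]))
  invisible(x)
}

#' Read an ensemble from per-frame files or a multi-model PDB
#'
#' A directory is read as one PDB file per frame, ordered by natural sort of
#' the file names; a single multi-model PDB is split on its MODEL records.
#'
#' @param path directory of PDB files, or one multi-model PDB file.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) < 2) abort("ensemble directory needs >= 2 coordinate files")
    files <- files[natural_order(basename(files))]
    frames <- lapply(files, read_structure)
    return(ensemble(frames, labels = basename(files)))
  }
  if (!file.exists(path)) abort(paste0("cannot read ensemble from ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) abort("multi-model PDB must contain >= 2 MODEL records")
  ends <- grep("^ENDMDL", lines)
  frames <- lapply(seq_along(starts), function(i) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(lines[(starts[i] + 1):(ends[i] - 1)], "END"), tmp)
    read_structure(tmp, format = "pdb",
                   id = paste0(tools::file_path_sans_ext(basename(path)),
                               "_model", i))
  })
  ensemble(frames, labels = paste("model", seq_along(frames)))
}

natural_order <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("\\D+", "", x)))
  order(is.na(num), num, x)
}

ensemble_common_keys <- function(e, sel = NULL, atoms = NULL) {
  keysets <- lapply(e$frames, function(f) {
    tbl <- if (is.null(sel)) as_tibble(f) else resolve_selection(f, sel)
    if (!is.null(atoms)) tbl <- tbl[tbl$atom %in% atoms, ]
    do.call(paste, c(tbl[, c("chain", "resno", "insert", "atom")], sep = "|"))
  })
  Reduce(intersect, keysets)
}

frame_coords_by_key <- function(f, keys) {
  tbl <- as_tibble(f)
  k <- do.call(paste, c(tbl[, c("chain", "resno", "insert", "atom")], sep = "|"))
  coords(tbl[match(keys, k), ])
}

#' Pairwise RMSD matrix of an ensemble
#'
#' Entry (i, j) is the Kabsch RMSD (no outlier rejection) over the atoms
#' common to all frames under the selection -- the intersection policy copes
#' with sub-state models whose peripheral nucleotides are structured only in
#' some frames.
#'
#' @param e an [ensemble()].
#' @param sel optional [selection()]; `NULL` uses all atoms.
#' @param atoms optional atom-name filter (e.g. `"P"`).
#' @return Symmetric matrix (Angstrom) with zero diagonal, labelled by frame.
#' @export
pairwise_rmsd_matrix <- function(e, sel = NULL, atoms = NULL) {
  stopifnot(inherits(e, "rna_ensemble"))
  keys <- ensemble_common_keys(e, sel, atoms)
  if (length(keys) < 3) {
    abort("fewer than 3 atoms are common to all frames under this selection")
  }
  keys <- sort(keys)
  mats <- lapply(e$frames, frame_coords_by_key, keys = keys)
  n <- length(mats)
  M <- matrix(0, n, n, dimnames = list(e$labels, e$labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- kabsch_superpose(mats[[i]], mats[[j]], reject_cycles = 0L)$rmsd
      M[i, j] <- r; M[j, i] <- r
    }
  }
  M
}

#' Descriptor series over an ensemble
#'
#' Runs [compute_descriptors()] on every frame (best-effort per frame:
#' missing residues are tallied, a frame whose axis fit fails yields a row of
#' `NA`s flagged in `failed`), preserving frame order. On the twenty
#' 3D-variability sub-states of the group II intron constructs this
#' reproduces the progressive opening trends of angle A and the gate
#' distance.
#'
#' @param e an [ensemble()].
#' @param registry a [read_registry()] registry.
#' @param convention angle convention.
#' @return Tibble with one row per frame: `frame`, `label`, the descriptor
#'   columns, and `failed`.
#' @export
descriptor_series <- function(e, registry = default_registry(),
                              convention = c("directed", "undirected")) {
  convention <- match.arg(convention)
  stopifnot(inherits(e, "rna_ensemble"))
  rows <- lapply(seq_along(e$frames), function(i) {
    d <- tryCatch(
      compute_descriptors(e$frames[[i]], registry, convention = convention),
      error = function(err) NULL
    )
    if (is.null(d)) {
      return(tibble(frame = i, label = e$labels[i], failed = TRUE))
    }
    dplyr::bind_cols(tibble(frame = i, label = e$labels[i]),
                     as_tibble(d), tibble(failed = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Tip displacement between two frames
#'
#' Superposes frame `frame_j` onto frame `frame_i` over the anchor subdomain
#' (default the core D1c stem), then reports the per-residue phosphate
#' displacement within the named subdomain and its maximum -- the movement at
#' the helix tip.
#'
#' @param e an [ensemble()].
#' @param frame_i,frame_j frame indices (reference, displaced).
#' @param subdomain registry label of the subdomain to profile.
#' @param registry a [read_registry()] registry.
#' @param anchor registry label of the superposition anchor
#'   (default `"core_d1c"`).
#' @param atom_used displaced atom per residue (default `"P"`).
#' @return Tibble of per-residue displacements with attribute
#'   `max_displacement` (also returned in the `tip` column flagging the
#'   maximum row).
#' @export
tip_displacement <- function(e, frame_i, frame_j, subdomain,
                             registry = default_registry(),
                             anchor = "core_d1c", atom_used = "P") {
  stopifnot(inherits(e, "rna_ensemble"))
  a <- e$frames[[frame_i]]; b <- e$frames[[frame_j]]
  anchor_sel <- registry$subdomains[[anchor]]
  if (is.null(anchor_sel)) abort(paste0("unknown anchor subdomain: ", anchor))
  sub_sel <- registry$subdomains[[subdomain]]
  if (is.null(sub_sel)) abort(paste0("unknown subdomain: ", subdomain))
  sup <- superpose_structures(b, a, sel = anchor_sel, reject_cycles = 0L)
  bb <- sup$structure
  pa <- resolve_selection(a, sub_sel)
  pb <- resolve_selection(bb, sub_sel)
  pair <- common_atoms(pa, pb, atoms = atom_used)
  if (nrow(pair$a) == 0) abort("no common atoms in the profiled subdomain")
  d <- sqrt(rowSums((coords(pair$b) - coords(pair$a))^2))
  out <- tibble(chain = pair$a$chain, resno = pair$a$resno,
                resname = pair$a$resname, displacement = d,
                tip = d == max(d))
  attr(out, "max_displacement") <- max(d)
  out
}

#' Monotonic-trend summary of a per-frame scalar series
#'
#' @param series numeric vector (>= 2 values).
#' @return One-row tibble: `fraction_nondecreasing` (share of adjacent steps
#'   that do not decrease), `min`, `max`, `first`, `last`, `range`.
#' @export
trend_stats <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2) abort("trend statistics need >= 2 frames")
  steps <- diff(series)
  tibble(
    fraction_nondecreasing = mean(steps >= 0),
    min = min(series), max = max(series),
    first = series[1], last = series[length(series)],
    range = max(series) - min(series)
  )
}
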