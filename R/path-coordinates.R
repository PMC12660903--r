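#' Milestone paths for path-progress coordinates
#'
#' A path reference holds an ordered list of N >= 2 milestone coordinate sets
#' (matched atom lists, typically the P atoms of a subdomain) plus the
#' exponential width parameter lambda. Progress along the path is measured by
#'
#' \deqn{s_{path} = \frac{\sum_{i=1}^{N} i\, e^{-\lambda R(X - X_i)}}
#'                       {\sum_{i=1}^{N} e^{-\lambda R(X - X_i)}}}
#' \deqn{z_{path} = -\frac{1}{\lambda}
#'                  \ln\Big[\sum_{i=1}^{N} e^{-\lambda R(X - X_i)}\Big]}
#'
#' where `R(X - X_i)` is the mean-squared (default) or root-mean-squared
#' deviation between `X` and milestone `X_i` after optimal rigid
#' superposition. `spath` runs from 1 at the first milestone to N at the
#' last; `zpath` measures the distance from the path tube and is bounded
#' below by `-ln(N)/lambda`.
#'
#' @param milestones list of n x 3 coordinate matrices with identical atom
#'   count and ordering.
#' @param lambda positive width parameter; units are inverse squared-Angstrom
#'   for the `msd` metric and inverse Angstrom for `rmsd`. `NULL` calibrates
#'   via [calibrate_lambda()].
#' @param metric `"msd"` (default, the convention of the path-collective-
#'   variable method) or `"rmsd"`.
#' @return Object of class `path_reference`.
#' @export
path_reference <- function(milestones, lambda = NULL, metric = c("msd", "rmsd")) {
  metric <- match.arg(metric)
  if (length(milestones) < 2) abort("a path needs >= 2 milestones")
  milestones <- lapply(milestones, as_coord_matrix)
  n_atoms <- vapply(milestones, nrow, integer(1))
  if (length(unique(n_atoms)) != 1) {
    abort("all milestones must have the same atom count and ordering")
  }
  ref <- structure(list(milestones = milestones, lambda = lambda,
                        metric = metric),
                   class = "path_reference")
  if (is.null(lambda)) ref$lambda <- calibrate_lambda(ref)
  if (ref$lambda <= 0) abort("lambda must be positive")
  ref
}

#' @export
print.path_reference <- function(x, ...) {
  cat(sprintf("<path_reference> %d milestones x %d atoms, lambda %.4g (%s)\n",
              length(x$milestones), nrow(x$milestones[[1]]), x$lambda, x$metric))
  invisible(x)
}

#' Distance of a configuration from one milestone
#'
#' Optimal rigid superposition (Kabsch, no outlier rejection) of `x` onto
#' `xi`, then the mean-squared (squared-Angstrom) or root-mean-squared
#' (Angstrom) deviation. Rigid motion of `x` therefore does not contribute.
#'
#' @param x,xi n x 3 coordinate matrices with matching atom order.
#' @param metric `"msd"` or `"rmsd"`.
#' @return Non-negative scalar distance.
#' @export
milestone_distance <- function(x, xi, metric = c("msd", "rmsd")) {
  metric <- match.arg(metric)
  x <- as_coord_matrix(x); xi <- as_coord_matrix(xi)
  if (nrow(x) != nrow(xi)) abort("atom-count mismatch with milestone")
  fit <- kabsch_superpose(x, xi, reject_cycles = 0L)
  if (metric == "msd") fit$rmsd^2 else fit$rmsd
}

#' Path-progress coordinates of a configuration
#'
#' Evaluates `spath` and `zpath` against a [path_reference()]. The sums are
#' computed with a max-shifted exponent (log-sum-exp), so the result is
#' stable even when `lambda * R` is large; `stabilized = FALSE` evaluates the
#' textbook formula directly and exists for cross-checking only.
#'
#' @param x n x 3 coordinate matrix matching the milestone atom layout.
#' @param ref a [path_reference()].
#' @param stabilized use the log-sum-exp evaluation (default TRUE).
#' @return One-row tibble: `spath` (in `[1, N]`), `zpath`, and the list
#'   column `per_milestone_R` holding the N milestone distances.
#' @export
path_coordinates <- function(x, ref, stabilized = TRUE) {
  stopifnot(inherits(ref, "path_reference"))
  if (ref$lambda <= 0) abort("lambda must be positive")
  n <- length(ref$milestones)
  R <- vapply(ref$milestones, function(xi) {
    milestone_distance(x, xi, metric = ref$metric)
  }, numeric(1))
  idx <- seq_len(n)
  if (stabilized) {
    e <- -ref$lambda * R
    m <- max(e)
    w <- exp(e - m)
    spath <- sum(idx * w) / sum(w)
    zpath <- -(m + log(sum(w))) / ref$lambda
  } else {
    w <- exp(-ref$lambda * R)
    spath <- sum(idx * w) / sum(w)
    zpath <- -log(sum(w)) / ref$lambda
  }
  tibble(spath = spath, zpath = zpath, per_milestone_R = list(R))
}

#' Calibrate the path width parameter
#'
#' The standard path-collective-variable heuristic:
#' `lambda = 2.3 / mean(adjacent-milestone distance)`, so that neighbouring
#' milestones overlap by roughly a factor of ten in weight.
#'
#' @param ref a `path_reference` (lambda may be unset).
#' @return Positive lambda in the units of the reference metric.
#' @export
calibrate_lambda <- function(ref) {
  ms <- ref$milestones
  gaps <- vapply(seq_len(length(ms) - 1), function(i) {
    milestone_distance(ms[[i]], ms[[i + 1]], metric = ref$metric)
  }, numeric(1))
  if (any(gaps < 1e-12)) {
    abort("adjacent milestones are identical; cannot calibrate lambda")
  }
  2.3 / mean(gaps)
}

#' Build a milestone path from a conformational ensemble
#'
#' Ranks the frames by RMSD of the selected atoms to the last frame (the
#' wide-open end state), selects `n_milestones` frames evenly spaced along
#' that coordinate, and stores their coordinates after sequential
#' superposition onto the first selected frame.
#'
#' @param e an [ensemble()].
#' @param sel [selection()] defining the milestone atoms (typically P atoms
#'   of a subdomain).
#' @param n_milestones number of milestones, `2 <= n <= length(frames)`.
#' @param lambda optional lambda; `NULL` calibrates.
#' @param metric passed to [path_reference()].
#' @return A [path_reference()]; the chosen frame indices are attached as the
#'   `frame_indices` attribute.
#' @export
build_path_from_ensemble <- function(e, sel, n_milestones, lambda = NULL,
                                     metric = c("msd", "rmsd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(e, "rna_ensemble"))
  n_frames <- length(e$frames)
  if (n_milestones < 2 || n_milestones > n_frames) {
    abort("need ensemble size >= n_milestones >= 2")
  }
  mats <- lapply(e$frames, function(f) coords(resolve_selection(f, sel)))
  n_atoms <- vapply(mats, nrow, integer(1))
  if (length(unique(n_atoms)) != 1) {
    abort("frames do not share a common atom layout under the selection")
  }
  last <- mats[[n_frames]]
  r_to_end <- vapply(mats, function(m) {
    kabsch_superpose(m, last, reject_cycles = 0L)$rmsd
  }, numeric(1))
  targets <- seq(max(r_to_end), min(r_to_end), length.out = n_milestones)
  chosen <- integer(n_milestones)
  remaining <- seq_len(n_frames)
  for (k in seq_len(n_milestones)) {
    j <- remaining[which.min(abs(r_to_end[remaining] - targets[k]))]
    chosen[k] <- j
    remaining <- setdiff(remaining, j)
  }
  # sequential superposition onto the first milestone
  aligned <- vector("list", n_milestones)
  aligned[[1]] <- mats[[chosen[1]]]
  for (k in 2:n_milestones) {
    fit <- kabsch_superpose(mats[[chosen[k]]], aligned[[k - 1]],
                            reject_cycles = 0L)
    aligned[[k]] <- transform_coords(mats[[chosen[k]]], fit$rotation,
                                     fit$translation)
  }
  ref <- path_reference(aligned, lambda = lambda, metric = metric)
  attr(ref, "frame_indices") <- chosen
  attr(ref, "rmsd_to_end") <- r_to_end[chosen]
  ref
}

#' Path coordinates of every frame of an ensemble
#'
#' @param e an [ensemble()].
#' @param sel the [selection()] the path was built with.
#' @param ref a [path_reference()].
#' @return Tibble with one row per frame: `frame`, `label`, `spath`, `zpath`.
#' @export
ensemble_path_coordinates <- function(e, sel, ref) {
  stopifnot(inherits(e, "rna_ensemble"))
  rows <- lapply(seq_along(e$frames), function(i) {
    m <- coords(resolve_selection(e$frames[[i]], sel))
    pc <- path_coordinates(m, ref)
    tibble(frame = i, label = e$labels[i], spath = pc$spath, zpath = pc$zpath)
  })
  dplyr::bind_rows(rows)
}
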