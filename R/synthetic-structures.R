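#' Synthetic idealized RNA duplex
#'
#' Builds an idealized A-form-like duplex: two antiparallel chains whose
#' atoms sit on concentric helical tracks around the z axis (canonical
#' fibre-diffraction defaults: 32.7 degrees twist and 2.81 Angstrom rise per
#' base pair), so that the least-squares helical axis coincides with the
#' construction axis. Every residue carries the full sugar-phosphate backbone
#' set plus C1' and named nucleobase ring pseudo-atoms at a small radial
#' offset, which is all the downstream descriptors consume; the generator
#' makes no claim of atomistic realism beyond that.
#'
#' @param n_bp number of base pairs (>= 4).
#' @param twist helical twist, degrees per base pair.
#' @param rise helical rise, Angstrom per base pair.
#' @param chain chain identifier shared by both strands (intron numbering
#'   lives on one author chain).
#' @param start_seq `c(start1, start2)` author numbers of the two strands'
#'   first pairs; strand 2 runs antiparallel, so the last residue of strand 1
#'   pairs with `start2`.
#' @param sequence optional strand-1 nucleotide names (recycled); strand 2
#'   takes Watson-Crick complements.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed RNG seed for the noise (fixed seed gives identical output).
#' @return An `rna_structure`; the noiseless least-squares axis is attached
#'   as the `construction_axis` attribute (list with `anchor`, `direction`).
#' @export
make_helix <- function(n_bp, twist = 32.7, rise = 2.81, chain = "A",
                       start_seq = c(1L, n_bp + 4L), sequence = NULL,
                       noise_sigma = 0, seed = NULL) {
  if (n_bp < 4) abort("n_bp must be >= 4")
  if (rise <= 0) abort("rise must be positive")
  if (twist <= 0 || twist >= 360) abort("twist must be in (0, 360)")
  sequence <- sequence %||% rep(c("G", "C", "A", "U"), length.out = n_bp)
  sequence <- rep(toupper(sequence), length.out = n_bp)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  seq2 <- unname(comp[sequence])

  bb <- backbone_template()
  rows <- list()
  add_residue <- function(resno, resname, phase_deg, z0, flip) {
    sgn <- if (flip) -1 else 1
    ph <- (phase_deg + sgn * bb$phase) * pi / 180
    pts <- cbind(bb$radius * cos(ph), bb$radius * sin(ph), z0 + sgn * bb$dz)
    ring_names <- base_ring_atoms(resname)
    ctr_ph <- (phase_deg + sgn * (-30)) * pi / 180
    ctr <- c(4.5 * cos(ctr_ph), 4.5 * sin(ctr_ph), z0 + sgn * 1.5)
    e1 <- c(cos(ctr_ph), sin(ctr_ph), 0)
    e2 <- c(0, 0, 1)
    k <- seq_along(ring_names)
    ring <- t(vapply(k, function(j) {
      a <- 2 * pi * (j - 1) / length(ring_names)
      ctr + 1.4 * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
    tibble(
      chain = chain, resno = as.integer(resno), insert = "",
      resname = resname,
      atom = c(bb$atom, ring_names),
      element = substr(c(bb$atom, ring_names), 1, 1),
      x = c(pts[, 1], ring[, 1]),
      y = c(pts[, 2], ring[, 2]),
      z = c(pts[, 3], ring[, 3]),
      occupancy = 1, b = 0
    )
  }
  for (i in seq_len(n_bp)) {
    phase <- (i - 1) * twist
    z0 <- (i - 1) * rise
    rows[[length(rows) + 1]] <-
      add_residue(start_seq[1] + i - 1, sequence[i], phase, z0, flip = FALSE)
    rows[[length(rows) + 1]] <-
      add_residue(start_seq[2] + (n_bp - i), seq2[i], phase + 150, z0,
                  flip = TRUE)
  }
  atoms <- dplyr::bind_rows(rows)
  atoms <- atoms[order(atoms$resno), ]
  atoms$eleno <- seq_len(nrow(atoms))
  s <- new_structure(atoms, id = sprintf("helix_%dbp", n_bp),
                     source_format = "internal")
  sel <- selection(list(range(atoms$resno)), chain = chain)
  ax <- fit_helix_axis(s, sel)
  if (noise_sigma > 0) {
    noisy <- withr::with_seed(seed %||% 1L, {
      coords(s) + matrix(rnorm(3 * nrow(s), sd = noise_sigma), ncol = 3)
    })
    s <- set_coords(s, noisy)
  }
  attr(s, "construction_axis") <- list(anchor = ax$anchor,
                                       direction = ax$direction)
  s
}

backbone_template <- function() {
  list(
    atom   = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'"),
    radius = c(9.4, 10.4, 9.0, 8.9, 9.2, 9.4, 9.7, 9.6, 8.0),
    phase  = c(0, 6, 12, -10, -18, -26, -33, -40, -30),
    dz     = c(0, 0.6, -0.5, 0.3, 0.8, 1.2, 0.5, -0.2, 1.5)
  )
}

rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b); c_ <- sum(a * b)
  if (sum(v^2) < 1e-16) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- cross3(a, p); axis <- axis / sqrt(sum(axis^2))
    return(rotation_about_axis(axis, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_about_axis <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  cth <- cos(angle_rad); sth <- sin(angle_rad); v <- 1 - cth
  matrix(c(
    cth + x * x * v,     x * y * v - z * sth, x * z * v + y * sth,
    y * x * v + z * sth, cth + y * y * v,     y * z * v - x * sth,
    z * x * v - y * sth, z * y * v + x * sth, cth + z * z * v
  ), 3, 3, byrow = TRUE)
}

d1_mimic_helix_plan <- function() {
  list(
    core_d1c       = list(n_bp = 10, start_seq = c(66L, 112L),
                          ranges = list(c(66, 75), c(112, 121)),
                          offset = c(0, 0, 0)),
    # D1d1 strands are unequal in the registry (124-133 vs 230-242): build a
    # 13-bp duplex and trim strand 1 to the registry range
    d1d1           = list(n_bp = 13, start_seq = c(124L, 230L),
                          drop = 134:136,
                          ranges = list(c(124, 133), c(230, 242)),
                          offset = c(-26, -14, 2)),
    peripheral_d1c = list(n_bp = 11, start_seq = c(80L, 92L),
                          ranges = list(c(80, 102)),
                          offset = c(24, 6, 12)),
    i1_i2          = list(n_bp = 18, start_seq = c(6L, 250L),
                          ranges = list(c(6, 23), c(250, 267)),
                          offset = c(4, -30, -8))
  )
}

solve_d1_directions <- function(angles) {
  deg <- pi / 180
  u <- list(core_d1c = c(0, 0, 1))
  if (!is.na(angles["A"])) {
    u$d1d1 <- c(sin(angles["A"] * deg), 0, cos(angles["A"] * deg))
  }
  if (!is.na(angles["B"])) {
    u$peripheral_d1c <- c(0, sin(angles["B"] * deg), cos(angles["B"] * deg))
  }
  if (!is.na(angles["C"])) {
    aC <- angles["C"] * deg
    if (!is.na(angles["A"]) && !is.na(angles["D"])) {
      aA <- angles["A"] * deg; aD <- angles["D"] * deg
      denom <- sin(aA) * sin(aC)
      cphi <- if (abs(denom) < 1e-12) NA_real_
              else (cos(aD) - cos(aA) * cos(aC)) / denom
      if (is.na(cphi) || abs(cphi) > 1 + 1e-9) {
        abort(sprintf(
          "angle set (A=%g, C=%g, D=%g) has no 3D realization",
          angles["A"], angles["C"], angles["D"]))
      }
      phi <- acos(max(-1, min(1, cphi)))
      u$i1_i2 <- c(sin(aC) * cos(phi), sin(aC) * sin(phi), cos(aC))
    } else {
      u$i1_i2 <- c(-sin(aC), 0, cos(aC))
    }
  }
  lapply(u, unname)
}

#' Synthetic multi-helix D1 scaffold mimic
#'
#' Assembles idealized duplexes (one per registered subdomain, carrying the
#' packaged O. iheyensis residue numbering) so that the least-squares helical
#' axes realize the requested inter-axis angles exactly and the C1' gate
#' atoms (residues 75 and 238) sit at the requested separation. Subsets are
#' allowed: passing only `angle_A` builds the two-helix core-D1c/D1d1
#' construct. The returned ground truth makes the construct a recovery oracle
#' for the descriptor pipeline.
#'
#' @param angle_A,angle_B,angle_C,angle_D target inter-axis angles, degrees
#'   in (0, 180); `NA` omits the corresponding helix (B: peripheral D1c,
#'   C/D: i1-i2).
#' @param gate_dist target gate distance, Angstrom.
#' @param noise_sigma isotropic coordinate noise, Angstrom.
#' @param seed RNG seed for the noise.
#' @return List with `structure` (an `rna_structure`), `truth` (one-row
#'   tibble of the construction descriptor values), and `placement`
#'   (per-helix axis directions and hinge point, used by the sweep
#'   generator).
#' @export
make_d1_construct <- function(angle_A = 62.9, angle_B = 30, angle_C = 45,
                              angle_D = 60, gate_dist = 32.0,
                              noise_sigma = 0, seed = NULL) {
  angles <- c(A = angle_A, B = angle_B, C = angle_C, D = angle_D)
  ok <- !is.na(angles)
  if (any(angles[ok] <= 0 | angles[ok] >= 180)) {
    abort("target angles must lie in (0, 180) degrees")
  }
  dirs <- solve_d1_directions(angles)
  plan <- d1_mimic_helix_plan()[names(dirs)]
  placed <- list()
  for (nm in names(plan)) {
    p <- plan[[nm]]
    h <- make_helix(p$n_bp, start_seq = p$start_seq)
    if (!is.null(p$drop)) {
      tbl <- as_tibble(h)
      h <- new_structure(tbl[!(tbl$resno %in% p$drop), ],
                         id = structure_id(h), source_format = "internal")
    }
    # fit the construction axis on exactly the registry selection so the
    # realized inter-axis angles match the requested values
    ax <- fit_helix_axis(h, selection(p$ranges, chain = "A"))
    R <- rotation_between(ax$direction, dirs[[nm]])
    m <- coords(h)
    m <- sweep(m, 2, ax$anchor)            # centre on the fitted axis anchor
    m <- m %*% t(R)
    m <- sweep(m, 2, p$offset, `+`)
    placed[[nm]] <- set_coords(h, m)
  }
  # set the gate distance exactly by translating D1d1 along the gate vector
  if (!is.null(placed$d1d1)) {
    p75 <- gate_atom_xyz(placed$core_d1c, 75)
    p238 <- gate_atom_xyz(placed$d1d1, 238)
    ug <- (p238 - p75) / sqrt(sum((p238 - p75)^2))
    shift <- (p75 + gate_dist * ug) - p238
    placed$d1d1 <- set_coords(placed$d1d1,
                              sweep(coords(placed$d1d1), 2, shift, `+`))
  }
  atoms <- dplyr::bind_rows(lapply(placed, as_tibble))
  atoms$eleno <- seq_len(nrow(atoms))
  s <- new_structure(atoms, id = "synthetic_d1_mimic",
                     source_format = "internal")
  if (noise_sigma > 0) {
    noisy <- withr::with_seed(seed %||% 1L, {
      coords(s) + matrix(rnorm(3 * nrow(s), sd = noise_sigma), ncol = 3)
    })
    s <- set_coords(s, noisy)
  }
  truth <- tibble(angle_A = angle_A, angle_B = angle_B, angle_C = angle_C,
                  angle_D = angle_D, gate_distance = gate_dist)
  hinge_point <- gate_atom_xyz(placed$core_d1c, 75)
  list(structure = s, truth = truth,
       placement = list(directions = dirs, hinge_point = hinge_point))
}

gate_atom_xyz <- function(s, resno, atom = "C1'") {
  tbl <- as_tibble(s)
  hit <- tbl[tbl$resno == resno & tbl$atom == atom, ]
  if (nrow(hit) == 0) abort(sprintf("atom %s of residue %d not found", atom, resno))
  as.numeric(coords(hit)[1, ])
}

#' Linear morph between two conformations
#'
#' Superposes `b` onto `a` over their common atoms (Kabsch, no rejection) and
#' interpolates Cartesian coordinates linearly: frame 1 is `a`, frame
#' `n_frames` is aligned `b`. Both structures must share an identical atom
#' layout.
#'
#' @param a,b `rna_structure` objects with identical atom layouts.
#' @param n_frames number of frames (>= 2).
#' @return An [ensemble()] of `n_frames` structures.
#' @export
make_morph <- function(a, b, n_frames) {
  if (n_frames < 2) abort("a morph needs >= 2 frames")
  key <- function(s) do.call(paste, c(as_tibble(s)[, c("chain", "resno",
                                                       "insert", "atom")],
                                      sep = "|"))
  if (!identical(key(a), key(b))) {
    abort("morph endpoints must have identical atom layouts")
  }
  fit <- kabsch_superpose(coords(b), coords(a), reject_cycles = 0L)
  mb <- transform_coords(coords(b), fit$rotation, fit$translation)
  ma <- coords(a)
  frames <- lapply(seq_len(n_frames), function(k) {
    w <- (k - 1) / (n_frames - 1)
    f <- set_coords(a, (1 - w) * ma + w * mb)
    attr(f, "id") <- sprintf("%s_morph%02d", structure_id(a), k)
    f
  })
  ensemble(frames, labels = paste("frame", seq_len(n_frames)))
}

#' Synthetic sub-state sweep ensemble
#'
#' Emulates an ordered series of conformational sub-states by sweeping one
#' descriptor of the D1 mimic across the given values: for `"angle_A"` the
#' D1d1 helix is rotated about the hinge point (the gate C1' of residue 75)
#' around the axis perpendicular to the core-D1c/D1d1 plane, so the
#' inter-axis angle tracks the requested values exactly; for
#' `"gate_distance"` D1d1 is translated along the gate vector. Ground truth
#' per frame is returned for recovery tests, together with the rigid-lever
#' geometry (hinge point and axis) that fixes the closed-form tip
#' displacement `2 L sin(delta/2)`.
#'
#' @param descriptor `"angle_A"` or `"gate_distance"`.
#' @param values descriptor values, one frame per value.
#' @param noise_sigma per-frame isotropic coordinate noise, Angstrom.
#' @param seed RNG seed for the noise.
#' @param ... base-construct arguments passed to [make_d1_construct()].
#' @return List with `ensemble` (an [ensemble()]), `truth` (tibble of frame
#'   and descriptor value), and `lever` (list: `hinge_point`, `axis`, only
#'   for angle sweeps).
#' @export
make_sweep_ensemble <- function(descriptor = c("angle_A", "gate_distance"),
                                values, noise_sigma = 0, seed = NULL, ...) {
  descriptor <- match.arg(descriptor)
  if (length(values) < 2) abort("a sweep needs >= 2 values")
  base_args <- list(...)
  if (descriptor == "angle_A") base_args$angle_A <- values[1]
  if (descriptor == "gate_distance") base_args$gate_dist <- values[1]
  base <- do.call(make_d1_construct, base_args)
  s0 <- base$structure
  tbl0 <- as_tibble(s0)
  d1d1_rows <- tbl0$resno %in% c(124:133, 230:242)
  lever <- NULL
  frames <- vector("list", length(values))
  for (k in seq_along(values)) {
    m <- coords(s0)
    if (descriptor == "angle_A") {
      u_core <- base$placement$directions$core_d1c
      u_d1d1 <- base$placement$directions$d1d1
      axis <- cross3(u_core, u_d1d1)
      axis <- axis / sqrt(sum(axis^2))
      # rotating D1d1 about this axis changes angle A additively
      delta <- (values[k] - values[1]) * pi / 180
      R <- rotation_about_axis(axis, delta)
      p0 <- base$placement$hinge_point
      sub <- sweep(m[d1d1_rows, , drop = FALSE], 2, p0)
      m[d1d1_rows, ] <- sweep(sub %*% t(R), 2, p0, `+`)
      lever <- list(hinge_point = p0, axis = axis)
    } else {
      p75 <- gate_atom_xyz(s0, 75)
      p238 <- gate_atom_xyz(s0, 238)
      ug <- (p238 - p75) / sqrt(sum((p238 - p75)^2))
      m[d1d1_rows, ] <- sweep(m[d1d1_rows, , drop = FALSE], 2,
                              (values[k] - values[1]) * ug, `+`)
    }
    f <- set_coords(s0, m)
    if (noise_sigma > 0) {
      noisy <- withr::with_seed((seed %||% 1L) + k, {
        coords(f) + matrix(rnorm(3 * nrow(f), sd = noise_sigma), ncol = 3)
      })
      f <- set_coords(f, noisy)
    }
    attr(f, "id") <- sprintf("sweep_%s_%02d", descriptor, k)
    frames[[k]] <- f
  }
  list(
    ensemble = ensemble(frames),
    truth = tibble(frame = seq_along(values), value = as.numeric(values),
                   descriptor = descriptor),
    lever = lever
  )
}

#' Synthetic kinetic data
#'
#' Evaluates the two-step splicing populations or the Michaelis-Menten rate
#' law on a design grid and adds Gaussian noise (fractions are clipped to
#' `[0, 1]`). Deterministic under a fixed seed.
#'
#' @param type `"two_step"` or `"michaelis_menten"`.
#' @param params named list: `k1`, `k2` (and optional `p0`) for
#'   `"two_step"`; `vmax`, `km` for `"michaelis_menten"`.
#' @param design numeric grid: times (minutes) or substrate concentrations.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return A tibble: time course with `precursor`/`intermediate`/`product`
#'   columns, or a rate table with `S` and `v` columns.
#' @export
make_kinetics_data <- function(type = c("two_step", "michaelis_menten"),
                               params, design, noise_sigma = 0, seed = 1L) {
  type <- match.arg(type)
  if (type == "two_step") {
    out <- two_step_populations(params$k1, params$k2, design,
                                p0 = params$p0 %||% 1)
    if (noise_sigma > 0) {
      out <- withr::with_seed(seed, {
        for (col in c("precursor", "intermediate", "product")) {
          out[[col]] <- pmin(1, pmax(0, out[[col]] +
                                        rnorm(nrow(out), sd = noise_sigma)))
        }
        out
      })
    }
    out
  } else {
    if (params$vmax <= 0 || params$km <= 0) abort("vmax and km must be positive")
    v <- params$vmax * design / (params$km + design)
    if (noise_sigma > 0) {
      v <- withr::with_seed(seed, pmax(0, v + rnorm(length(v),
                                                    sd = noise_sigma)))
    }
    tibble(S = as.numeric(design), v = v)
  }
}
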