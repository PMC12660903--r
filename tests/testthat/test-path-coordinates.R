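random_conformation <- function(n = 15, sd = 4) {
  matrix(rnorm(3 * n, sd = sd), ncol = 3)
}

test_that("milestone distance removes rigid motion and matches the superpose RMSD", {
  set.seed(31)
  x <- random_conformation()
  expect_equal(milestone_distance(x, x), 0, tolerance = 1e-12)
  xr <- sweep(x %*% t(random_rotation()), 2, rnorm(3, sd = 10), `+`)
  expect_lt(milestone_distance(xr, x), 1e-9)
  y <- random_conformation()
  r <- kabsch_superpose(x, y, reject_cycles = 0L)$rmsd
  expect_equal(milestone_distance(x, y, metric = "msd"), r^2, tolerance = 1e-9)
  expect_equal(milestone_distance(x, y, metric = "rmsd"), r, tolerance = 1e-9)
  expect_error(milestone_distance(x, y[1:5, ]), "mismatch")
})

test_that("path coordinates hit the limiting values at the endpoints", {
  set.seed(32)
  base <- random_conformation()
  target <- base + matrix(rnorm(length(base), sd = 3), ncol = 3)
  n <- 20
  ms <- lapply(seq_len(n), function(k) {
    w <- (k - 1) / (n - 1)
    (1 - w) * base + w * target
  })
  # limit case needs lambda * gap >> 1: use a width well above the calibrated one
  gaps <- vapply(seq_len(n - 1), function(i) {
    milestone_distance(ms[[i]], ms[[i + 1]])
  }, numeric(1))
  ref <- path_reference(ms, lambda = 8 / mean(gaps))
  at1 <- path_coordinates(ms[[1]], ref)
  atN <- path_coordinates(ms[[n]], ref)
  expect_equal(at1$spath, 1, tolerance = 0.05)
  expect_equal(atN$spath, n, tolerance = 0.05)
  expect_lte(at1$zpath, 1e-9)
  expect_gte(at1$zpath, -log(n) / ref$lambda)
  expect_equal(length(at1$per_milestone_R[[1]]), n)
})

test_that("equidistant configurations land exactly mid-path by symmetry", {
  # milestones on a circle, probe at the centre: equal R to every milestone
  n <- 8
  ms <- lapply(seq_len(n), function(k) {
    matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  })
  probe <- matrix(c(0, 0, 0.5, 1, 0, 0.5, 0, 1, 0.5), ncol = 3, byrow = TRUE)
  ref <- path_reference(ms, lambda = 1.7)
  pc <- path_coordinates(probe, ref)
  expect_equal(pc$spath, (n + 1) / 2, tolerance = 1e-9)
})

test_that("stabilized evaluation equals the naive textbook formula", {
  set.seed(33)
  base <- random_conformation()
  ms <- lapply(1:12, function(k) base + k * 0.4)
  # note: pure translations collapse under alignment; add shape change
  ms <- lapply(1:12, function(k) {
    base + matrix(rnorm(length(base), sd = 0.15 * k), ncol = 3)
  })
  ref <- path_reference(ms)
  for (rep in 1:10) {
    x <- base + matrix(rnorm(length(base), sd = runif(1, 0.1, 2)), ncol = 3)
    stab <- path_coordinates(x, ref, stabilized = TRUE)
    naive <- path_coordinates(x, ref, stabilized = FALSE)
    expect_equal(stab$spath, naive$spath, tolerance = 1e-9)
    expect_equal(stab$zpath, naive$zpath, tolerance = 1e-9)
    oracle <- path_oracle(stab$per_milestone_R[[1]], ref$lambda)
    expect_equal(stab$spath, oracle$spath, tolerance = 1e-9)
    expect_equal(stab$zpath, oracle$zpath, tolerance = 1e-9)
  }
})

test_that("spath and zpath respect their bounds for arbitrary inputs", {
  set.seed(34)
  base <- random_conformation()
  ms <- lapply(1:10, function(k) {
    base + matrix(rnorm(length(base), sd = 0.3 * k), ncol = 3)
  })
  ref <- path_reference(ms)
  for (rep in 1:25) {
    x <- random_conformation(sd = runif(1, 1, 8))
    pc <- path_coordinates(x, ref)
    expect_gte(pc$spath, 1)
    expect_lte(pc$spath, 10)
    expect_gte(pc$zpath, -log(10) / ref$lambda)
  }
  # far from the path the exponents underflow naively; stabilized still works
  far <- random_conformation(sd = 500)
  pc <- path_coordinates(far, ref)
  expect_true(is.finite(pc$spath) && is.finite(pc$zpath))
  expect_gte(pc$spath, 1); expect_lte(pc$spath, 10)
})

test_that("lambda calibration follows the 2.3 / mean-gap heuristic", {
  base <- random_conformation()
  shift <- matrix(rnorm(length(base)), ncol = 3)
  ms <- lapply(0:5, function(k) base + sqrt(k) * shift)
  ref_unset <- structure(list(milestones = lapply(ms, rnagate:::as_coord_matrix),
                              lambda = NULL, metric = "msd"),
                         class = "path_reference")
  gaps <- vapply(1:5, function(i) milestone_distance(ms[[i]], ms[[i + 1]]),
                 numeric(1))
  expect_equal(calibrate_lambda(ref_unset), 2.3 / mean(gaps), tolerance = 1e-9)
  # identical adjacent milestones cannot be calibrated
  ms_dup <- list(base, base, base + 1)
  ref_dup <- structure(list(milestones = ms_dup, lambda = NULL, metric = "msd"),
                       class = "path_reference")
  expect_error(calibrate_lambda(ref_dup), "identical")
  expect_error(path_reference(ms, lambda = -1), "positive")
})

test_that("calibrated milestones self-index: milestone k maps to spath near k", {
  cons <- make_d1_construct(angle_A = 62.9)
  sweep20 <- make_sweep_ensemble("angle_A",
                                 values = seq(62.9, 80.5, length.out = 20))
  sel <- selection(list(c(66, 75), c(112, 121), c(124, 133), c(230, 242)),
                   atoms = "P")
  ref <- build_path_from_ensemble(sweep20$ensemble, sel, 20)
  for (k in c(1, 5, 10, 15, 20)) {
    pc <- path_coordinates(ref$milestones[[k]], ref)
    expect_equal(pc$spath, k, tolerance = 0.25)
  }
})

test_that("milestone selection spaces frames evenly along the end-state RMSD", {
  a <- make_d1_construct(angle_A = 62.9)$structure
  b <- make_sweep_ensemble("angle_A", c(62.9, 80.5))$ensemble$frames[[2]]
  morph <- make_morph(a, b, 100)
  sel <- selection(list(c(66, 75), c(112, 121), c(124, 133), c(230, 242)),
                   atoms = "P")
  ref <- build_path_from_ensemble(morph, sel, 20)
  r <- attr(ref, "rmsd_to_end")
  gaps <- abs(diff(r))
  expect_lt(max(gaps) - min(gaps), 0.05 * max(r))
  # boundary cases: n = 2 picks the endpoints; n = size keeps every frame
  ref2 <- build_path_from_ensemble(morph, sel, 2)
  expect_equal(sort(attr(ref2, "frame_indices")), c(1L, 100L))
  small <- make_morph(a, b, 5)
  ref_all <- build_path_from_ensemble(small, sel, 5)
  expect_equal(attr(ref_all, "frame_indices"), 1:5)
})

test_that("spath is monotone along a noiseless morph", {
  a <- make_d1_construct(angle_A = 62.9)$structure
  b <- make_sweep_ensemble("angle_A", c(62.9, 80.5))$ensemble$frames[[2]]
  morph <- make_morph(a, b, 30)
  sel <- selection(list(c(66, 75), c(112, 121), c(124, 133), c(230, 242)),
                   atoms = "P")
  ref <- build_path_from_ensemble(morph, sel, 10)
  pc <- ensemble_path_coordinates(morph, sel, ref)
  expect_true(all(diff(pc$spath) >= -1e-9))
  # rigid transformation of a probe frame does not change its coordinates
  probe <- coords(resolve_selection(morph$frames[[17]], sel))
  pc0 <- path_coordinates(probe, ref)
  set.seed(35)
  probe_r <- sweep(probe %*% t(random_rotation()), 2, rnorm(3, sd = 30), `+`)
  pc1 <- path_coordinates(probe_r, ref)
  expect_equal(pc1$spath, pc0$spath, tolerance = 1e-6)
  expect_equal(pc1$zpath, pc0$zpath, tolerance = 1e-6)
})
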