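test_that("the fitted axis of an ideal helix lies along the construction axis", {
  h <- make_helix(22)
  ax <- fit_helix_axis(h, selection(list(c(1, 22), c(26, 47))))
  dev <- acos(min(1, abs(ax$direction[3]))) * 180 / pi
  expect_lt(dev, 1)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  expect_gt(ax$residual_rms, 0)
  # 5'->3' rule: strand 1 ascends +z, so the axis points up
  expect_gt(ax$direction[3], 0)
})

test_that("axis fitting is equivariant under rigid rotation", {
  h <- make_helix(22)
  sel <- selection(list(c(1, 22), c(26, 47)))
  ax0 <- fit_helix_axis(h, sel)
  set.seed(7)
  for (rep in 1:5) {
    R <- random_rotation()
    hr <- transform_coords(h, R, rnorm(3, sd = 20))
    axr <- fit_helix_axis(hr, sel)
    expect_equal(axr$direction, as.numeric(R %*% ax0$direction),
                 tolerance = 1e-6)
    expect_equal(axr$residual_rms, ax0$residual_rms, tolerance = 1e-9)
  }
})

test_that("axis fit equals the numerical total-least-squares oracle on random clouds", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    d0 <- rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
    tpar <- seq(-10, 10, length.out = n)
    M <- outer(tpar, d0) + matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
    s <- new_structure(tibble::tibble(
      chain = "A", resno = seq_len(n), insert = "", resname = "G",
      atom = "P", element = "P",
      x = M[, 1], y = M[, 2], z = M[, 3], occupancy = 1, b = 0
    ))
    ax <- fit_helix_axis(s, selection(c(1, n)), atom_set = NULL)
    oracle <- tls_line_oracle(M)
    expect_gt(abs(sum(ax$direction * oracle$direction)), 1 - 1e-6)
    expect_equal(nrow(M) * ax$residual_rms^2, oracle$rss, tolerance = 1e-6)
  }
})

test_that("too few atoms or a degenerate cloud are reported", {
  s <- new_structure(tibble::tibble(
    chain = "A", resno = 1:5, insert = "", resname = "G", atom = "P",
    element = "P", x = 1:5, y = 0, z = 0, occupancy = 1, b = 0
  ))
  expect_error(fit_helix_axis(s, selection(c(1, 5)), atom_set = NULL),
               ">= 6 atoms")
  # planar ring: the two largest cloud variances coincide
  th <- 2 * pi * (0:7) / 8
  sym <- new_structure(tibble::tibble(
    chain = "A", resno = 1:8, insert = "", resname = "G", atom = "P",
    element = "P",
    x = cos(th), y = sin(th), z = 0, occupancy = 1, b = 0
  ))
  expect_warning(ax <- fit_helix_axis(sym, selection(c(1, 8)), atom_set = NULL),
                 "ambiguous")
  expect_true(ax$ambiguous)
})

test_that("inter-axis angles follow both conventions", {
  z <- c(0, 0, 1)
  expect_equal(angle_between_axes(z, z)$angle, 0)
  expect_equal(angle_between_axes(z, c(1, 0, 0))$angle, 90)
  a <- angle_between_axes(z, c(sin(2), 0, cos(2)))  # 114.6 degrees directed
  expect_equal(a$directed, 2 * 180 / pi, tolerance = 1e-9)
  expect_equal(a$undirected, 180 - 2 * 180 / pi, tolerance = 1e-9)
  expect_equal(angle_between_axes(z, z, convention = "undirected")$angle, 0)
})

test_that("a two-helix construct built at 57 degrees is recovered", {
  cons <- make_d1_construct(angle_A = 57, angle_B = NA, angle_C = NA,
                            angle_D = NA)
  reg <- default_registry()
  ax1 <- fit_helix_axis(cons$structure, reg$subdomains$core_d1c)
  ax2 <- fit_helix_axis(cons$structure, reg$subdomains$d1d1)
  expect_equal(angle_between_axes(ax1, ax2)$directed, 57, tolerance = 1)
})

test_that("gate distance is a plain interatomic distance, rigid-invariant", {
  s <- new_structure(tibble::tibble(
    chain = "A", resno = c(75L, 238L), insert = "", resname = c("G", "U"),
    atom = "C1'", element = "C",
    x = 0, y = 0, z = c(0, 32), occupancy = 1, b = 0
  ))
  expect_equal(gate_distance(s), 32)
  set.seed(9)
  sr <- transform_coords(s, random_rotation(), rnorm(3, sd = 50))
  expect_equal(gate_distance(sr), 32, tolerance = 1e-9)
  s_missing <- s[s$resno != 238, ]
  class(s_missing) <- class(s)
  expect_error(gate_distance(s_missing), "238")
})

test_that("radius of gyration matches closed forms and the direct formula", {
  two <- new_structure(tibble::tibble(
    chain = "A", resno = 1:2, insert = "", resname = "G", atom = "P",
    element = "P", x = c(0, 2), y = 0, z = 0, occupancy = 1, b = 0
  ))
  expect_equal(radius_of_gyration(two), 1.0)
  # uniform ring of radius r -> Rg converges to r
  r <- 7.5; n <- 500
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- new_structure(tibble::tibble(
    chain = "A", resno = seq_len(n), insert = "", resname = "G", atom = "P",
    element = "P", x = r * cos(th), y = r * sin(th), z = 0,
    occupancy = 1, b = 0
  ))
  expect_equal(radius_of_gyration(ring), r, tolerance = 1e-6)
  set.seed(10)
  M <- matrix(rnorm(90), ncol = 3)
  cloud <- new_structure(tibble::tibble(
    chain = "A", resno = 1:30, insert = "", resname = "G", atom = "P",
    element = "P", x = M[, 1], y = M[, 2], z = M[, 3], occupancy = 1, b = 0
  ))
  direct <- sqrt(mean(rowSums(sweep(M, 2, colMeans(M))^2)))
  expect_equal(radius_of_gyration(cloud), direct, tolerance = 1e-9)
})

test_that("the full descriptor set is recovered on a four-helix construct", {
  cons <- make_d1_construct(angle_A = 62.9, angle_B = 30, angle_C = 45,
                            angle_D = 60, gate_dist = 32.0)
  d <- compute_descriptors(cons$structure)
  expect_equal(d$angle_A, 62.9, tolerance = 1)
  expect_equal(d$angle_B, 30, tolerance = 1)
  expect_equal(d$angle_C, 45, tolerance = 1)
  expect_equal(d$angle_D, 60, tolerance = 1)
  expect_equal(d$gate_distance, 32.0, tolerance = 0.01)
  expect_gt(d$rg, 0)
})

test_that("descriptors are invariant under rigid transforms and atom order", {
  cons <- make_d1_construct()
  s <- cons$structure
  d0 <- compute_descriptors(s)
  set.seed(11)
  sr <- transform_coords(s, random_rotation(), rnorm(3, sd = 30))
  dr <- compute_descriptors(sr)
  num <- vapply(d0, is.numeric, logical(1))
  expect_equal(as.numeric(dr[1, num]), as.numeric(d0[1, num]),
               tolerance = 1e-6)
  # permute atoms within residues
  perm <- s[sample(nrow(s)), ]
  perm <- perm[order(perm$chain, perm$resno, perm$insert), ]
  class(perm) <- class(s)
  dp <- compute_descriptors(perm)
  expect_equal(as.numeric(dp[1, num]), as.numeric(d0[1, num]),
               tolerance = 1e-6)
})

test_that("noisy constructs across the printed angle range recover within 2 degrees", {
  angles <- c(30, 57, 62.9, 80.5, 90)
  for (i in seq_along(angles)) {
    cons <- make_d1_construct(angle_A = angles[i], angle_B = NA,
                              angle_C = NA, angle_D = NA,
                              noise_sigma = 0.5, seed = 100 + i)
    reg <- default_registry()
    ax1 <- fit_helix_axis(cons$structure, reg$subdomains$core_d1c)
    ax2 <- fit_helix_axis(cons$structure, reg$subdomains$d1d1)
    expect_equal(angle_between_axes(ax1, ax2)$directed, angles[i],
                 tolerance = 2)
  }
})
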