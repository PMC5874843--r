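# Interaction energies, orientation sampling, screening and inclusion
# classification.

test_that("interaction energy matches analytic limits", {
  m <- lj_only_model(sigma = 3.4, epsilon = 0.1)
  a <- molecule("C", rbind(c(0, 0, 0)))
  # far-separated fragments do not interact
  b_far <- molecule("C", rbind(c(1e6, 0, 0)))
  expect_lt(abs(interaction_energy(a, b_far, m)), 1e-9)
  # LJ minimum at 2^(1/6) sigma is exactly -epsilon
  b_min <- molecule("C", rbind(c(2^(1 / 6) * 3.4, 0, 0)))
  expect_equal(interaction_energy(a, b_min, m), -0.1, tolerance = 1e-12)
  # pure Coulomb at 10 A with unit charges is -k_e / 10
  mq <- null_model()
  ap <- molecule("C", rbind(c(0, 0, 0)), charge = 1)
  bm <- molecule("C", rbind(c(10, 0, 0)), charge = -1)
  expect_equal(interaction_energy(ap, bm, mq), -33.20636, tolerance = 1e-9)
  # empty system has zero energy
  expect_equal(total_energy(m, list()), 0)
})

test_that("supermolecular energy equals the inter-fragment pair sum for rigid poses", {
  m <- energy_model()
  host <- make_toy_host()
  guest <- make_rod_guest(6)
  poses <- sample_orientations(host, guest, 50, shell = c(10, 30), seed = 21)
  for (i in seq_len(50)) {
    g <- apply_pose(guest, poses, i, centroid(host))
    expect_lt(abs(interaction_energy(host, g, m) - cross_energy(host, g, m)),
              1e-9)
  }
})

test_that("interaction energy is invariant under joint rigid motion", {
  m <- energy_model()
  host <- make_toy_host()
  guest <- apply_pose(make_rod_guest(6),
                      sample_orientations(make_toy_host(), make_rod_guest(6),
                                          1, seed = 2), 1, centroid(host))
  e0 <- interaction_energy(host, guest, m)
  set.seed(31)
  for (rep in 1:5) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 20)
    h2 <- transform_molecule(host, R, t, about = c(0, 0, 0))
    g2 <- transform_molecule(guest, R, t, about = c(0, 0, 0))
    expect_equal(interaction_energy(h2, g2, m), e0, tolerance = 1e-8)
  }
})

test_that("orientation sampling is seeded, shell-bounded and SO(3)-uniform", {
  host <- make_toy_host(); guest <- make_rod_guest(6)
  expect_length(sample_orientations(host, guest, 0, seed = 1), 0L)
  p1 <- sample_orientations(host, guest, 100, seed = 5)
  p2 <- sample_orientations(host, guest, 100, seed = 5)
  expect_identical(p1, p2)
  expect_error(sample_orientations(host, guest, 10, shell = c(5, 2)), "shell")
  ps <- sample_orientations(host, guest, 2000, shell = c(3, 8), seed = 6)
  r <- sqrt(rowSums(ps$t^2))
  expect_true(all(r >= 3 - 1e-9 & r <= 8 + 1e-9))
  # Haar-uniform rotations: E[trace R] = 0 (checked against direct averaging)
  tr <- 3 - 4 * rowSums(ps$q[, 1:3]^2)
  se <- stats::sd(tr) / sqrt(length(tr))
  expect_lt(abs(mean(tr)), 3 * se + 1e-12)
  # quaternions normalized
  expect_lt(max(abs(rowSums(ps$q^2) - 1)), 1e-12)
})

test_that("screen statistics and lowest-k selection follow the contract", {
  host <- make_toy_host(); guest <- make_rod_guest(6)
  s0 <- screen(host, guest, null_model(), n = 25, k = 5, seed = 7)
  expect_equal(s0$mean, 0)
  expect_equal(s0$se, 0)
  s <- screen(host, guest, lj_only_model(), n = 40, k = 40, seed = 8)
  expect_equal(s$lowest$energy, sort(s$energies))
  expect_equal(s$mean, mean(s$energies))
  expect_equal(s$se, stats::sd(s$energies) / sqrt(40))
  # ties broken by pose index: constant model keeps original order
  expect_equal(s0$lowest$pose, 1:5)
})

test_that("screen standard error halves when the pose budget quadruples", {
  host <- make_toy_host(); guest <- make_rod_guest(4)
  m <- lj_only_model()
  # clash-free shell: capped steric outliers would dominate the variance
  s1 <- screen(host, guest, m, n = 2000, k = 0, shell = c(10, 20), seed = 9)
  s2 <- screen(host, guest, m, n = 8000, k = 0, shell = c(10, 20), seed = 10)
  expect_equal(s2$se / s1$se, 0.5, tolerance = 0.35)
})

test_that("inclusion classification distinguishes A, B and none", {
  fr <- cavity_frame(c(0, 0, 0), c(0, 0, 1), rim_radius = 5)
  rod <- make_rod_guest(5)
  markers <- attr(rod, "markers")
  outside <- rod
  outside$coords <- sweep(outside$coords, 2, c(50, 0, 0), "+")
  expect_equal(classify_inclusion(fr, outside, markers), "none")
  # end_A deeper (+2) than end_B (-3) along the axis
  upright <- rod
  upright$coords <- cbind(0, 0, seq(-3, 2, length.out = nrow(rod$coords)))
  upright$coords <- upright$coords[rev(seq_len(nrow(upright$coords))), ]
  expect_equal(classify_inclusion(fr, upright, markers), "A")
  mirrored <- upright
  mirrored$coords[, 3] <- -mirrored$coords[, 3]
  expect_equal(classify_inclusion(fr, mirrored, markers), "B")
  expect_error(cavity_frame(c(0, 0, 0), c(0, 0, 0), 5), "degenerate")
  expect_error(classify_inclusion(fr, upright, list(end_A = 1L, end_B = 1L)),
               "disjoint")
})

test_that("inclusion labels are invariant under joint rigid motion", {
  rod <- make_rod_guest(5)
  markers <- attr(rod, "markers")
  rod$coords <- cbind(0.5, 0, seq(2.5, -2.5, length.out = nrow(rod$coords)))
  set.seed(77)
  for (rep in 1:10) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 15)
    fr <- cavity_frame(drop(R %*% c(0, 0, 0)) + t, drop(R %*% c(0, 0, 1)), 5)
    g <- rod
    g$coords <- sweep(rod$coords %*% t(R), 2, t, "+")
    expect_equal(classify_inclusion(fr, g, markers), "A")
  }
})

test_that("candidate ranking orders by mean interaction energy", {
  host <- make_toy_host()
  base <- make_rod_guest(6)
  # augmenting a candidate with a purely repulsive site worsens its rank
  rep_site <- molecule("C", rbind(c(0, 2, 0)), charge = 0)
  rep_model <- energy_model(lj = data.frame(element = "C", sigma = 3.4,
                                            epsilon = 0))  # LJ off
  augmented <- combine_molecules(base, rep_site, name = "augmented")
  augmented$charge <- c(rep(1, n_atoms(base)), 1)   # like charges repel the host
  host_q <- host; host_q$charge <- rep(1, n_atoms(host))
  base_q <- base; base_q$charge <- rep(1, n_atoms(base))
  tab <- rank_candidates(list(plain = base_q, augmented = augmented), host_q,
                         rep_model, n = 300, seed = 12)
  expect_equal(tab$name, c("plain", "augmented"))
  expect_lt(tab$mean[1], tab$mean[2])
  # single candidate ranks first; identical candidates tie under one seed
  one <- rank_candidates(list(only = base), host, n = 50, seed = 3)
  expect_equal(one$id, 1L)
  two <- rank_candidates(list(a = base, b = base), host, n = 50, seed = 3)
  expect_equal(two$mean[1], two$mean[2])
  expect_error(rank_candidates(list(), host), "empty")
})
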