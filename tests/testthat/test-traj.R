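# Structural observables: RGYR, SASA, water/guest counting, hydrogen
# bonds, series and block averaging.

test_that("radius of gyration matches analytic and brute-force values", {
  f1 <- gel_frame(rbind(c(3, -2, 7)), "gel")
  expect_equal(radius_of_gyration(f1), 0)
  f2 <- gel_frame(rbind(c(5, 0, 0), c(-5, 0, 0)), "gel")
  expect_equal(radius_of_gyration(f2), 5)
  set.seed(42)
  x <- matrix(stats::rnorm(300, sd = 4), ncol = 3)
  m <- stats::runif(100, 0.5, 16)
  f3 <- gel_frame(x, "gel", masses = m)
  cm <- colSums(x * m) / sum(m)
  brute <- sqrt(sum(m * rowSums(sweep(x, 2, cm)^2)) / sum(m))
  expect_equal(radius_of_gyration(f3), brute, tolerance = 1e-10)
  expect_error(radius_of_gyration(f3, integer(0)), "empty")
})

test_that("SASA matches the analytic sphere, is additive when disjoint, and converges", {
  one <- gel_frame(rbind(c(0, 0, 0)), "gel", radii = 1.9)
  analytic <- 4 * pi * 3.3^2
  expect_equal(sasa(one, probe = 1.4, n_points = 960), analytic,
               tolerance = 0.005 * analytic)
  two_far <- gel_frame(rbind(c(0, 0, 0), c(100, 0, 0)), "gel", radii = 1.9)
  expect_equal(sasa(two_far), 2 * analytic, tolerance = 0.005 * 2 * analytic)
  # doubling the lattice moves the overlapping-pair estimate < 0.5%
  pair <- gel_frame(rbind(c(0, 0, 0), c(3, 0, 0)), "gel", radii = 1.9)
  a960 <- sasa(pair, n_points = 960)
  a1920 <- sasa(pair, n_points = 1920)
  expect_lt(abs(a1920 - a960) / a960, 0.005)
})

test_that("overlapping-pair SASA agrees with a dense Monte-Carlo oracle", {
  r <- 1.9 + 1.4
  centers <- rbind(c(0, 0, 0), c(3, 0, 0))
  set.seed(7)
  # MC oracle: accessible fraction of each inflated sphere
  n_mc <- 5e5
  oracle <- 0
  for (i in 1:2) {
    u <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r, 2, centers[i, ], "+")
    other <- centers[3 - i, ]
    acc <- rowSums(sweep(p, 2, other)^2) >= r^2
    oracle <- oracle + mean(acc) * 4 * pi * r^2
  }
  pair <- gel_frame(centers, "gel", radii = 1.9)
  expect_equal(sasa(pair, n_points = 960), oracle, tolerance = 0.01 * oracle)
})

test_that("water counting combines the surface shell and the flood-fill interior", {
  # small gel cluster with one near water, one far water
  gel <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2), ncol = 3, byrow = TRUE)
  waters <- rbind(c(0, 0, -2.9), c(50, 0, 0))
  f <- gel_frame(rbind(gel, waters), c(rep("gel", 4), rep("water", 2)),
                 elements = c(rep("C", 4), "O", "O"))
  expect_equal(count_waters_in_gel(f, shell = 3), 1L)
  expect_equal(count_waters_in_gel(f, shell = 0.5), 0L)
  # hollow shell: interior waters count even when far from the wall
  tr <- make_trajectory(n_frames = 1, n_waters_inside = 7, n_waters_outside = 5,
                        n_guests_captured = 0, n_guests_free = 0, seed = 11)
  expect_equal(count_waters_in_gel(tr$frames[[1]]), 7L)
  # monotone non-decreasing in the shell distance
  counts <- vapply(c(0.5, 1, 3, 6, 12), function(s) {
    as.integer(count_waters_in_gel(f, shell = s))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_waters_in_gel(gel_frame(waters, "water")), "gel")
})

test_that("guest capture brackets the contact threshold", {
  gel <- rbind(c(0, 0, 0))
  near <- rbind(c(4.4, 0, 0))
  far <- rbind(c(4.6, 0, 0))
  f_near <- gel_frame(rbind(gel, near), c("gel", "guest_1"))
  f_far <- gel_frame(rbind(gel, far), c("gel", "guest_1"))
  expect_equal(count_captured_guests(f_near), 1L)
  expect_equal(count_captured_guests(f_far), 0L)
  expect_equal(count_captured_guests(gel_frame(gel, "gel")), 0L)
  # monotone non-decreasing in contact distance
  counts <- vapply(c(2, 4.4, 4.6, 10), function(ct) {
    as.integer(count_captured_guests(f_far, contact = ct))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("persistence filtering over a trajectory is non-increasing", {
  # guest 1 always in contact; guest 2 alternates
  frames <- lapply(1:6, function(i) {
    g2 <- if (i %% 2 == 0) c(20, 0, 0) else c(3, 0, 0)
    gel_frame(rbind(c(0, 0, 0), c(2, 0, 0), g2),
              c("gel", "guest_1", "guest_2"), time = i)
  })
  tr <- gel_trajectory(frames)
  c1 <- count_captured_guests(tr, persistence = 1)
  c2 <- count_captured_guests(tr, persistence = 2)
  c3 <- count_captured_guests(tr, persistence = 3)
  expect_equal(c1, c(2L, 1L, 2L, 1L, 2L, 1L))
  expect_true(all(c2 <= c1) && all(c3 <= c2))
  expect_equal(c3, c(0L, 0L, 1L, 1L, 1L, 1L))
})

test_that("hydrogen bonds respect the distance and angle criteria", {
  # ideal linear O-H...O at 2.8 A donor-acceptor distance
  f <- gel_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0)),
                 c("gel", "gel", "guest_1"), elements = c("O", "H", "O"))
  expect_equal(count_hbonds(f, cbind(1L, 2L), 3L), 1L)
  # bent to 90 degrees at the hydrogen fails the angle cut
  f90 <- gel_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 2.0, 0)),
                   c("gel", "gel", "guest_1"), elements = c("O", "H", "O"))
  expect_equal(count_hbonds(f90, cbind(1L, 2L), 3L), 0L)
  # beyond d_max fails even when linear
  ffar <- gel_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), c(3.8, 0, 0)),
                    c("gel", "gel", "guest_1"), elements = c("O", "H", "O"))
  expect_equal(count_hbonds(ffar, cbind(1L, 2L), 3L), 0L)
  # same-component pairs never count
  fsame <- gel_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0)),
                     c("gel", "gel", "gel"), elements = c("O", "H", "O"))
  expect_equal(count_hbonds(fsame, cbind(1L, 2L), 3L), 0L)
})

test_that("a constructed donor lattice yields exactly its valid bond count", {
  # k donors pointing at acceptors 2.8 A away, plus k decoys at 6 A
  k <- 4L
  donors <- NULL; coords <- NULL; tags <- character(0); elements <- character(0)
  acceptors <- integer(0)
  for (i in seq_len(k)) {
    base <- c(0, 0, 10 * i)
    coords <- rbind(coords, base, base + c(0.96, 0, 0), base + c(2.8, 0, 0),
                    base + c(6, 0, 0))
    donors <- rbind(donors, c(nrow(coords) - 3L, nrow(coords) - 2L))
    acceptors <- c(acceptors, nrow(coords) - 1L, nrow(coords))
    tags <- c(tags, "gel", "gel", "guest_1", "guest_1")
    elements <- c(elements, "O", "H", "O", "O")
  }
  f <- gel_frame(coords, tags, elements = elements)
  # brute-force oracle over all donor-acceptor pairs
  brute <- 0L
  for (d in seq_len(nrow(donors))) for (a in acceptors) {
    D <- coords[donors[d, 1], ]; H <- coords[donors[d, 2], ]; A <- coords[a, ]
    if (sqrt(sum((D - A)^2)) > 3.5) next
    ang <- acos(sum((D - H) * (A - H)) /
                  (sqrt(sum((D - H)^2)) * sqrt(sum((A - H)^2)))) * 180 / pi
    if (ang >= 150) brute <- brute + 1L
  }
  expect_equal(brute, k)
  expect_equal(count_hbonds(f, donors, acceptors), brute)
})

test_that("observables are invariant under global rigid motion", {
  tr <- make_trajectory(n_frames = 1, seed = 13)
  f <- tr$frames[[1]]
  r0 <- radius_of_gyration(f)
  s0 <- sasa(f, selection = "gel", n_points = 960)
  w0 <- count_waters_in_gel(f)
  g0 <- count_captured_guests(f)
  set.seed(99)
  for (rep in 1:3) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 30)
    f2 <- f
    f2$coords <- sweep(f$coords %*% t(R), 2, t, "+")
    expect_equal(radius_of_gyration(f2), r0, tolerance = 1e-10)
    # SASA is lattice-discretized, so rigid-motion invariance holds to the
    # lattice resolution, not machine precision
    expect_equal(sasa(f2, selection = "gel", n_points = 960), s0,
                 tolerance = 0.01)
    expect_equal(count_waters_in_gel(f2), w0)
    expect_equal(count_captured_guests(f2), g0)
  }
})

test_that("series evaluation and block averaging follow the contracts", {
  frames <- lapply(1:8, function(i) {
    gel_frame(rbind(c(0, 0, 0), c(ifelse(i %% 2 == 0, 4, 2), 0, 0)),
              c("gel", "guest_1"), time = i)
  })
  tr <- gel_trajectory(frames)
  ser <- observable_series(tr, "captures")
  expect_equal(ser$values, rep(1, 8))
  ba <- block_average(ser, 4)
  expect_equal(ba$se, 0)
  # alternating two-value series, 2 blocks: block means computable by hand
  alt <- structure(list(times = 1:8, values = rep(c(1, 3), 4), name = "x"),
                   class = "observable_series")
  ba2 <- block_average(alt, 2)
  expect_equal(ba2$block_means, c(2, 2))
  expect_equal(block_average(alt, 1)$mean, 2)
  expect_error(observable_series(tr, "nope"), "unknown")
  expect_error(gel_trajectory(list(frames[[2]], frames[[1]])), "increasing")
})
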