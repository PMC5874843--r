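# Crosslinked network construction: stoichiometry, the cyclic-iteration
# bridging loop, local relaxation, grafting and guest placement.

test_that("crosslinker targets follow the stated stoichiometry", {
  expect_equal(target_crosslink_count(1960, c(10, 2)), 392L)
  expect_equal(target_crosslink_count(100, c(10, 2)), 20L)
  expect_equal(target_crosslink_count(0, c(10, 2)), 0L)
  expect_error(target_crosslink_count(100, c(10, 0)), "positive")
  expect_error(target_crosslink_count(-1), "n_monomers")
})

test_that("a dense small build reaches its target and satisfies every invariant", {
  mdl <- build_matrix(small_build_config(seed = 1))
  expect_equal(nrow(mdl$crosslinks),
               target_crosslink_count(100, c(10, 2)))
  check_crosslink_invariants(mdl)
  # site conservation: free + consumed = total
  expect_equal(sum(!mdl$sites$used) + sum(mdl$sites$used), nrow(mdl$sites))
  # determinism: identical config and seed give the same crosslink list
  mdl2 <- build_matrix(small_build_config(seed = 1))
  expect_identical(mdl$crosslinks, mdl2$crosslinks)
})

test_that("infeasible targets raise a structured shortfall carrying the partial model", {
  cfg <- builder_config(n_chains = 2L, chain_length = 4L,
                        box_lengths = c(30, 30, 30), seed = 3)
  # two 4-monomer chains cannot host the (rounded) target in most packings;
  # force infeasibility with a tiny cutoff
  cfg$crosslink_cutoff <- 0.5
  err <- tryCatch(build_matrix(cfg), gelforge_shortfall = function(e) e)
  expect_s3_class(err, "gelforge_shortfall")
  expect_equal(err$achieved, 0L)
  expect_s3_class(err$model, "hydrogel_model")
  expect_match(conditionMessage(err), "0 of")
})

test_that("mass bookkeeping loses one water per ester bond", {
  mdl <- build_matrix(small_build_config(seed = 2))
  cs <- composition_summary(mdl)
  chain_mass <- molar_mass(mdl$chain_formula)
  expected <- cs$n_chains * chain_mass +
    cs$n_crosslinks * molar_mass("C4H6O4") -
    2 * cs$n_crosslinks * molar_mass("H2O")
  expect_equal(cs$mass, expected, tolerance = 1e-12)
  g <- graft_cyclodextrins(mdl, 2, seed = 4)
  cs2 <- composition_summary(g)
  expect_equal(cs2$mass,
               expected + 2 * (molar_mass("C48H80O40") - molar_mass("H2O")),
               tolerance = 1e-12)
  # grafting consumes no hydroxyl sites (CDs anchor to bridge carboxylates)
  expect_equal(sum(g$sites$used), sum(mdl$sites$used))
})

test_that("local relaxation finds the LJ dimer minimum and never raises energy", {
  m <- lj_only_model(sigma = 3.4, epsilon = 0.1)
  dimer <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0.9 * 3.4, 0, 0)))
  e0 <- total_energy(m, dimer)
  rel <- local_relax(dimer, m, max_steps = 500, step_size = 0.05)
  sep <- sqrt(sum((rel$coords[1, ] - rel$coords[2, ])^2))
  expect_equal(sep, 2^(1 / 6) * 3.4, tolerance = 1e-2 * 3.4)
  expect_lte(total_energy(m, rel), e0)
  # an already-minimal dimer barely moves
  at_min <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0)))
  rel2 <- local_relax(at_min, m, max_steps = 100, step_size = 0.01)
  expect_lt(max(abs(rel2$coords - at_min$coords)), 0.05)
  # zero budget returns the input unchanged
  expect_identical(local_relax(dimer, m, max_steps = 0), dimer)
})

test_that("grafting anchors each cyclodextrin to a distinct bridge", {
  mdl <- build_matrix(small_build_config(seed = 5))
  expect_identical(graft_cyclodextrins(mdl, 0), mdl)
  g <- graft_cyclodextrins(mdl, 4, seed = 6)
  expect_equal(nrow(g$cds), 4L)
  expect_equal(anyDuplicated(g$cds$anchor_crosslink), 0L)
  expect_equal(sum(g$atoms$unit == "cd") %% 4, 0)
  err <- tryCatch(graft_cyclodextrins(mdl, nrow(mdl$crosslinks) + 1L, seed = 1),
                  gelforge_capacity_error = function(e) e)
  expect_s3_class(err, "gelforge_capacity_error")
  expect_equal(err$available, nrow(mdl$crosslinks))
})

test_that("guest placement keeps the separation contract or fails structurally", {
  mdl <- build_matrix(small_build_config(seed = 7))
  guest <- make_rod_guest(4)
  expect_identical(place_guests(mdl, guest, 0), mdl)
  g <- place_guests(mdl, guest, n_guests = 5, min_distance = 8, seed = 8)
  expect_equal(g$n_guests, 5L)
  gel_xyz <- as.matrix(g$atoms[g$atoms$unit != "guest", c("x", "y", "z")])
  for (i in 1:5) {
    gi <- as.matrix(g$atoms[g$atoms$unit == "guest" & g$atoms$unit_id == i,
                            c("x", "y", "z")])
    expect_gte(gelforge:::min_cross_dist(gi, gel_xyz), 8)
    if (i > 1) for (j in 1:(i - 1)) {
      gj <- as.matrix(g$atoms[g$atoms$unit == "guest" & g$atoms$unit_id == j,
                              c("x", "y", "z")])
      expect_gte(gelforge:::min_cross_dist(gi, gj), 8)
    }
  }
  err <- tryCatch(place_guests(mdl, guest, 1, min_distance = 500, seed = 1,
                               max_attempts = 20),
                  gelforge_placement_error = function(e) e)
  expect_s3_class(err, "gelforge_placement_error")
})

test_that("no crosslink joins one chain to itself across seeded builds", {
  for (seed in 1:6) {
    mdl <- tryCatch(build_matrix(small_build_config(seed = seed)),
                    gelforge_shortfall = function(e) e$model)
    check_crosslink_invariants(mdl)
  }
})

test_that("model export writes PDB plus a composition JSON", {
  mdl <- build_matrix(small_build_config(seed = 9))
  pdb <- file.path(tempdir(), "model.pdb")
  js <- file.path(tempdir(), "model.json")
  export_model(mdl, pdb = pdb, json = js)
  back <- read_structure(pdb)
  expect_equal(n_atoms(back), nrow(mdl$atoms))
  cs <- jsonlite::read_json(js)
  expect_equal(cs$n_crosslinks, nrow(mdl$crosslinks))
})
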