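# Crosslinked hydrogel network construction: the cyclic-iteration succinate
# bridging scheme at fixed PVA:SA stoichiometry, cyclodextrin grafting and
# guest placement.
#
# The model is held flat: one atom table for the whole system (with stable
# atom ids), a hydroxyl-site registry, and a crosslink table. Bridge
# insertion esterifies two hydroxyl oxygens on distinct chains: the
# hydroxyl hydrogens are removed and the diester fragment is bonded in,
# followed by a short local steepest-descent relaxation around the new
# bridge.

#' Builder configuration
#'
#' Defaults are the study conditions of the modelled system: 56 chains of
#' 35 monomers in a 90 x 80 x 100 A box at >= 5 A chain separation, 10:2
#' PVA:SA stoichiometry with a 10 A crosslink formation cutoff, and 30
#' guests at >= 10 A separation.
#'
#' @param n_chains,chain_length Chain count and monomers per chain.
#' @param box_lengths Box edges in angstrom.
#' @param min_separation Packing separation (angstrom).
#' @param crosslink_cutoff Maximum O-O distance for bridge formation.
#' @param pva_sa_ratio Length-2 integer vector, monomer:crosslinker parts.
#' @param n_cd Number of grafted cyclodextrins (0, 6, 12 or 24 in the
#'   modelled systems; any non-negative count is accepted).
#' @param n_guests,guest_min_distance Guest placement parameters.
#' @param relax_steps Steepest-descent steps after each bridge insertion.
#' @param max_stall Consecutive failed eligible-pair draws before the
#'   builder declares a shortfall.
#' @param seed Integer seed.
#' @return A `builder_config` list.
#' @export
builder_config <- function(n_chains = 56L, chain_length = 35L,
                           box_lengths = c(90, 80, 100), min_separation = 5,
                           crosslink_cutoff = 10, pva_sa_ratio = c(10L, 2L),
                           n_cd = 0L, n_guests = 30L, guest_min_distance = 10,
                           relax_steps = 20L, max_stall = 10000L, seed = 1L) {
  stopifnot(n_chains >= 0, chain_length >= 1, all(box_lengths > 0),
            n_cd >= 0, n_guests >= 0)
  if (any(pva_sa_ratio <= 0)) stop_gf("ratio parts must be positive", "gelforge_invalid")
  structure(list(
    n_chains = as.integer(n_chains), chain_length = as.integer(chain_length),
    box_lengths = box_lengths, min_separation = min_separation,
    crosslink_cutoff = crosslink_cutoff, pva_sa_ratio = pva_sa_ratio,
    n_cd = as.integer(n_cd), n_guests = as.integer(n_guests),
    guest_min_distance = guest_min_distance,
    relax_steps = as.integer(relax_steps), max_stall = as.integer(max_stall),
    seed = as.integer(seed)
  ), class = "builder_config")
}

#' Crosslinker target count at a given stoichiometry
#'
#' The number of succinic-acid bridges required to hit the stated
#' monomer-to-crosslinker proportion: `round(n_monomers * sa / pva)`.
#'
#' @param n_monomers Total PVA monomer count.
#' @param ratio Length-2 vector `c(pva_parts, sa_parts)`.
#' @return Integer crosslinker count.
#' @export
#' @examples
#' target_crosslink_count(1960, c(10, 2))  # 392
target_crosslink_count <- function(n_monomers, ratio = c(10, 2)) {
  if (n_monomers < 0) stop_gf("n_monomers must be >= 0", "gelforge_invalid")
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop_gf("ratio must be two positive parts", "gelforge_invalid")
  }
  as.integer(round(n_monomers * ratio[2] / ratio[1]))
}

mol_to_flat <- function(mol, unit, unit_id, chain = NA_integer_, id_start = 1L) {
  n <- n_atoms(mol)
  data.frame(
    id = seq.int(id_start, length.out = n),
    element = mol$element,
    x = mol$coords[, 1], y = mol$coords[, 2], z = mol$coords[, 3],
    charge = mol$charge, radius = mol$radius, role = mol$role,
    unit = unit, unit_id = unit_id, chain = chain
  )
}

flat_coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Build the crosslinked polymer matrix
#'
#' Generates and packs the chains, then runs the cyclic-iteration
#' crosslinking scheme: repeatedly pick, uniformly at random, an unused
#' hydroxyl-oxygen pair on two distinct chains separated by at most the
#' cutoff; esterify both sites with an idealized succinate diester bridge;
#' locally relax atoms within 6 A of the new bridge; stop at the target
#' count (from [target_crosslink_count()]) or when no eligible pair
#' remains, which raises a structured shortfall error carrying the partial
#' model.
#'
#' @param config A [builder_config()].
#' @param model [energy_model()] used for local relaxation.
#' @return A `hydrogel_model`.
#' @export
build_matrix <- function(config = builder_config(), model = energy_model()) {
  stopifnot(inherits(config, "builder_config"))
  box <- sim_box(config$box_lengths)
  chains <- lapply(seq_len(config$n_chains), function(i) {
    build_pva_chain(config$chain_length, seed = config$seed + i)
  })
  if (length(chains)) {
    chains <- random_pack(chains, box, config$min_separation,
                          seed = config$seed)
  }
  atoms <- NULL
  sites <- NULL
  bonds <- NULL
  id0 <- 1L
  for (i in seq_along(chains)) {
    fl <- mol_to_flat(chains[[i]], "chain", i, chain = i, id_start = id0)
    atoms <- rbind(atoms, fl)
    if (nrow(chains[[i]]$bonds)) {
      bonds <- rbind(bonds, chains[[i]]$bonds + (id0 - 1L))
    }
    sites <- rbind(sites, data.frame(
      chain = i, site = seq_along(chains[[i]]$hydroxyl_sites),
      atom = chains[[i]]$hydroxyl_sites + (id0 - 1L), used = FALSE
    ))
    id0 <- id0 + n_atoms(chains[[i]])
  }
  mdl <- structure(list(
    atoms = atoms, bonds = bonds, sites = sites,
    crosslinks = data.frame(chain_a = integer(0), site_a = integer(0),
                            chain_b = integer(0), site_b = integer(0),
                            formation_distance = numeric(0),
                            bridge_unit = integer(0)),
    cds = data.frame(cd_unit = integer(0), anchor_crosslink = integer(0)),
    n_guests = 0L,
    box = box, config = config,
    chain_formula = if (length(chains)) mol_formula(chains[[1]]) else NULL
  ), class = "hydrogel_model")
  target <- target_crosslink_count(config$n_chains * config$chain_length,
                                   config$pva_sa_ratio)
  if (target == 0L) return(mdl)
  mdl <- with_seed(config$seed + 104729L,
                   crosslink_to_target(mdl, target, model))
  mdl
}

# The cyclic-iteration loop. Eligibility is computed once from the packed
# coordinates and pruned as sites are consumed; the actual formation
# distance is re-measured at creation time and pairs that drifted past the
# cutoff are dropped.
crosslink_to_target <- function(mdl, target, model) {
  cfg <- mdl$config
  site_xyz <- flat_coords(mdl$atoms[match(mdl$sites$atom, mdl$atoms$id), ])
  d2 <- cross_dist2(site_xyz, site_xyz)
  same_chain <- outer(mdl$sites$chain, mdl$sites$chain, "==")
  elig <- which(upper.tri(d2) & d2 <= cfg$crosslink_cutoff^2 & !same_chain,
                arr.ind = TRUE)
  pair_a <- elig[, 1]; pair_b <- elig[, 2]
  alive <- rep(TRUE, length(pair_a))
  site_used <- rep(FALSE, nrow(mdl$sites))
  next_unit <- 1L
  while (nrow(mdl$crosslinks) < target) {
    cand <- which(alive)
    if (!length(cand)) {
      cnd <- structure(
        class = c("gelforge_shortfall", "gelforge_error", "error", "condition"),
        list(message = sprintf(
          "crosslinking stalled at %d of %d bridges: no eligible hydroxyl pair remains",
          nrow(mdl$crosslinks), target),
          call = NULL, achieved = nrow(mdl$crosslinks), target = target,
          model = mdl))
      stop(cnd)
    }
    pick <- cand[[sample.int(length(cand), 1L)]]
    ia <- pair_a[pick]; ib <- pair_b[pick]
    alive[pick] <- FALSE
    oa_row <- match(mdl$sites$atom[ia], mdl$atoms$id)
    ob_row <- match(mdl$sites$atom[ib], mdl$atoms$id)
    oa <- as.numeric(mdl$atoms[oa_row, c("x", "y", "z")])
    ob <- as.numeric(mdl$atoms[ob_row, c("x", "y", "z")])
    dist_now <- vec_norm(ob - oa)
    if (dist_now > cfg$crosslink_cutoff) next
    bridge <- build_succinate_bridge(oa, ob)
    mdl <- insert_bridge(mdl, bridge, ia, ib, next_unit, dist_now, model)
    site_used[c(ia, ib)] <- TRUE
    alive <- alive & !(site_used[pair_a] | site_used[pair_b])
    next_unit <- next_unit + 1L
  }
  mdl
}

insert_bridge <- function(mdl, bridge, ia, ib, unit_id, dist_now, model) {
  cfg <- mdl$config
  # remove the two hydroxyl hydrogens (esterification)
  for (sidx in c(ia, ib)) {
    o_id <- mdl$sites$atom[sidx]
    nbr <- c(mdl$bonds[mdl$bonds[, 1] == o_id, 2],
             mdl$bonds[mdl$bonds[, 2] == o_id, 1])
    h_id <- nbr[mdl$atoms$element[match(nbr, mdl$atoms$id)] == "H"]
    if (length(h_id)) {
      h_id <- h_id[1]
      mdl$atoms <- mdl$atoms[mdl$atoms$id != h_id, ]
      mdl$bonds <- mdl$bonds[!(mdl$bonds[, 1] == h_id | mdl$bonds[, 2] == h_id), ,
                             drop = FALSE]
    }
  }
  id0 <- max(mdl$atoms$id) + 1L
  fl <- mol_to_flat(bridge, "bridge", unit_id, id_start = id0)
  mdl$atoms <- rbind(mdl$atoms, fl)
  link <- attr(bridge, "link_atoms") + (id0 - 1L)
  mdl$bonds <- rbind(mdl$bonds, bridge$bonds + (id0 - 1L),
                     c(mdl$sites$atom[ia], link[1]),
                     c(mdl$sites$atom[ib], link[2]))
  mdl$sites$used[c(ia, ib)] <- TRUE
  mdl$crosslinks <- rbind(mdl$crosslinks, data.frame(
    chain_a = mdl$sites$chain[ia], site_a = mdl$sites$site[ia],
    chain_b = mdl$sites$chain[ib], site_b = mdl$sites$site[ib],
    formation_distance = dist_now, bridge_unit = unit_id
  ))
  if (cfg$relax_steps > 0L) mdl <- relax_around(mdl, fl$id, model,
                                                max_steps = cfg$relax_steps)
  mdl
}

# Relax atoms within 6 A of the given atom ids against a fixed environment
# (atoms within 12 A), with harmonic restraints on bonds touching the
# moving set.
relax_around <- function(mdl, center_ids, model, max_steps = 20L,
                         move_radius = 6, env_radius = 12) {
  xyz <- flat_coords(mdl$atoms)
  ctr <- xyz[match(center_ids, mdl$atoms$id), , drop = FALSE]
  d2 <- cross_dist2(xyz, ctr)
  mind <- sqrt(apply(d2, 1, min))
  moving <- which(mind <= move_radius)
  env <- which(mind > move_radius & mind <= env_radius)
  if (!length(moving)) return(mdl)
  ids_m <- mdl$atoms$id[moving]
  in_m1 <- match(mdl$bonds[, 1], ids_m)
  in_m2 <- match(mdl$bonds[, 2], ids_m)
  ids_all <- c(ids_m, mdl$atoms$id[env])
  rows_all <- c(moving, env)
  bonds_keep <- which(!is.na(in_m1) | !is.na(in_m2))
  bl <- cbind(match(mdl$bonds[bonds_keep, 1], ids_all),
              match(mdl$bonds[bonds_keep, 2], ids_all))
  bl <- bl[stats::complete.cases(bl), , drop = FALSE]
  par_all <- lj_atom_params(model, mdl$atoms$element[rows_all])
  q_all <- mdl$atoms$charge[rows_all]
  x_all <- xyz[rows_all, , drop = FALSE]
  nm <- length(moving)
  relaxed <- sd_relax(x_all, seq_len(nm), par_all, q_all, bl, model,
                      max_steps = max_steps)
  mdl$atoms[moving, c("x", "y", "z")] <- relaxed[seq_len(nm), , drop = FALSE]
  mdl
}

# Steepest descent with backtracking on LJ+Coulomb (1-2 and 1-3 exclusions)
# plus harmonic bond restraints at entry-time lengths. Only rows in
# `moving` move. Returns the full coordinate matrix.
sd_relax <- function(x, moving, par, q, bond_list, model, max_steps = 200L,
                     step0 = 0.02, gtol = 1e-3, k_bond = 300) {
  n <- nrow(x)
  excl <- matrix(FALSE, n, n)
  if (nrow(bond_list)) {
    excl[bond_list] <- TRUE
    excl[bond_list[, c(2, 1), drop = FALSE]] <- TRUE
    # 1-3 exclusions via one step of adjacency
    adj <- excl
    excl <- excl | ((adj %*% adj) > 0)
  }
  diag(excl) <- TRUE
  r0 <- if (nrow(bond_list)) {
    sqrt(rowSums((x[bond_list[, 1], , drop = FALSE] -
                    x[bond_list[, 2], , drop = FALSE])^2))
  } else {
    numeric(0)
  }
  sij <- outer(par$sigma, par$sigma, "+") / 2
  eij <- sqrt(outer(par$epsilon, par$epsilon))
  qq <- outer(q, q) * model$ke / model$eps_r
  energy_grad <- function(xx) {
    d2 <- cross_dist2(xx, xx)
    d <- sqrt(d2)
    capped <- d < model$r_cap & !excl
    d[d < model$r_cap] <- model$r_cap
    d[excl] <- Inf
    x6 <- (sij / d)^6
    e_nb <- sum(4 * eij * (x6 * x6 - x6) + qq / d) / 2
    # dE/dr / r for each pair (zero where capped or excluded)
    coef <- (4 * eij * (-12 * x6 * x6 + 6 * x6) / d - qq / d^2) / d
    coef[capped] <- 0
    coef[!is.finite(coef)] <- 0
    g <- xx * rowSums(coef) - coef %*% xx
    e_b <- 0
    if (nrow(bond_list)) {
      dv <- xx[bond_list[, 1], , drop = FALSE] - xx[bond_list[, 2], , drop = FALSE]
      rb <- sqrt(rowSums(dv^2))
      e_b <- sum(k_bond * (rb - r0)^2)
      fb <- 2 * k_bond * (rb - r0) / pmax(rb, 1e-12)
      gb <- dv * fb
      for (kk in seq_len(nrow(bond_list))) {
        g[bond_list[kk, 1], ] <- g[bond_list[kk, 1], ] + gb[kk, ]
        g[bond_list[kk, 2], ] <- g[bond_list[kk, 2], ] - gb[kk, ]
      }
    }
    list(e = e_nb + e_b, g = g)
  }
  eg <- energy_grad(x)
  if (!is.finite(eg$e)) stop_gf("non-finite starting energy", "gelforge_energy_error")
  step <- step0
  for (it in seq_len(max_steps)) {
    gm <- eg$g
    gm[-moving, ] <- 0
    gn <- sqrt(sum(gm^2))
    if (!is.finite(gn)) stop_gf("non-finite gradient", "gelforge_energy_error")
    if (gn < gtol) break
    accepted <- FALSE
    for (bt in 1:12) {
      xn <- x - step * gm / gn
      egn <- energy_grad(xn)
      if (is.finite(egn$e) && egn$e <= eg$e) {
        x <- xn; eg <- egn; step <- min(step * 1.5, 0.5)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  x
}

#' Locally relax a molecular region
#'
#' Steepest descent with backtracking line search on the nonbonded energy
#' (1-2 and 1-3 pairs excluded) plus harmonic restraints holding bonds at
#' their entry-time lengths. Accepted steps never increase the energy; the
#' run stops at `max_steps` or when the gradient norm drops below
#' `1e-3` kcal/mol/A.
#'
#' @param mol The `molecule` to relax (all atoms move).
#' @param model An [energy_model()].
#' @param fixed Optional `molecule` kept rigid as the environment.
#' @param max_steps Iteration budget (0 returns the input unchanged).
#' @param step_size Initial step length (angstrom).
#' @return The relaxed `molecule`.
#' @export
local_relax <- function(mol, model = energy_model(), fixed = NULL,
                        max_steps = 200L, step_size = 0.02) {
  if (max_steps <= 0L) return(mol)
  nm <- n_atoms(mol)
  if (is.null(fixed)) {
    x <- mol$coords
    par <- lj_atom_params(model, mol$element)
    qv <- mol$charge
    bl <- mol$bonds
  } else {
    x <- rbind(mol$coords, fixed$coords)
    par <- lj_atom_params(model, c(mol$element, fixed$element))
    qv <- c(mol$charge, fixed$charge)
    bl <- rbind(mol$bonds,
                if (nrow(fixed$bonds)) fixed$bonds + nm else NULL)
  }
  if (is.null(bl)) bl <- matrix(integer(0), ncol = 2)
  out <- sd_relax(x, seq_len(nm), par, qv, bl, model,
                  max_steps = max_steps, step0 = step_size)
  mol$coords <- out[seq_len(nm), , drop = FALSE]
  mol
}

#' Graft cyclodextrins onto a built matrix
#'
#' Anchors each cyclodextrin by one primary-face hydroxyl oxygen to the
#' carbonyl carbon of a distinct succinate bridge (ester linkage,
#' abstracted), choosing unclashed placements pointing away from the gel
#' interior. Raises a capacity error naming the available anchor count when
#' `n_cd` exceeds it.
#'
#' @param mdl A `hydrogel_model`.
#' @param n_cd Number of cyclodextrins to graft.
#' @param seed Integer seed.
#' @param clash_min Minimum allowed distance to existing atoms (angstrom).
#' @return The updated `hydrogel_model`.
#' @export
graft_cyclodextrins <- function(mdl, n_cd, seed = 1L, clash_min = 1.5) {
  stopifnot(inherits(mdl, "hydrogel_model"), n_cd >= 0)
  if (n_cd == 0L) return(mdl)
  free <- setdiff(seq_len(nrow(mdl$crosslinks)), mdl$cds$anchor_crosslink)
  if (n_cd > length(free)) {
    stop_gf(sprintf("cannot graft %d cyclodextrins: only %d free anchors available",
                    n_cd, length(free)),
            "gelforge_capacity_error", available = length(free))
  }
  cd0 <- build_cyclodextrin()
  cd_base <- sweep(cd0$coords, 2, centroid(cd0))
  gel_center <- colMeans(flat_coords(mdl$atoms))
  dirs <- fibonacci_sphere(26)
  with_seed(seed, {
    free <- sample(free)
    grafted <- 0L
    for (anchor in free) {
      if (grafted >= n_cd) break
      bridge_rows <- which(mdl$atoms$unit == "bridge" &
                             mdl$atoms$unit_id == mdl$crosslinks$bridge_unit[anchor])
      bpos <- colMeans(flat_coords(mdl$atoms[bridge_rows, ]))
      out_dir <- bpos - gel_center
      if (vec_norm(out_dir) < 1e-9) out_dir <- c(0, 0, 1)
      out_dir <- normalize(out_dir)
      ord <- order(-drop(dirs %*% out_dir))
      placed <- FALSE
      all_xyz <- flat_coords(mdl$atoms)
      for (di in ord) {
        u <- dirs[di, ]
        R <- rotation_to(c(0, 0, -1), -u)  # primary face toward the anchor
        for (offset in c(4.5, 6, 8)) {
          cand <- sweep(cd_base %*% t(R), 2, bpos + u * offset, "+")
          if (min_cross_dist(cand, all_xyz) >= clash_min) {
            mol <- cd0
            mol$coords <- cand
            id0 <- max(mdl$atoms$id) + 1L
            unit_id <- nrow(mdl$cds) + 1L
            fl <- mol_to_flat(mol, "cd", unit_id, id_start = id0)
            mdl$atoms <- rbind(mdl$atoms, fl)
            mdl$bonds <- rbind(mdl$bonds, mol$bonds + (id0 - 1L))
            # ester bond: nearest primary-face O to a bridge carbonyl C
            prim <- fl$id[fl$role == "primary-OH"]
            bc <- mdl$atoms$id[bridge_rows][
              mdl$atoms$role[bridge_rows] == "sa-C"]
            px <- flat_coords(mdl$atoms[match(prim, mdl$atoms$id), ])
            bx <- flat_coords(mdl$atoms[match(bc, mdl$atoms$id), ])
            dd <- cross_dist2(px, bx)
            best <- arrayInd(which.min(dd), dim(dd))
            mdl$bonds <- rbind(mdl$bonds, c(prim[best[1]], bc[best[2]]))
            mdl$cds <- rbind(mdl$cds, data.frame(cd_unit = unit_id,
                                                 anchor_crosslink = anchor))
            grafted <- grafted + 1L
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
    }
    if (grafted < n_cd) {
      stop_gf(sprintf("grafting placed %d of %d cyclodextrins: %d anchors available but placements clashed",
                      grafted, n_cd, length(free)),
              "gelforge_capacity_error", available = length(free))
    }
    mdl
  })
}

# Rotation matrix mapping unit vector a to unit vector b.
rotation_to <- function(a, b) {
  a <- normalize(a); b <- normalize(b)
  v <- pracma_cross(a, b)
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) normalize(pracma_cross(a, c(1, 0, 0))) else
      normalize(pracma_cross(a, c(0, 1, 0)))
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Place guest molecules around a hydrogel model
#'
#' Rejection placement of rigid guest copies with every guest-to-gel and
#' guest-to-guest minimum atom distance at least `min_distance`. By default
#' guests are placed in a 160 A cube centered on the gel (the solvation box
#' the modelled systems are re-centered into), since the build box itself
#' leaves no room at 10 A clearance.
#'
#' @param mdl A `hydrogel_model`.
#' @param guest A `molecule`.
#' @param n_guests Number of copies.
#' @param min_distance Minimum separation (angstrom).
#' @param box Optional [sim_box()] for placement.
#' @param seed Integer seed.
#' @param max_attempts Attempt budget per guest.
#' @return The updated `hydrogel_model`.
#' @export
place_guests <- function(mdl, guest, n_guests = 30L, min_distance = 10,
                         box = NULL, seed = 1L, max_attempts = 10000L) {
  stopifnot(inherits(mdl, "hydrogel_model"), n_guests >= 0)
  if (n_guests == 0L) return(mdl)
  gel_xyz <- flat_coords(mdl$atoms)
  if (is.null(box)) {
    box <- sim_box(c(160, 160, 160), origin = colMeans(gel_xyz) - 80)
  }
  base <- sweep(guest$coords, 2, centroid(guest))
  lo <- box$origin; hi <- box$origin + box$lengths
  with_seed(seed, {
    for (gi in seq_len(n_guests)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        R <- quat_to_matrix(drop(random_quaternion(1)))
        rot <- base %*% t(R)
        mins <- apply(rot, 2, min); maxs <- apply(rot, 2, max)
        span <- maxs - mins
        if (any(span > box$lengths)) break
        shift <- lo - mins + stats::runif(3) * (box$lengths - span)
        cand <- sweep(rot, 2, shift, "+")
        if (min_cross_dist(cand, gel_xyz) < min_distance) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_gf(sprintf("guest placement failed: placed %d of %d guests", gi - 1L, n_guests),
                "gelforge_placement_error", achieved = gi - 1L)
      }
      mol <- guest
      mol$coords <- cand
      id0 <- max(mdl$atoms$id) + 1L
      fl <- mol_to_flat(mol, "guest", mdl$n_guests + 1L, id_start = id0)
      mdl$atoms <- rbind(mdl$atoms, fl)
      if (nrow(guest$bonds)) mdl$bonds <- rbind(mdl$bonds, guest$bonds + (id0 - 1L))
      mdl$n_guests <- mdl$n_guests + 1L
      gel_xyz <- rbind(gel_xyz, cand)
    }
    mdl
  })
}

#' Composition summary of a hydrogel model
#'
#' Monomer, crosslinker, cyclodextrin and guest counts plus the free-
#' fragment mass balance: total mass = sum of free fragment masses minus
#' one water (18.015 g/mol) per ester bond formed (two per succinate
#' bridge, one per cyclodextrin anchor).
#'
#' @param mdl A `hydrogel_model`.
#' @return A list with counts, `cd_mass_fraction` and `mass` (g/mol).
#' @export
composition_summary <- function(mdl) {
  n_sa <- nrow(mdl$crosslinks)
  n_cd <- nrow(mdl$cds)
  n_chain <- mdl$config$n_chains
  chain_mass <- if (is.null(mdl$chain_formula)) 0 else molar_mass(mdl$chain_formula)
  sa_mass <- molar_mass("C4H6O4")
  cd_mass <- molar_mass("C48H80O40")
  water <- molar_mass("H2O")
  total <- n_chain * chain_mass + n_sa * sa_mass + n_cd * cd_mass -
    water * (2 * n_sa + n_cd)
  list(
    n_chains = n_chain,
    n_monomers = n_chain * mdl$config$chain_length,
    n_crosslinks = n_sa,
    n_cd = n_cd,
    n_guests = mdl$n_guests,
    sites_total = nrow(mdl$sites),
    sites_consumed = sum(mdl$sites$used),
    cd_mass_fraction = if (total > 0) n_cd * cd_mass / total else 0,
    mass = total
  )
}

#' @export
print.hydrogel_model <- function(x, ...) {
  cs <- composition_summary(x)
  cat(sprintf(paste0(
    "<hydrogel_model> %d chains (%d monomers), %d SA crosslinks, ",
    "%d CDs, %d guests\n  mass %.1f g/mol, CD mass fraction %.3f\n"),
    cs$n_chains, cs$n_monomers, cs$n_crosslinks, cs$n_cd, cs$n_guests,
    cs$mass, cs$cd_mass_fraction))
  invisible(x)
}

#' Flatten a hydrogel model to a single molecule
#'
#' @param mdl A `hydrogel_model`.
#' @return A `molecule` carrying attributes `unit` and `unit_id` per atom.
#' @export
model_to_molecule <- function(mdl) {
  a <- mdl$atoms
  bonds <- cbind(match(mdl$bonds[, 1], a$id), match(mdl$bonds[, 2], a$id))
  bonds <- bonds[stats::complete.cases(bonds), , drop = FALSE]
  mol <- molecule(a$element, flat_coords(a), bonds = bonds, charge = a$charge,
                  radius = a$radius, role = a$role, name = "hydrogel")
  attr(mol, "unit") <- a$unit
  attr(mol, "unit_id") <- a$unit_id
  attr(mol, "chain") <- a$chain
  mol
}

#' Export a hydrogel model
#'
#' Writes a PDB (chains in the chain-ID column, bridges/CDs/guests as
#' separate chain groups) and a JSON composition summary.
#'
#' @param mdl A `hydrogel_model`.
#' @param pdb,json Output paths (`NULL` skips either).
#' @return Invisibly, `pdb`.
#' @export
export_model <- function(mdl, pdb = NULL, json = NULL) {
  if (!is.null(pdb)) {
    mol <- model_to_molecule(mdl)
    chain_index <- ifelse(mdl$atoms$unit == "chain", mdl$atoms$chain,
                          ifelse(mdl$atoms$unit == "bridge",
                                 mdl$config$n_chains + 1L,
                                 ifelse(mdl$atoms$unit == "cd",
                                        mdl$config$n_chains + 2L,
                                        mdl$config$n_chains + 3L)))
    write_pdb(mol, pdb, chain_index = chain_index)
  }
  if (!is.null(json)) {
    cs <- composition_summary(mdl)
    cs$mass <- signif(cs$mass, 6)
    cs$cd_mass_fraction <- signif(cs$cd_mass_fraction, 6)
    jsonlite::write_json(cs, json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(pdb)
}
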