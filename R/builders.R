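# Idealized coarse structure builders: PVA chains, succinate diester
# bridges, gamma-cyclodextrin rings, and rigid random packing into a box.
#
# Geometries use standard bond lengths (C-C 1.54, C-O 1.43, C-H 1.09,
# O-H 0.96 A) and tetrahedral angles. These are starting structures for
# geometric/energetic pipeline stages, not quantum-optimized molecules.

BOND_CC <- 1.54
BOND_CO <- 1.43
BOND_CH <- 1.09
BOND_OH <- 0.96

#' Build an idealized PVA chain
#'
#' Extended zig-zag backbone of `-CH2-CH(OH)-` repeat units with standard
#' bond lengths and tetrahedral angles, H-capped ends, and atactic hydroxyl
#' placement (side chosen per monomer from the seed).
#'
#' @param n_monomers Number of repeat units (>= 1).
#' @param seed Integer seed controlling tacticity; identical seeds give
#'   identical coordinates.
#' @return A `polymer_chain` (a `molecule` with fields `monomer_count` and
#'   `hydroxyl_sites`, the atom indices of the graftable hydroxyl oxygens).
#' @export
#' @examples
#' ch <- build_pva_chain(5, seed = 1)
#' length(ch$hydroxyl_sites)
build_pva_chain <- function(n_monomers, seed = 1L) {
  if (n_monomers < 1) stop_gf("n_monomers must be >= 1", "gelforge_invalid")
  n_monomers <- as.integer(n_monomers)
  nb <- 2L * n_monomers                       # backbone carbons
  d <- BOND_CC * sqrt(2 / 3)                  # zig-zag axial step
  e <- BOND_CC / sqrt(3)                      # zig-zag height
  kk <- seq_len(nb + 2L) - 1L                 # includes phantom neighbors
  back <- cbind((kk - 1L) * d, 0, ifelse(kk %% 2L == 0L, 0, e))
  # back rows: 1 = phantom before, 2..nb+1 = carbons, nb+2 = phantom after
  subst_dirs <- function(k) {
    u1 <- normalize(back[k - 1L, ] - back[k, ])
    u2 <- normalize(back[k + 1L, ] - back[k, ])
    s <- normalize(u1 + u2)
    p <- normalize(pracma_cross(u1, u2))
    alpha <- (1 / 3) / drop(crossprod(s, u1))
    beta <- sqrt(max(0, 1 - alpha^2))
    list(plus = -alpha * s + beta * p, minus = -alpha * s - beta * p)
  }
  up_side <- with_seed(seed, sample(c(TRUE, FALSE), n_monomers, replace = TRUE))
  element <- character(0); coords <- NULL; role <- character(0)
  bonds <- NULL
  hydroxyl_sites <- integer(n_monomers)
  idx <- 0L
  add_atom <- function(el, pos, rl) {
    element[idx + 1L] <<- el
    coords <<- rbind(coords, pos)
    role[idx + 1L] <<- rl
    idx <<- idx + 1L
    idx
  }
  add_bond <- function(i, j) bonds <<- rbind(bonds, c(i, j))
  prev_c <- 0L
  for (m in seq_len(n_monomers)) {
    for (half in 1:2) {
      k <- 2L * (m - 1L) + half + 1L          # row in `back`
      ci <- add_atom("C", back[k, ], "backbone")
      if (prev_c) add_bond(prev_c, ci)
      sd2 <- subst_dirs(k)
      if (half == 1L) {                       # CH2
        add_bond(ci, add_atom("H", back[k, ] + BOND_CH * sd2$plus, "h"))
        add_bond(ci, add_atom("H", back[k, ] + BOND_CH * sd2$minus, "h"))
      } else {                                # CH(OH)
        o_dir <- if (up_side[m]) sd2$plus else sd2$minus
        h_dir <- if (up_side[m]) sd2$minus else sd2$plus
        add_bond(ci, add_atom("H", back[k, ] + BOND_CH * h_dir, "h"))
        o_pos <- back[k, ] + BOND_CO * o_dir
        oi <- add_atom("O", o_pos, "hydroxyl-O")
        add_bond(ci, oi)
        hi <- add_atom("H", o_pos + BOND_OH * o_dir, "hydroxyl-H")
        add_bond(oi, hi)
        hydroxyl_sites[m] <- oi
      }
      # H caps replacing the phantom continuation bonds
      if (k == 2L) {
        cap <- back[k, ] + BOND_CH * normalize(back[1L, ] - back[k, ])
        add_bond(ci, add_atom("H", cap, "h"))
      }
      if (k == nb + 1L) {
        cap <- back[k, ] + BOND_CH * normalize(back[nb + 2L, ] - back[k, ])
        add_bond(ci, add_atom("H", cap, "h"))
      }
      prev_c <- ci
    }
  }
  mol <- molecule(element, coords, bonds = bonds, role = role,
                  name = sprintf("PVA%d", n_monomers))
  mol$monomer_count <- n_monomers
  mol$hydroxyl_sites <- hydroxyl_sites
  class(mol) <- c("polymer_chain", "molecule")
  mol
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build an idealized succinate diester bridge
#'
#' Places the `-C(=O)-CH2-CH2-C(=O)-` fragment along the segment between
#' two ester oxygen positions (the hydroxyl oxygens of the two crosslinked
#' chains). The terminal carbons carry the carbonyl oxygens and bond to the
#' site oxygens.
#'
#' @param o_a,o_b Positions (angstrom) of the two ester oxygens.
#' @return A `molecule` with attributes `link_atoms` (indices of the two
#'   carbons that bond to the site oxygens) and `formation_distance`.
#' @export
build_succinate_bridge <- function(o_a, o_b) {
  u <- o_b - o_a
  d <- vec_norm(u)
  if (d < 1e-6) stop_gf("bridge endpoints coincide", "gelforge_invalid")
  u <- u / d
  # perpendicular reference
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- normalize(pracma_cross(u, ref))
  q <- normalize(pracma_cross(u, p))
  c1 <- o_a + BOND_CO * u
  c4 <- o_b - BOND_CO * u
  inner <- vec_norm(c4 - c1)
  c2 <- c1 + (c4 - c1) * (1 / 3) + 0.4 * p
  c3 <- c1 + (c4 - c1) * (2 / 3) - 0.4 * p
  coords <- rbind(
    c1, c1 + 1.22 * p,                     # C1, =O
    c2, c2 + BOND_CH * q, c2 - BOND_CH * q,
    c3, c3 + BOND_CH * q, c3 - BOND_CH * q,
    c4, c4 - 1.22 * p                      # C4, =O
  )
  mol <- molecule(
    element = c("C", "O", "C", "H", "H", "C", "H", "H", "C", "O"),
    coords = coords,
    bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(3, 6),
                  c(6, 7), c(6, 8), c(6, 9), c(9, 10)),
    role = c("sa-C", "carbonyl-O", "sa-C", "h", "h", "sa-C", "h", "h",
             "sa-C", "carbonyl-O"),
    name = "SA-bridge"
  )
  attr(mol, "link_atoms") <- c(1L, 9L)
  attr(mol, "formation_distance") <- d
  attr(mol, "free_formula") <- parse_formula("C4H6O4")  # succinic acid
  mol
}

#' Build a coarse gamma-cyclodextrin ring
#'
#' Heavy-atom ring of `n_units` glucopyranoside units: glycosidic oxygens
#' on a circle, ring carbons outside it, two secondary-face hydroxyl
#' oxygens per unit on the wide rim and one primary-face hydroxyl oxygen on
#' the narrow rim. Geometry is idealized; the real molecular formula
#' (`C48H80O40` for eight units) is carried as metadata for mass
#' bookkeeping.
#'
#' @param n_units Number of glucose units (8 for gamma-CD).
#' @param rim_radius Glycosidic-oxygen circle radius (angstrom).
#' @return A `molecule` with role tags `glycosidic-O`, `secondary-OH`,
#'   `primary-OH`, `cd-C`, plus attributes `free_formula` and `frame`
#'   (its [cavity_frame()]).
#' @export
build_cyclodextrin <- function(n_units = 8L, rim_radius = 5.9) {
  stopifnot(n_units >= 6L)
  phi <- 2 * pi * (seq_len(n_units) - 1L) / n_units
  ring <- function(r, z) cbind(r * cos(phi), r * sin(phi), z)
  half <- pi / n_units
  ring2 <- function(r, z) cbind(r * cos(phi + half), r * sin(phi + half), z)
  coords <- rbind(
    ring(rim_radius, 0),                     # glycosidic O
    ring2(rim_radius + 1.2, 0.6),            # ring C (C1-ish)
    ring2(rim_radius + 1.2, -0.6),           # ring C (C4-ish)
    ring2(rim_radius + 2.0, 1.4),            # ring C bearing secondary OH
    ring(rim_radius + 1.8, 1.6),             # ring C bearing secondary OH
    ring2(rim_radius + 2.2, 2.4),            # secondary OH (wide rim)
    ring(rim_radius + 2.0, 2.6),             # secondary OH (wide rim)
    ring2(rim_radius - 0.2, -1.6),           # CH2 carbon toward narrow rim
    ring2(rim_radius - 0.8, -2.6)            # primary OH (narrow rim)
  )
  element <- rep(c("O", "C", "C", "C", "C", "O", "O", "C", "O"), each = n_units)
  role <- rep(c("glycosidic-O", "cd-C", "cd-C", "cd-C", "cd-C",
                "secondary-OH", "secondary-OH", "cd-C", "primary-OH"),
              each = n_units)
  idx <- function(block, i) (block - 1L) * n_units + i
  bonds <- NULL
  for (i in seq_len(n_units)) {
    j <- if (i == n_units) 1L else i + 1L
    bonds <- rbind(bonds,
                   c(idx(1, i), idx(2, i)), c(idx(2, i), idx(3, i)),
                   c(idx(3, i), idx(1, j)),                      # glycosidic link
                   c(idx(2, i), idx(4, i)), c(idx(4, i), idx(6, i)),
                   c(idx(1, i), idx(5, i)), c(idx(5, i), idx(7, i)),
                   c(idx(3, i), idx(8, i)), c(idx(8, i), idx(9, i)))
  }
  mol <- molecule(element, coords, bonds = bonds, role = role,
                  name = sprintf("CD%d", n_units))
  attr(mol, "free_formula") <- parse_formula(
    sprintf("C%dH%dO%d", 6L * n_units, 10L * n_units, 5L * n_units))
  attr(mol, "frame") <- cd_cavity_frame(mol)
  mol
}

#' Randomly pack rigid chains into a box
#'
#' Rejection sampling with random rigid placement: each chain receives a
#' random rotation and a uniform translation keeping all atoms in the box,
#' and is accepted when its minimum atom-atom distance to every
#' already-placed chain is at least `min_separation`. Rotation proposals
#' start uniform on SO(3); once a third of the attempt budget is spent on
#' a chain, they progressively align the chain's principal axis with the
#' box axes it fits along (with a shrinking random tilt), which lets dense
#' systems of elongated chains reach full occupancy the way optimizing
#' packers do.
#'
#' @param chains List of `molecule`s (e.g. [build_pva_chain()] output).
#' @param box A [sim_box()].
#' @param min_separation Minimum inter-chain atom distance (angstrom).
#' @param seed Integer seed; packing is deterministic given the seed.
#' @param max_attempts Placement attempt budget per chain.
#' @return The list of placed chains (same objects, new coordinates).
#' @export
random_pack <- function(chains, box, min_separation = 5, seed = NULL,
                        max_attempts = 10000L) {
  stopifnot(inherits(box, "sim_box"))
  lo <- box$origin
  hi <- box$origin + box$lengths
  with_seed(seed, {
    placed_coords <- matrix(numeric(0), 0, 3)
    out <- vector("list", length(chains))
    axes <- rbind(diag(3), -diag(3))
    # reference lateral footprint for the aligned-phase slot lattice
    lat_span <- vapply(chains, function(mol) {
      b <- sweep(mol$coords, 2, centroid(mol))
      pr <- svd(b, nu = 0, nv = 3)$v
      bp <- b %*% pr
      max(apply(bp[, 2:3, drop = FALSE], 2, function(v) diff(range(v))))
    }, numeric(1))
    pitch_ref <- min_separation + max(lat_span, 0) + 0.6
    for (ci in seq_along(chains)) {
      mol <- chains[[ci]]
      base <- sweep(mol$coords, 2, centroid(mol))
      principal <- svd(base, nu = 0, nv = 1)$v[, 1]
      span_main <- diff(range(base %*% principal))
      clearance <- box$lengths - span_main
      best_axis <- if (any(clearance >= 0.2)) which.max(clearance) else 0L
      ok <- FALSE
      # chains nearly as long as the smallest box edge cannot coexist at
      # random orientations: go nematic from the first attempt
      dense_rod <- best_axis > 0L && span_main > 0.8 * min(box$lengths)
      for (att in seq_len(max_attempts)) {
        aligned <- best_axis > 0L && (dense_rod || att > max_attempts / 10)
        if (!aligned) {
          R <- quat_to_matrix(drop(random_quaternion(1)))
        } else {
          # aligned proposal: principal axis along the most spacious box
          # axis (random sign and spin, small random tilt), the nematic
          # arrangement dense elongated systems need
          target <- axes[best_axis + sample(c(0L, 3L), 1L), ]
          R <- rotation_to(principal, target) %*%
            rotation_about(principal, stats::runif(1, 0, 2 * pi))
        }
        rot <- base %*% t(R)
        mins <- apply(rot, 2, min)
        maxs <- apply(rot, 2, max)
        span <- maxs - mins
        if (any(span > box$lengths)) next
        if (!aligned || att %% 2L == 1L) {
          shift <- lo - mins + stats::runif(3) * (box$lengths - span)
        } else {
          # jittered lattice slots in the perpendicular plane: random
          # translations jam well below full occupancy for dense rod
          # systems, slots do not
          shift <- numeric(3)
          shift[best_axis] <- lo[best_axis] - mins[best_axis] +
            stats::runif(1) * (box$lengths[best_axis] - span[best_axis])
          for (ax in setdiff(1:3, best_axis)) {
            pitch <- pitch_ref
            n_slots <- max(1L, floor(box$lengths[ax] / pitch))
            margin <- box$lengths[ax] - n_slots * pitch
            k <- sample.int(n_slots, 1L) - 1L
            center <- lo[ax] + margin / 2 + (k + 0.5) * pitch +
              stats::runif(1, -0.25, 0.25)
            shift[ax] <- center - (mins[ax] + maxs[ax]) / 2
          }
        }
        cand <- sweep(rot, 2, shift, "+")
        if (nrow(placed_coords)) {
          # bounding-box prefilter before exact distances
          cl <- apply(cand, 2, min) - min_separation
          ch <- apply(cand, 2, max) + min_separation
          sel <- placed_coords[, 1] >= cl[1] & placed_coords[, 1] <= ch[1] &
            placed_coords[, 2] >= cl[2] & placed_coords[, 2] <= ch[2] &
            placed_coords[, 3] >= cl[3] & placed_coords[, 3] <= ch[3]
          if (any(sel)) {
            if (min_cross_dist(cand, placed_coords[sel, , drop = FALSE]) <
                min_separation) next
          }
        }
        mol$coords <- cand
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_gf(sprintf("packing failed: placed %d of %d chains within the attempt budget",
                        ci - 1L, length(chains)),
                "gelforge_packing_error", achieved = ci - 1L)
      }
      out[[ci]] <- mol
      placed_coords <- rbind(placed_coords, mol$coords)
    }
    out
  })
}
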