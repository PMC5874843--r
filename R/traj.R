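# Structural observables over coordinate frames: radius of gyration,
# Shrake-Rupley solvent accessible surface area, water-in-gel counting via
# a grid flood-fill envelope, guest capture at a contact distance,
# geometric hydrogen bonds, and per-frame series with block averaging.
#
# Frames are treated as whole molecules in free space; no periodic imaging
# is applied, so inputs must be pre-imaged.

#' Construct a coordinate frame
#'
#' @param coords n x 3 coordinate matrix (angstrom).
#' @param tags Per-atom component tags: `"gel"`, `"water"` or `"guest_<i>"`.
#' @param masses Per-atom masses (amu); default 1.
#' @param elements Per-atom element symbols (needed for water-oxygen
#'   selection and SASA radii); default `"C"`.
#' @param radii Per-atom van der Waals radii; default by element.
#' @param time Frame time in ns.
#' @return A `gel_frame` object.
#' @export
gel_frame <- function(coords, tags, masses = 1, elements = "C", radii = NULL,
                      time = 0) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  tags <- rep_len(as.character(tags), n)
  elements <- rep_len(as.character(elements), n)
  masses <- rep_len(as.numeric(masses), n)
  if (is.null(radii)) radii <- default_radius(elements)
  structure(list(coords = coords, tags = tags, masses = masses,
                 elements = elements, radii = rep_len(radii, n),
                 time = as.numeric(time)),
            class = "gel_frame")
}

#' @export
print.gel_frame <- function(x, ...) {
  cat(sprintf("<gel_frame> t = %g ns: %d atoms (%s)\n", x$time,
              nrow(x$coords),
              paste(sprintf("%s:%d", names(table(sub("_.*", "", x$tags))),
                            table(sub("_.*", "", x$tags))), collapse = ", ")))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames List of [gel_frame()]s with consistent atom ordering and
#'   strictly increasing times.
#' @return A `gel_trajectory`.
#' @export
gel_trajectory <- function(frames) {
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_gf("frame times must be strictly increasing", "gelforge_invalid")
  }
  structure(list(frames = frames, times = times), class = "gel_trajectory")
}

#' @export
length.gel_trajectory <- function(x) length(x$frames)

#' @export
print.gel_trajectory <- function(x, ...) {
  cat(sprintf("<gel_trajectory> %d frames, t = %g..%g ns\n",
              length(x), min(x$times), max(x$times)))
  invisible(x)
}

resolve_selection <- function(frame, selection) {
  n <- nrow(frame$coords)
  if (is.null(selection)) return(seq_len(n))
  if (is.character(selection)) {
    sel <- which(sub("_.*", "", frame$tags) %in% selection |
                   frame$tags %in% selection)
  } else if (is.logical(selection)) {
    sel <- which(rep_len(selection, n))
  } else {
    sel <- as.integer(selection)
  }
  if (!length(sel)) stop_gf("empty selection", "gelforge_invalid")
  sel
}

#' Mass-weighted radius of gyration
#'
#' `sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))` about the mass-weighted
#' centroid of the selection.
#'
#' @param frame A [gel_frame()].
#' @param selection Tag name(s), logical mask or indices; default all atoms.
#' @return RGYR in angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL) {
  sel <- resolve_selection(frame, selection)
  m <- frame$masses[sel]
  if (any(m <= 0)) stop_gf("masses must be positive", "gelforge_invalid")
  x <- frame$coords[sel, , drop = FALSE]
  cm <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, cm)^2)) / sum(m))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Each selected atom's sphere of radius `r + probe` is sampled on a
#' deterministic Fibonacci spiral lattice; points occluded by any other
#' inflated sphere are removed and the accessible fraction scales the
#' analytic sphere area.
#'
#' @param frame A [gel_frame()] (or a `molecule`).
#' @param selection Atoms to include; default all.
#' @param probe Probe radius in angstrom.
#' @param n_points Lattice points per atom.
#' @return Area in square angstrom.
#' @export
sasa <- function(frame, selection = NULL, probe = 1.4, n_points = 960L) {
  if (inherits(frame, "molecule")) {
    frame <- gel_frame(frame$coords, "gel", elements = frame$element,
                       radii = frame$radius)
  }
  sel <- resolve_selection(frame, selection)
  x <- frame$coords[sel, , drop = FALSE]
  r <- frame$radii[sel] + probe
  if (anyNA(r)) stop_gf("missing radius in selection", "gelforge_invalid")
  pts <- fibonacci_sphere(n_points)
  n <- nrow(x)
  d2 <- cross_dist2(x, x)
  total <- 0
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, x[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      acc[acc] <- rowSums(sweep(p[acc, , drop = FALSE], 2, x[j, ])^2) >= r[j]^2
    }
    total <- total + mean(acc) * 4 * pi * r[i]^2
  }
  total
}

# Occupancy-grid flood fill from the bounding-box boundary. Returns a
# function classifying points as interior (not reached by the outside
# flood and not gel-occupied) or gel cells.
gel_envelope <- function(gel_xyz, cell = 2) {
  lo <- apply(gel_xyz, 2, min) - 2 * cell
  hi <- apply(gel_xyz, 2, max) + 2 * cell
  dims <- pmax(2L, ceiling((hi - lo) / cell))
  cell_of <- function(p) {
    ix <- pmin(pmax(floor((p[, 1] - lo[1]) / cell) + 1L, 1L), dims[1])
    iy <- pmin(pmax(floor((p[, 2] - lo[2]) / cell) + 1L, 1L), dims[2])
    iz <- pmin(pmax(floor((p[, 3] - lo[3]) / cell) + 1L, 1L), dims[3])
    cbind(ix, iy, iz)
  }
  gel <- array(FALSE, dims)
  gel[cell_of(gel_xyz)] <- TRUE
  reach <- array(FALSE, dims)
  # seed the whole boundary shell
  reach[1, , ] <- TRUE; reach[dims[1], , ] <- TRUE
  reach[, 1, ] <- TRUE; reach[, dims[2], ] <- TRUE
  reach[, , 1] <- TRUE; reach[, , dims[3]] <- TRUE
  reach <- reach & !gel
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-dims[1], , ]
    grown[-dims[1], , ] <- grown[-dims[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -dims[2], ]
    grown[, -dims[2], ] <- grown[, -dims[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -dims[3]]
    grown[, , -dims[3]] <- grown[, , -dims[3]] | reach[, , -1]
    grown <- grown & !gel
    if (identical(grown, reach)) break
    reach <- grown
  }
  list(
    interior = function(p) {
      idx <- cell_of(p)
      inside_bb <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
        p[, 2] >= lo[2] & p[, 2] <= hi[2] &
        p[, 3] >= lo[3] & p[, 3] <= hi[3]
      inside_bb & !reach[idx]
    }
  )
}

#' Count water molecules in and around the gel
#'
#' Counts waters (by oxygen position) within `shell` of any gel atom plus
#' all waters inside the gel envelope, where the envelope is the set of
#' grid cells (edge `cell`) not reached by a 6-connected flood fill from
#' the bounding-box boundary.
#'
#' @param frame A [gel_frame()] with `gel` and `water` tags.
#' @param shell Surface shell distance (angstrom).
#' @param cell Envelope grid edge (angstrom).
#' @return Integer count.
#' @export
count_waters_in_gel <- function(frame, shell = 3.0, cell = 2) {
  gel <- frame$coords[frame$tags == "gel", , drop = FALSE]
  if (!nrow(gel)) stop_gf("frame has no gel atoms", "gelforge_invalid")
  wsel <- frame$tags == "water" & frame$elements == "O"
  if (!any(wsel)) wsel <- frame$tags == "water"  # coarse single-site waters
  w <- frame$coords[wsel, , drop = FALSE]
  if (!nrow(w)) return(0L)
  d2 <- cross_dist2(w, gel)
  near <- sqrt(apply(d2, 1, min)) <= shell
  env <- gel_envelope(gel, cell = cell)
  sum(near | env$interior(w))
}

#' Count captured guests
#'
#' A guest is captured in a frame when any of its atoms lies within
#' `contact` of any gel atom. On a trajectory with `persistence > 1` a
#' guest counts at frame i only when the contact holds in that many
#' consecutive frames ending at i.
#'
#' @param x A [gel_frame()] or [gel_trajectory()].
#' @param contact Contact distance in angstrom.
#' @param persistence Consecutive-frame requirement (trajectory only).
#' @return Integer count (frame) or integer vector per frame (trajectory).
#' @export
count_captured_guests <- function(x, contact = 4.5, persistence = 1L) {
  UseMethod("count_captured_guests")
}

guest_contacts <- function(frame, contact) {
  gel <- frame$coords[frame$tags == "gel", , drop = FALSE]
  guests <- unique(frame$tags[startsWith(frame$tags, "guest")])
  vapply(guests, function(g) {
    gx <- frame$coords[frame$tags == g, , drop = FALSE]
    min_cross_dist(gx, gel) <= contact
  }, logical(1))
}

#' @export
count_captured_guests.gel_frame <- function(x, contact = 4.5, persistence = 1L) {
  if (persistence != 1L) {
    stop_gf("persistence > 1 requires a trajectory", "gelforge_invalid")
  }
  sum(guest_contacts(x, contact))
}

#' @export
count_captured_guests.gel_trajectory <- function(x, contact = 4.5,
                                                 persistence = 1L) {
  hits <- vapply(x$frames, guest_contacts, contact = contact,
                 FUN.VALUE = guest_contacts(x$frames[[1]], contact))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1)
  nf <- length(x)
  out <- integer(nf)
  for (i in seq_len(nf)) {
    lo <- max(1L, i - persistence + 1L)
    if (i - lo + 1L < persistence) {
      out[i] <- 0L
    } else {
      run <- hits[, lo:i, drop = FALSE]
      out[i] <- sum(apply(run, 1, all))
    }
  }
  out
}

#' Count geometric hydrogen bonds
#'
#' A donor-hydrogen pair (D, H) and acceptor A form a bond when
#' `|D - A| <= d_max` and the D-H...A angle is at least `angle_min`
#' degrees, with D and A in different components (tags differ).
#'
#' @param frame A [gel_frame()].
#' @param donors Two-column integer matrix of (donor, hydrogen) indices.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param d_max Donor-acceptor distance cutoff (angstrom).
#' @param angle_min Minimum D-H...A angle (degrees).
#' @return Integer count.
#' @export
count_hbonds <- function(frame, donors, acceptors, d_max = 3.5,
                         angle_min = 150) {
  donors <- matrix(as.integer(donors), ncol = 2)
  if (anyNA(donors)) stop_gf("donor missing its hydrogen", "gelforge_invalid")
  if (!nrow(donors) || !length(acceptors)) return(0L)
  D <- frame$coords[donors[, 1], , drop = FALSE]
  H <- frame$coords[donors[, 2], , drop = FALSE]
  A <- frame$coords[acceptors, , drop = FALSE]
  da <- sqrt(cross_dist2(D, A))
  comp_d <- frame$tags[donors[, 1]]
  comp_a <- frame$tags[acceptors]
  count <- 0L
  for (i in seq_len(nrow(donors))) {
    cand <- which(da[i, ] <= d_max & comp_a != comp_d[i])
    if (!length(cand)) next
    hd <- D[i, ] - H[i, ]
    for (j in cand) {
      ha <- A[j, ] - H[i, ]
      cosang <- sum(hd * ha) / (vec_norm(hd) * vec_norm(ha))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= angle_min) count <- count + 1L
    }
  }
  count
}

#' Evaluate an observable along a trajectory
#'
#' @param traj A [gel_trajectory()].
#' @param observable One of `"rgyr"`, `"sasa"`, `"waters"`, `"captures"`,
#'   `"hbonds"`.
#' @param ... Passed to the per-frame observable function.
#' @return An `observable_series` with fields `times`, `values`, `name`.
#' @export
observable_series <- function(traj, observable, ...) {
  fn <- switch(observable,
               rgyr = radius_of_gyration,
               sasa = sasa,
               waters = count_waters_in_gel,
               captures = count_captured_guests,
               hbonds = count_hbonds,
               stop_gf(sprintf("unknown observable '%s'", observable),
                       "gelforge_invalid"))
  if (!length(traj)) stop_gf("empty trajectory", "gelforge_invalid")
  values <- vapply(traj$frames, function(f) as.numeric(fn(f, ...)), numeric(1))
  structure(list(times = traj$times, values = values, name = observable),
            class = "observable_series")
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("<observable_series '%s'> %d frames, mean %.4g\n",
              x$name, length(x$values), mean(x$values)))
  invisible(x)
}

#' Block average of an observable series
#'
#' Splits the series into `n_blocks` contiguous equal blocks (remainder
#' into the last block); reports the overall mean and the standard error
#' of the block means. With one block the SE is `NA`.
#'
#' @param series An [observable_series()] (or numeric vector).
#' @param n_blocks Number of blocks (>= 1).
#' @return List with `mean`, `se`, `block_means`.
#' @export
block_average <- function(series, n_blocks = 5L) {
  v <- if (inherits(series, "observable_series")) series$values else as.numeric(series)
  if (n_blocks < 1L) stop_gf("n_blocks must be >= 1", "gelforge_invalid")
  n <- length(v)
  if (!n) stop_gf("empty series", "gelforge_invalid")
  n_blocks <- min(n_blocks, n)
  size <- n %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, n)
  bm <- vapply(seq_len(n_blocks), function(b) mean(v[starts[b]:ends[b]]),
               numeric(1))
  list(mean = mean(v),
       se = if (n_blocks > 1L) stats::sd(bm) / sqrt(n_blocks) else NA_real_,
       block_means = bm)
}

#' Hydrogel model as a coordinate frame
#'
#' Tags chain/bridge/CD atoms `"gel"` and each guest `"guest_<i>"`; masses
#' are standard atomic weights.
#'
#' @param mdl A `hydrogel_model`.
#' @param time Frame time (ns).
#' @return A [gel_frame()].
#' @export
model_frame <- function(mdl, time = 0) {
  a <- mdl$atoms
  tags <- ifelse(a$unit == "guest", paste0("guest_", a$unit_id), "gel")
  gel_frame(flat_coords(a), tags,
            masses = atomic_weights()[a$element],
            elements = a$element, radii = a$radius, time = time)
}
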