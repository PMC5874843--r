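# Synthetic-data generators with known ground truth: a toy ring host with
# an open cavity, rod guests with end markers, gel/water/guest frames with
# known category counts, factorial response tables, and biphasic release
# curves. Every generator is deterministic under a fixed seed and verifies
# its ground truth by brute-force distance checks after construction.

#' Build a toy ring host with an open cavity
#'
#' Two coaxial rings of Lennard-Jones sites in parallel planes form a
#' torus-like cavity around the origin: the stand-in for a cyclodextrin
#' cavity in screening tests. The cavity frame matches the construction
#' exactly.
#'
#' @param rim_radius Ring radius (angstrom), must exceed `atom_radius`.
#' @param n_rim_atoms Sites per ring (>= 6).
#' @param atom_radius Site van der Waals radius.
#' @param axial_thickness Axial separation of the two rings.
#' @return A `molecule` with attribute `frame` (its [cavity_frame()]).
#' @export
make_toy_host <- function(rim_radius = 5, n_rim_atoms = 16L, atom_radius = 1.7,
                          axial_thickness = 1.2) {
  if (n_rim_atoms < 6L) stop_gf("need at least 6 rim atoms", "gelforge_invalid")
  if (rim_radius <= atom_radius) {
    stop_gf("cavity closed: rim_radius must exceed atom_radius", "gelforge_invalid")
  }
  phi <- 2 * pi * (seq_len(n_rim_atoms) - 1L) / n_rim_atoms
  ring <- cbind(rim_radius * cos(phi), rim_radius * sin(phi), 0)
  coords <- rbind(sweep(ring, 2, c(0, 0, axial_thickness / 2), "+"),
                  sweep(ring, 2, c(0, 0, -axial_thickness / 2), "+"))
  mol <- molecule(rep("C", 2L * n_rim_atoms), coords, radius = atom_radius,
                  role = "host", name = "toy-host")
  attr(mol, "frame") <- cavity_frame(c(0, 0, 0), c(0, 0, -1), rim_radius)
  mol
}

#' Build a rod guest with end markers
#'
#' Linear chain of Lennard-Jones sites along the x axis, centered at the
#' origin, with disjoint `end_A`/`end_B` marker sets (first and last site).
#'
#' @param length Rod length (angstrom), must exceed the site spacing.
#' @param spacing Site spacing (angstrom).
#' @return A `molecule` with attribute `markers` (list `end_A`, `end_B`).
#' @export
make_rod_guest <- function(length = 6, spacing = 1.5) {
  if (length <= 0) stop_gf("length must be positive", "gelforge_invalid")
  n <- floor(length / spacing) + 1L
  if (n < 2L) stop_gf("rod too short for two marker sites", "gelforge_invalid")
  x <- seq(0, by = spacing, length.out = n)
  coords <- cbind(x - mean(x), 0, 0)
  mol <- molecule(rep("C", n), coords, role = "guest", name = "rod-guest")
  attr(mol, "markers") <- list(end_A = 1L, end_B = n)
  mol
}

#' Generate a synthetic trajectory with known category counts
#'
#' Builds a hollow spherical-shell gel and places the requested numbers of
#' waters inside/outside the envelope and guests in/out of capture
#' contact, applies Gaussian jitter, and re-draws (up to 100 attempts)
#' until brute-force distance checks confirm every category assignment.
#' The ground truth ships with the trajectory.
#'
#' @param n_frames Number of frames.
#' @param n_waters_inside,n_waters_outside Water counts by category.
#' @param n_guests_captured,n_guests_free Guest counts by category.
#' @param jitter Coordinate noise sigma (angstrom).
#' @param shell_radius Gel shell radius (angstrom).
#' @param contact Capture contact distance used for construction.
#' @param seed Integer seed.
#' @return A [gel_trajectory()] with attribute `truth` (list of the four
#'   counts and the construction parameters).
#' @export
make_trajectory <- function(n_frames = 5L, n_waters_inside = 7L,
                            n_waters_outside = 5L, n_guests_captured = 12L,
                            n_guests_free = 18L, jitter = 0.1,
                            shell_radius = 8, contact = 4.5, seed = 1L) {
  stopifnot(n_frames >= 1, n_waters_inside >= 0, n_waters_outside >= 0,
            n_guests_captured >= 0, n_guests_free >= 0, jitter >= 0)
  gel0 <- fibonacci_sphere(900) * shell_radius
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      ok <- FALSE
      for (att in 1:100) {
        # waters inside: well within the shell; outside: far away
        wi <- if (n_waters_inside) {
          u <- fibonacci_sphere(max(n_waters_inside, 2))[seq_len(n_waters_inside), , drop = FALSE]
          u * (shell_radius * 0.4)
        } else matrix(numeric(0), 0, 3)
        wo <- if (n_waters_outside) {
          u <- fibonacci_sphere(max(n_waters_outside, 2))[seq_len(n_waters_outside), , drop = FALSE]
          u * (shell_radius + 3 + 8)
        } else matrix(numeric(0), 0, 3)
        gc_ <- if (n_guests_captured) {
          u <- fibonacci_sphere(max(n_guests_captured, 2))[seq_len(n_guests_captured), , drop = FALSE]
          u * (shell_radius + 0.5 * contact)
        } else matrix(numeric(0), 0, 3)
        gf <- if (n_guests_free) {
          u <- fibonacci_sphere(max(n_guests_free, 2))[seq_len(n_guests_free), , drop = FALSE]
          u * (shell_radius + contact + 10)
        } else matrix(numeric(0), 0, 3)
        gel <- gel0
        coords <- rbind(gel, wi, wo, gc_, gf)
        if (jitter > 0) {
          coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter),
                                    ncol = 3)
        }
        ng <- nrow(gel)
        tags <- c(rep("gel", ng),
                  rep("water", n_waters_inside + n_waters_outside),
                  if (n_guests_captured + n_guests_free)
                    paste0("guest_", seq_len(n_guests_captured + n_guests_free)))
        gx <- coords[seq_len(ng), , drop = FALSE]
        # brute-force category verification, independent of the counters
        wrows <- ng + seq_len(n_waters_inside + n_waters_outside)
        grows <- ng + n_waters_inside + n_waters_outside +
          seq_len(n_guests_captured + n_guests_free)
        wr <- sqrt(rowSums(coords[wrows, , drop = FALSE]^2))
        w_inside_ok <- all(wr[seq_len(n_waters_inside)] < shell_radius - 2)
        w_outside_ok <- if (n_waters_outside) {
          out_rows <- wrows[n_waters_inside + seq_len(n_waters_outside)]
          all(vapply(out_rows, function(r) {
            min_cross_dist(coords[r, , drop = FALSE], gx) > 3 + 2
          }, logical(1))) && all(wr[n_waters_inside + seq_len(n_waters_outside)] > shell_radius + 4)
        } else TRUE
        g_cap_ok <- all(vapply(seq_len(n_guests_captured), function(i) {
          min_cross_dist(coords[grows[i], , drop = FALSE], gx) <= contact - 0.2
        }, logical(1)))
        g_free_ok <- all(vapply(seq_len(n_guests_free), function(i) {
          min_cross_dist(coords[grows[n_guests_captured + i], , drop = FALSE],
                         gx) > contact + 2
        }, logical(1)))
        if (w_inside_ok && w_outside_ok && g_cap_ok && g_free_ok) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop_gf("jitter too large to satisfy category assignments after 100 attempts",
                "gelforge_invalid")
      }
      frames[[f]] <- gel_frame(coords, tags, elements = ifelse(tags == "water", "O", "C"),
                               time = f - 1)
    }
    traj <- gel_trajectory(frames)
    attr(traj, "truth") <- list(
      n_waters_inside = n_waters_inside, n_waters_outside = n_waters_outside,
      n_guests_captured = n_guests_captured, n_guests_free = n_guests_free,
      shell_radius = shell_radius, contact = contact, jitter = jitter
    )
    traj
  })
}

#' Table-layout presets for the factorial generator
#'
#' `"2x2"`: full 2^2 design at coded -1/+1. `"release"`: the 6-cell layout
#' of the packaged release experiment (4 A levels x 4 B levels with
#' replicate counts 2/2/6/6/2/2).
#'
#' @param preset `"2x2"` or `"release"`.
#' @return data.frame of coded `A`, `B` cells with a `replicates` column.
#' @export
factorial_layout <- function(preset = c("2x2", "release")) {
  preset <- match.arg(preset)
  if (preset == "2x2") {
    data.frame(A = c(-1, -1, 1, 1), B = c(-1, 1, -1, 1), replicates = 1L)
  } else {
    data.frame(
      A = c(-1, -1, -0.4637, 0.0462, 1, 1),
      B = c(-1, 1, -0.70213, 0, -1, 1),
      replicates = c(2L, 2L, 6L, 6L, 2L, 2L)
    )
  }
}

#' Generate a factorial response table with known coefficients
#'
#' `y = b0 + b1 A + b2 B + b3 A B + Normal(0, sigma)` on coded levels;
#' natural columns are emitted via [decode_factor()] over the stated
#' ranges.
#'
#' @param b Length-4 coefficient vector `(b0, b1, b2, b3)`.
#' @param layout Cell layout from [factorial_layout()] (or compatible).
#' @param replicates Replicates per cell; `NULL` uses the layout column.
#' @param sigma Noise standard deviation (>= 0).
#' @param ranges List with `A = c(min, max)`, `B = c(min, max)` for the
#'   natural columns.
#' @param seed Integer seed.
#' @return data.frame with columns `natural_A`, `natural_B`, `A`, `B`,
#'   `response`; attribute `truth` holds `b` and `sigma`.
#' @export
make_factorial_table <- function(b = c(69.95, 30.66, 0, 5.53),
                                 layout = factorial_layout("release"),
                                 replicates = NULL, sigma = 0,
                                 ranges = list(A = c(0, 9.1), B = c(1, 48)),
                                 seed = 1L) {
  stopifnot(length(b) == 4L, sigma >= 0)
  reps <- replicates %||% layout$replicates %||% 1L
  reps <- rep_len(reps, nrow(layout))
  if (any(reps < 1L)) stop_gf("need >= 1 replicate per cell", "gelforge_invalid")
  A <- rep(layout$A, reps)
  B <- rep(layout$B, reps)
  with_seed(seed, {
    y <- b[1] + b[2] * A + b[3] * B + b[4] * A * B +
      stats::rnorm(length(A), 0, sigma)
    out <- data.frame(
      natural_A = decode_factor(A, ranges$A[1], ranges$A[2]),
      natural_B = decode_factor(B, ranges$B[1], ranges$B[2]),
      A = A, B = B, response = y
    )
    attr(out, "truth") <- list(b = b, sigma = sigma)
    out
  })
}

#' Generate a biphasic release curve with known burst and slope
#'
#' Saturating-exponential burst phase reaching `burst` percent exactly at
#' `burst_window`, joined continuously to a linear zero-order phase of the
#' stated slope, plus optional Gaussian noise.
#'
#' @param burst Burst release at the end of the burst window (percent).
#' @param slope Zero-order slope (percent per hour).
#' @param times Sampling times (h), strictly increasing.
#' @param sigma Noise standard deviation (percent).
#' @param burst_window Burst phase duration (h).
#' @param seed Integer seed.
#' @return data.frame `time_h`, `released_pct`; attribute `truth` holds the
#'   generating parameters.
#' @export
make_release_curve <- function(burst = 60, slope = 1.2,
                               times = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 13, 25),
                               sigma = 0, burst_window = 2, seed = 1L) {
  if (burst + slope * max(times) > 100 + 2) {
    stop_gf("curve would exceed 100% release", "gelforge_invalid")
  }
  k <- 3 / burst_window
  base <- ifelse(times <= burst_window,
                 burst * (1 - exp(-k * times)) / (1 - exp(-k * burst_window)),
                 burst + slope * (times - burst_window))
  with_seed(seed, {
    y <- base + if (sigma > 0) stats::rnorm(length(times), 0, sigma) else 0
    out <- data.frame(time_h = times, released_pct = y)
    attr(out, "truth") <- list(burst = burst, slope = slope, sigma = sigma,
                               burst_window = burst_window)
    out
  })
}
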