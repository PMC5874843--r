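# Rigid-body orientation sampling of a guest around a host, ensemble
# energy statistics, lowest-k selection and geometric inclusion labels.

#' Sample rigid-body guest poses around a host
#'
#' Rotations are uniform on SO(3) (subgroup-algorithm quaternions);
#' translations are uniform over a spherical shell around the host
#' centroid, measured centroid to centroid.
#'
#' @param host,guest `molecule` objects.
#' @param n Number of poses.
#' @param shell Length-2 vector `c(r_min, r_max)` in angstrom. Default:
#'   0 to (host radius + guest radius + 5).
#' @param seed Integer seed; identical seeds give identical pose sets.
#' @return A `pose_set`: unit quaternions (`$q`, n x 4, x/y/z/w order) and
#'   translations (`$t`, n x 3).
#' @export
sample_orientations <- function(host, guest, n, shell = NULL, seed = NULL) {
  stopifnot(n >= 0)
  if (is.null(shell)) {
    r_host <- if (n_atoms(host)) max(sqrt(rowSums(sweep(host$coords, 2, centroid(host))^2))) else 0
    r_guest <- if (n_atoms(guest)) max(sqrt(rowSums(sweep(guest$coords, 2, centroid(guest))^2))) else 0
    shell <- c(0, r_host + r_guest + 5)
  }
  if (shell[1] < 0 || shell[2] < shell[1]) {
    stop_gf("shell must satisfy 0 <= r_min <= r_max", "gelforge_invalid")
  }
  with_seed(seed, {
    if (n == 0L) {
      return(structure(list(q = matrix(numeric(0), 0, 4),
                            t = matrix(numeric(0), 0, 3)), class = "pose_set"))
    }
    q <- random_quaternion(n)
    dir <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- (shell[1]^3 + stats::runif(n) * (shell[2]^3 - shell[1]^3))^(1 / 3)
    structure(list(q = q, t = dir * r), class = "pose_set")
  })
}

#' @export
length.pose_set <- function(x) nrow(x$q)

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses\n", length(x)))
  invisible(x)
}

#' Place a guest according to a pose
#'
#' Rotates the guest about its centroid by the pose quaternion and moves
#' its centroid to `host centroid + translation`.
#'
#' @param guest A `molecule`.
#' @param poses A `pose_set`.
#' @param i Pose index.
#' @param host_centroid Length-3 reference point.
#' @return The posed `molecule`.
#' @export
apply_pose <- function(guest, poses, i, host_centroid = c(0, 0, 0)) {
  R <- quat_to_matrix(poses$q[i, ])
  g <- transform_molecule(guest, rotation = R)
  shift <- host_centroid + poses$t[i, ] - centroid(g)
  g$coords <- sweep(g$coords, 2, shift, "+")
  g
}

#' Screen guest orientations against a host
#'
#' Samples `n` rigid poses, evaluates the supermolecular interaction energy
#' of each, and reports the ensemble mean, its standard error, and the
#' lowest-`k` subset sorted ascending by energy (ties broken by pose index).
#'
#' @param host,guest `molecule` objects.
#' @param model An [energy_model()].
#' @param n Number of poses.
#' @param k Size of the lowest-energy subset (`k <= n`).
#' @param shell,seed Passed to [sample_orientations()].
#' @return An `hg_screen` object with fields `energies`, `poses`, `mean`,
#'   `se`, `lowest` (data.frame `pose`, `energy`), `host`, `guest`.
#' @export
screen <- function(host, guest, model = energy_model(), n = 1000L,
                   k = min(100L, n), shell = NULL, seed = NULL) {
  stopifnot(n >= k, k >= 0)
  poses <- sample_orientations(host, guest, n, shell = shell, seed = seed)
  hc <- centroid(host)
  ph <- lj_atom_params(model, host$element)
  pg <- lj_atom_params(model, guest$element)
  g0 <- sweep(guest$coords, 2, centroid(guest))
  energies <- numeric(n)
  for (i in seq_len(n)) {
    gi <- g0 %*% t(quat_to_matrix(poses$q[i, ]))
    gi <- sweep(gi, 2, hc + poses$t[i, ], "+")
    energies[i] <- pair_energy_sum(model, host$coords, ph, host$charge,
                                   gi, pg, guest$charge)
  }
  if (any(!is.finite(energies))) {
    stop_gf("non-finite interaction energy during screening", "gelforge_energy_error")
  }
  ord <- order(energies, seq_along(energies))[seq_len(k)]
  structure(list(
    energies = energies,
    poses = poses,
    mean = if (n) mean(energies) else NA_real_,
    se = if (n > 1) stats::sd(energies) / sqrt(n) else 0,
    lowest = data.frame(pose = ord, energy = energies[ord]),
    n = n, k = k, host = host, guest = guest
  ), class = "hg_screen")
}

#' @export
print.hg_screen <- function(x, ...) {
  cat(sprintf("<hg_screen> %d poses: mean dE = %.4f +/- %.4f kcal/mol; lowest-%d kept\n",
              x$n, x$mean, x$se, x$k))
  invisible(x)
}

#' @export
summary.hg_screen <- function(object, ...) {
  data.frame(n = object$n, mean = object$mean, se = object$se,
             min = min(object$energies), max = max(object$energies))
}

#' Export a screening ensemble
#'
#' Writes a CSV of pose id, quaternion, translation, energy (and inclusion
#' label when supplied) plus a multi-model XYZ of the lowest-k complexes.
#'
#' @param scr An `hg_screen`.
#' @param csv,xyz Output paths (either may be `NULL` to skip).
#' @param labels Optional per-pose inclusion labels.
#' @return Invisibly, the CSV path.
#' @export
export_screen <- function(scr, csv = NULL, xyz = NULL, labels = NULL) {
  if (!is.null(csv)) {
    df <- data.frame(
      pose = seq_len(scr$n),
      qx = signif(scr$poses$q[, 1], 6), qy = signif(scr$poses$q[, 2], 6),
      qz = signif(scr$poses$q[, 3], 6), qw = signif(scr$poses$q[, 4], 6),
      tx = signif(scr$poses$t[, 1], 6), ty = signif(scr$poses$t[, 2], 6),
      tz = signif(scr$poses$t[, 3], 6),
      energy = signif(scr$energies, 6)
    )
    if (!is.null(labels)) df$label <- labels
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(xyz)) {
    hc <- centroid(scr$host)
    frames <- lapply(scr$lowest$pose, function(i) {
      combine_molecules(scr$host, apply_pose(scr$guest, scr$poses, i, hc),
                        name = sprintf("pose %d dE %.6f", i, scr$energies[i]))
    })
    write_xyz_frames(frames, xyz)
  }
  invisible(csv)
}

#' A cyclodextrin cavity reference frame
#'
#' @param center Cavity center (angstrom).
#' @param axis Unit vector oriented from the secondary to the primary face.
#' @param rim_radius Rim radius in angstrom (positive).
#' @return A `cavity_frame` object.
#' @export
cavity_frame <- function(center, axis, rim_radius) {
  if (vec_norm(axis) < .Machine$double.eps) {
    stop_gf("degenerate cavity axis", "gelforge_invalid")
  }
  if (rim_radius <= 0) stop_gf("rim_radius must be positive", "gelforge_invalid")
  structure(list(center = as.numeric(center), axis = normalize(axis),
                 rim_radius = rim_radius), class = "cavity_frame")
}

#' Cavity frame of a (built) cyclodextrin
#'
#' Center: centroid of the glycosidic oxygens. Axis: normal of their
#' best-fit plane, oriented so the secondary-hydroxyl rim sits at negative
#' depth. Rim radius: mean in-plane distance of the glycosidic oxygens.
#'
#' @param cd A cyclodextrin `molecule` with `glycosidic-O`, `secondary-OH`
#'   and `primary-OH` role tags (see [build_cyclodextrin()]).
#' @return A [cavity_frame()].
#' @export
cd_cavity_frame <- function(cd) {
  gly <- cd$coords[cd$role == "glycosidic-O", , drop = FALSE]
  if (nrow(gly) < 3L) stop_gf("need >= 3 glycosidic oxygens", "gelforge_invalid")
  center <- colMeans(gly)
  sv <- svd(sweep(gly, 2, center))
  axis <- sv$v[, 3]
  sec <- cd$coords[cd$role == "secondary-OH", , drop = FALSE]
  if (nrow(sec) && mean(sweep(sec, 2, center) %*% axis) > 0) axis <- -axis
  inplane <- sweep(gly, 2, center)
  inplane <- inplane - outer(drop(inplane %*% axis), axis)
  cavity_frame(center, axis, mean(sqrt(rowSums(inplane^2))))
}

#' Classify a host-guest inclusion pose
#'
#' A pose counts as an inclusion when any guest atom projects inside the
#' cavity cylinder (radius = rim radius, axial extent +/- `axial_extent`
#' around the center). Included poses are labelled `"A"` when the `end_A`
#' marker centroid sits deeper along the secondary-to-primary axis than the
#' `end_B` centroid, `"B"` otherwise.
#'
#' @param host_frame A [cavity_frame()].
#' @param guest_posed The posed guest `molecule`.
#' @param markers List with non-empty disjoint integer vectors `end_A`,
#'   `end_B` of guest atom indices.
#' @param axial_extent Half-length of the cavity cylinder (angstrom).
#' @return `"A"`, `"B"`, or `"none"`.
#' @export
classify_inclusion <- function(host_frame, guest_posed, markers,
                               axial_extent = 4) {
  stopifnot(inherits(host_frame, "cavity_frame"))
  a <- markers$end_A; b <- markers$end_B
  if (!length(a) || !length(b) || length(intersect(a, b))) {
    stop_gf("marker sets must be non-empty and disjoint", "gelforge_invalid")
  }
  rel <- sweep(guest_posed$coords, 2, host_frame$center)
  depth <- drop(rel %*% host_frame$axis)
  radial <- sqrt(pmax(0, rowSums(rel^2) - depth^2))
  inside <- abs(depth) <= axial_extent & radial <= host_frame$rim_radius
  if (!any(inside)) return("none")
  depth_a <- mean(depth[a])
  depth_b <- mean(depth[b])
  if (depth_a > depth_b) "A" else "B"
}

#' Rank candidate conjugates by mean interaction energy
#'
#' Screens each candidate against the same host with an identical pose
#' budget and seed policy, and tabulates mean interaction energy with its
#' standard error, sorted ascending (most attractive first).
#'
#' @param conjugates Named list of guest `molecule`s.
#' @param host Host `molecule`.
#' @param model An [energy_model()].
#' @param n Poses per candidate.
#' @param shell,seed Shared sampling policy (every candidate uses `seed`).
#' @return data.frame with columns `id`, `name`, `mean`, `se`, sorted by
#'   `mean`.
#' @export
rank_candidates <- function(conjugates, host, model = energy_model(),
                            n = 1000L, shell = NULL, seed = NULL) {
  if (!length(conjugates)) stop_gf("empty candidate list", "gelforge_invalid")
  nm <- names(conjugates) %||% as.character(seq_along(conjugates))
  res <- lapply(conjugates, function(g) {
    s <- screen(host, g, model, n = n, k = 0L, shell = shell, seed = seed)
    c(mean = s$mean, se = s$se)
  })
  tab <- data.frame(
    name = nm,
    mean = vapply(res, `[[`, numeric(1), "mean"),
    se = vapply(res, `[[`, numeric(1), "se")
  )
  tab <- tab[order(tab$mean), , drop = FALSE]
  tab <- data.frame(id = seq_len(nrow(tab)), tab, row.names = NULL)
  tab
}
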