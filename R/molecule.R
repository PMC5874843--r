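# The molecule container: an ordered atom table plus bond topology.
# This is the structural currency every other module consumes.

#' Construct a molecule
#'
#' @param element Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in angstrom.
#' @param bonds Two-column integer matrix of atom-index pairs (may have 0 rows).
#' @param charge Partial charges in elementary-charge units (default 0).
#' @param radius Van der Waals radii in angstrom; defaults to Bondi values by
#'   element.
#' @param role Free-text per-atom role tags (e.g. `"hydroxyl-O"`, `"water-O"`).
#' @param name Molecule identifier.
#' @return A `molecule` object.
#' @export
molecule <- function(element, coords, bonds = matrix(integer(0), ncol = 2),
                     charge = 0, radius = NULL, role = "", name = "mol") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(element)
  stopifnot(nrow(coords) == n)
  if (is.null(radius)) radius <- default_radius(element)
  radius <- rep_len(radius, n)
  if (any(radius <= 0)) stop_gf("atomic radii must be positive", "gelforge_invalid")
  known <- names(atomic_weights())
  bad <- setdiff(unique(element), known)
  if (length(bad)) {
    stop_gf(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
            "gelforge_invalid")
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n)) stop_gf("bond index out of range", "gelforge_invalid")
    if (any(bonds[, 1] == bonds[, 2])) stop_gf("self-bonds are not allowed", "gelforge_invalid")
  }
  structure(list(
    name = name,
    element = as.character(element),
    coords = unname(coords),
    charge = rep_len(as.numeric(charge), n),
    radius = radius,
    role = rep_len(as.character(role), n),
    bonds = bonds
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s'> %d atoms, %d bonds (%s)\n",
              x$name, n_atoms(x), nrow(x$bonds), format(mol_formula(x))))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' Geometric centroid of a molecule
#' @param mol A `molecule`.
#' @return Length-3 numeric vector (angstrom).
#' @export
centroid <- function(mol) colMeans(mol$coords)

#' Molecular formula of a molecule
#' @param mol A `molecule`.
#' @return A `chem_formula`.
#' @export
mol_formula <- function(mol) {
  tab <- table(mol$element)
  parse_formula(paste0(names(tab), as.integer(tab), collapse = ""))
}

#' Rigidly transform a molecule
#'
#' Rotates about the molecule's centroid, then translates.
#'
#' @param mol A `molecule`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 shift in angstrom (default none).
#' @param about Rotation center; defaults to the centroid.
#' @return The transformed `molecule`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0),
                               about = centroid(mol)) {
  shifted <- sweep(mol$coords, 2, about)
  mol$coords <- sweep(shifted %*% t(rotation), 2, about + translation, "+")
  mol
}

#' Concatenate molecules into one system
#'
#' Atom order is preserved; bond indices are offset.
#'
#' @param ... `molecule` objects (or a single list of them).
#' @param name Name for the combined system.
#' @return A `molecule`.
#' @export
combine_molecules <- function(..., name = "complex") {
  mols <- list(...)
  if (length(mols) == 1L && !inherits(mols[[1]], "molecule")) mols <- mols[[1]]
  offset <- 0L
  bonds <- list()
  for (i in seq_along(mols)) {
    b <- mols[[i]]$bonds
    if (nrow(b)) bonds[[length(bonds) + 1L]] <- b + offset
    offset <- offset + n_atoms(mols[[i]])
  }
  molecule(
    element = unlist(lapply(mols, `[[`, "element")),
    coords = do.call(rbind, lapply(mols, `[[`, "coords")),
    bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2),
    charge = unlist(lapply(mols, `[[`, "charge")),
    radius = unlist(lapply(mols, `[[`, "radius")),
    role = unlist(lapply(mols, `[[`, "role")),
    name = name
  )
}

#' Connected components of a molecule's bond graph
#' @param mol A `molecule`.
#' @return Integer vector of component labels, one per atom.
#' @export
connected_components <- function(mol) {
  n <- n_atoms(mol)
  labels <- seq_len(n)
  find <- function(i) {
    while (labels[i] != i) {
      labels[i] <<- labels[labels[i]]
      i <- labels[i]
    }
    i
  }
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- find(mol$bonds[k, 1]); b <- find(mol$bonds[k, 2])
      if (a != b) labels[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' An axis-aligned orthorhombic simulation box
#'
#' @param lengths Length-3 edge lengths in angstrom (all positive).
#' @param origin Corner position (default the coordinate origin).
#' @return A `sim_box` object.
#' @export
#' @examples
#' sim_box(c(90, 80, 100))
sim_box <- function(lengths, origin = c(0, 0, 0)) {
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) == 3L, length(origin) == 3L)
  if (any(lengths <= 0)) stop_gf("box lengths must be positive", "gelforge_invalid")
  structure(list(lengths = lengths, origin = as.numeric(origin)), class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("<sim_box> %.1f x %.1f x %.1f A at (%.1f, %.1f, %.1f)\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}
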