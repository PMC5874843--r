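# Pluggable rigid-geometry energy model: Lennard-Jones + Coulomb.
#
# The screening pipeline only requires a map from a set of molecules with
# fixed internal geometry to a total energy in kcal/mol. The bundled
# implementation sums pairwise 12-6 Lennard-Jones terms under
# Lorentz-Berthelot mixing plus Coulomb terms with k_e = 332.0636
# kcal A / (mol e^2). Distances below `r_cap` are clamped to the value at
# the cap so random rigid sampling never produces unbounded energies.

#' Default per-element Lennard-Jones parameters
#'
#' Sigma in angstrom, epsilon in kcal/mol. Elements missing from the table
#' fall back to the `"*"` row.
#'
#' @return data.frame with columns `element`, `sigma`, `epsilon`.
#' @export
default_lj_params <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P", "*"),
    sigma = c(2.50, 3.40, 3.25, 3.00, 3.55, 3.74, 3.40),
    epsilon = c(0.030, 0.086, 0.170, 0.170, 0.250, 0.200, 0.050)
  )
}

#' Construct a Lennard-Jones + Coulomb energy model
#'
#' @param lj Per-element parameter table as in [default_lj_params()].
#' @param ke Coulomb constant, kcal A / (mol e^2).
#' @param eps_r Relative permittivity (dimensionless).
#' @param r_cap Distance floor in angstrom: pair energies below it are
#'   clamped to their value at the cap.
#' @return An `energy_model` object.
#' @export
energy_model <- function(lj = default_lj_params(), ke = 332.0636,
                         eps_r = 1, r_cap = 0.5) {
  stopifnot(all(c("element", "sigma", "epsilon") %in% names(lj)),
            eps_r > 0, r_cap >= 0)
  structure(list(lj = lj, ke = ke, eps_r = eps_r, r_cap = r_cap),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> LJ + Coulomb (ke = %.4f, eps_r = %g, r_cap = %g A)\n",
              x$ke, x$eps_r, x$r_cap))
  invisible(x)
}

# Per-atom sigma/epsilon lookup with "*" fallback.
lj_atom_params <- function(model, element) {
  i <- match(element, model$lj$element)
  fallback <- match("*", model$lj$element)
  if (anyNA(i)) {
    if (is.na(fallback)) {
      stop_gf(sprintf("no LJ parameters for element(s): %s",
                      paste(unique(element[is.na(i)]), collapse = ", ")),
              "gelforge_energy_error")
    }
    i[is.na(i)] <- fallback
  }
  list(sigma = model$lj$sigma[i], epsilon = model$lj$epsilon[i])
}

# Summed pair energy between coordinate sets a and b (all cross pairs).
# With b == NULL, sums the unordered pairs within a.
pair_energy_sum <- function(model, a, pa, qa, b = NULL, pb = NULL, qb = NULL) {
  self <- is.null(b)
  if (self) { b <- a; pb <- pa; qb <- qa }
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  d <- sqrt(cross_dist2(a, b))
  if (self) diag(d) <- Inf
  d[d < model$r_cap] <- model$r_cap
  sij <- outer(pa$sigma, pb$sigma, "+") / 2
  eij <- sqrt(outer(pa$epsilon, pb$epsilon))
  x6 <- (sij / d)^6
  e <- sum(4 * eij * (x6 * x6 - x6)) +
    model$ke / model$eps_r * sum(outer(qa, qb) / d)
  if (self) e / 2 else e
}

#' Total energy of a molecular system
#'
#' Sums every unordered atom pair of the combined system (the empty system
#' has energy zero). Invariant under global rotation and translation.
#'
#' @param model An [energy_model()].
#' @param mols A `molecule` or list of molecules.
#' @return Energy in kcal/mol.
#' @export
total_energy <- function(model, mols) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (!length(mols)) return(0)
  sys <- if (length(mols) == 1L) mols[[1]] else combine_molecules(mols)
  if (n_atoms(sys) == 0L) return(0)
  p <- lj_atom_params(model, sys$element)
  pair_energy_sum(model, sys$coords, p, sys$charge)
}

#' Supermolecular interaction energy
#'
#' Interaction energy of a posed guest with a host at fixed internal
#' geometries: the complex energy minus the energies of the isolated parts,
#' each from its own model evaluation. For rigid fragments this equals the
#' direct inter-fragment pair sum (see [cross_energy()]).
#'
#' @param host,guest_posed `molecule` objects in their interaction geometry.
#' @param model An [energy_model()].
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(host, guest_posed, model = energy_model()) {
  e <- total_energy(model, list(host, guest_posed)) -
    (total_energy(model, host) + total_energy(model, guest_posed))
  if (!is.finite(e)) {
    stop_gf("energy model returned a non-finite value", "gelforge_energy_error")
  }
  e
}

#' Direct inter-fragment pair energy
#'
#' Sums pair terms between the two fragments only; the independent route to
#' the supermolecular interaction energy for rigid fragments.
#'
#' @inheritParams interaction_energy
#' @return Energy in kcal/mol.
#' @export
cross_energy <- function(host, guest_posed, model = energy_model()) {
  pa <- lj_atom_params(model, host$element)
  pb <- lj_atom_params(model, guest_posed$element)
  pair_energy_sum(model, host$coords, pa, host$charge,
                  guest_posed$coords, pb, guest_posed$charge)
}
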