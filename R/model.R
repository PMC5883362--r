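## Domain types: particle systems, collective-variable definitions,
## simulation parameters, and the distance geometry shared by the sampler
## and the analysis pipeline.

#' Construct a particle system
#'
#' The basic container for a simulated molecular system: coordinates,
#' masses, partial charges and residue bookkeeping for every atom, plus the
#' receptor/ligand partition on which both the enhanced sampling layer and
#' the contact analysis operate.
#'
#' @param positions numeric n x 3 matrix of coordinates (Angstrom).
#' @param masses per-atom masses (amu), strictly positive.
#' @param role character vector, each entry `"receptor"` or `"ligand"`.
#' @param charges per-atom partial charges (elementary charge units);
#'   defaults to zero.
#' @param residue_index integer residue number per atom (1-based, PDB
#'   convention); must be non-decreasing within each role partition.
#'   Defaults to one residue per atom, numbered separately per role.
#' @param residue_name,atom_name per-atom labels (recycled).
#' @param bonds optional two-column integer matrix of bonded atom index
#'   pairs (used by the toy chain models).
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(positions, masses, role, charges = NULL,
                            residue_index = NULL, residue_name = "RES",
                            atom_name = "CA", bonds = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("'positions' must be an n x 3 matrix")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  n <- nrow(positions)
  masses <- as.numeric(masses)
  if (length(masses) == 1L) masses <- rep(masses, n)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("'masses' must be ", n, " strictly positive finite values")
  role <- as.character(role)
  if (length(role) != n || !all(role %in% c("receptor", "ligand")))
    stop("'role' must assign every atom to 'receptor' or 'ligand'")
  charges <- as.numeric(charges %||% rep(0, n))
  if (length(charges) != n || any(!is.finite(charges)))
    stop("'charges' must be ", n, " finite values")
  if (is.null(residue_index)) {
    residue_index <- integer(n)
    for (r in c("receptor", "ligand")) {
      idx <- which(role == r)
      residue_index[idx] <- seq_along(idx)
    }
  }
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != n) stop("'residue_index' must have one entry per atom")
  for (r in c("receptor", "ligand")) {
    ri <- residue_index[role == r]
    if (length(ri) > 1L && any(diff(ri) < 0L))
      stop("'residue_index' must be non-decreasing within the ", r, " partition")
  }
  residue_name <- rep_len(as.character(residue_name), n)
  atom_name <- rep_len(as.character(atom_name), n)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (any(bonds < 1L) || any(bonds > n)) stop("'bonds' reference atoms out of range")
  }
  structure(list(
    positions = positions, masses = masses, charges = charges,
    role = role, residue_index = residue_index,
    residue_name = residue_name, atom_name = atom_name, bonds = bonds
  ), class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d atoms (%d receptor, %d ligand)\n",
              length(x$masses), length(receptor_atoms(x)), length(ligand_atoms(x))))
  invisible(x)
}

#' Atom indices of the receptor / ligand partition
#' @param system a [particle_system()].
#' @return integer vector of atom indices.
#' @export
receptor_atoms <- function(system) which(system$role == "receptor")

#' @rdname receptor_atoms
#' @export
ligand_atoms <- function(system) which(system$role == "ligand")

#' Define collective variables as geometric centers of atom groups
#'
#' Each collective variable is the unweighted geometric center of an
#' ordered group of ligand atoms, so a definition with N groups yields an
#' N x 3 matrix of CV values.  Groups must be non-empty and reference
#' ligand atoms only: the enhanced sampling acts on the peptide, not the
#' receptor.
#'
#' @param groups list of integer vectors of atom indices, one per CV.
#' @param system the [particle_system()] the indices refer to; if supplied,
#'   indices are checked to lie in the ligand partition.
#' @param n_atoms alternatively, the total atom count to validate against.
#' @return an object of class `cv_definition`.
#' @export
cv_definition <- function(groups, system = NULL, n_atoms = NULL) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("'groups' must be a non-empty list of atom index vectors")
  groups <- lapply(groups, function(g) as.integer(g))
  if (any(vapply(groups, length, 1L) == 0L)) stop("CV groups must be non-empty")
  if (!is.null(system)) n_atoms <- length(system$masses)
  if (!is.null(n_atoms)) {
    all_idx <- unlist(groups)
    if (any(all_idx < 1L) || any(all_idx > n_atoms))
      stop("CV group indices out of range (1..", n_atoms, ")")
  }
  if (!is.null(system)) {
    lig <- ligand_atoms(system)
    if (!all(unlist(groups) %in% lig))
      stop("CV groups must reference ligand atoms only")
  }
  structure(list(groups = groups, n_cvs = length(groups)),
            class = "cv_definition")
}

#' Evaluate collective variables
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param cvdef a [cv_definition()].
#' @return N x 3 matrix; row `a` is the geometric center of group `a`.
#' @export
evaluate_cvs <- function(positions, cvdef) {
  if (max(unlist(cvdef$groups)) > nrow(positions))
    stop("CV definition references atoms beyond the position array")
  out <- matrix(0, cvdef$n_cvs, 3L)
  for (a in seq_len(cvdef$n_cvs)) {
    g <- cvdef$groups[[a]]
    out[a, ] <- if (length(g) == 1L) positions[g, ] else colMeans(positions[g, , drop = FALSE])
  }
  out
}

#' Gradient of the collective variables with respect to coordinates
#'
#' For a geometric-center CV over a group of n atoms the derivative of each
#' CV component with respect to the matching coordinate of a member atom is
#' 1/n, and zero for all other entries.  Returned as a dense N x n_atoms
#' weight matrix (identical for the x, y and z components).
#'
#' @param cvdef a [cv_definition()].
#' @param n_atoms total number of atoms.
#' @return N x n_atoms matrix of weights; rows sum to 1.
#' @export
cv_gradient <- function(cvdef, n_atoms) {
  if (max(unlist(cvdef$groups)) > n_atoms)
    stop("CV definition references atoms beyond 'n_atoms'")
  G <- matrix(0, cvdef$n_cvs, n_atoms)
  for (a in seq_len(cvdef$n_cvs)) {
    g <- cvdef$groups[[a]]
    G[a, g] <- G[a, g] + 1 / length(g)
  }
  G
}

#' Smallest ligand-receptor atom distance
#'
#' The adaptive artificial temperature is driven by the smallest distance
#' between any physical ligand atom and any receptor atom.
#'
#' @param system a [particle_system()] with both partitions non-empty.
#' @param positions coordinates to evaluate at (defaults to the system's).
#' @return minimum pair distance in Angstrom.
#' @export
min_ligand_receptor_distance <- function(system, positions = system$positions) {
  rec <- receptor_atoms(system); lig <- ligand_atoms(system)
  if (length(rec) == 0L || length(lig) == 0L)
    stop("both receptor and ligand partitions must be non-empty")
  sqrt(min(pair_dist2(positions[lig, , drop = FALSE],
                      positions[rec, , drop = FALSE])))
}

#' Distance from each CV target to the nearest receptor atom
#'
#' The soft-ratcheting filter compares, per collective variable, the
#' distance between the target point z_i and the receptor; that distance is
#' taken to the nearest receptor atom.
#'
#' @param z N x 3 matrix of CV target points (Angstrom).
#' @param system a [particle_system()] with a non-empty receptor.
#' @param positions receptor coordinates to use (defaults to the system's).
#' @return numeric vector of N distances (Angstrom).
#' @export
cv_target_receptor_distances <- function(z, system, positions = system$positions) {
  rec <- receptor_atoms(system)
  if (length(rec) == 0L) stop("receptor partition is empty")
  z <- matrix(z, ncol = 3L)
  d2 <- pair_dist2(z, positions[rec, , drop = FALSE])
  sqrt(apply(d2, 1L, min))
}

#' Simulation parameters for re-TAMD
#'
#' Bundles every thermostat, coupling, adaptive-temperature and ratcheting
#' parameter.  Units: kappa kcal/(mol A^2); gamma, gamma_bar ps^-1;
#' beta_inv, h_adapt kcal/mol; k_adapt A kcal/mol; dt ps; c_ratchet
#' dimensionless (distances enter the ratchet formula as Angstrom
#' numerics).
#'
#' @param kappa spring force constant coupling CVs to their targets.
#' @param gamma physical Langevin friction.
#' @param beta_inv physical thermal energy \eqn{k_B T}.
#' @param gamma_bar friction of the overdamped Langevin dynamics on the CV
#'   targets; larger values make the targets move more slowly.
#' @param k_adapt,h_adapt adaptive artificial-temperature law
#'   \eqn{\bar\beta^{-1} = k/min(D) + h}.
#' @param c_ratchet strictness coefficient of the soft-ratcheting filter.
#' @param dt integration timestep.
#' @param n_steps number of steps to integrate.
#' @param seed master seed for the physical, target and acceptance noise
#'   substreams.
#' @param beta_bar_inv optional constant artificial thermal energy, used
#'   when the distance-adaptive law is disabled.
#' @return an object of class `retamd_params`.
#' @export
retamd_params <- function(kappa = 100, gamma = 2, beta_inv = 0.6,
                          gamma_bar = 50, k_adapt = 40, h_adapt = 10,
                          c_ratchet = 0.02, dt = 0.005, n_steps = 10000L,
                          seed = 1L, beta_bar_inv = NULL) {
  num1 <- function(v, nm, strict = TRUE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (strict && v <= 0) || (!strict && v < 0))
      stop("'", nm, "' must be a ", if (strict) "strictly positive" else "non-negative",
           " finite scalar")
    as.numeric(v)
  }
  p <- list(
    kappa = num1(kappa, "kappa"), gamma = num1(gamma, "gamma"),
    beta_inv = num1(beta_inv, "beta_inv"),
    gamma_bar = num1(gamma_bar, "gamma_bar"),
    k_adapt = num1(k_adapt, "k_adapt"),
    h_adapt = num1(h_adapt, "h_adapt", strict = FALSE),
    c_ratchet = num1(c_ratchet, "c_ratchet"),
    dt = num1(dt, "dt"),
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    beta_bar_inv = if (is.null(beta_bar_inv)) NULL else num1(beta_bar_inv, "beta_bar_inv")
  )
  if (p$n_steps < 1L) stop("'n_steps' must be at least 1")
  structure(p, class = "retamd_params")
}

#' @export
print.retamd_params <- function(x, ...) {
  cat("retamd_params:\n")
  cat(sprintf("  kappa=%g gamma=%g beta_inv=%g gamma_bar=%g\n",
              x$kappa, x$gamma, x$beta_inv, x$gamma_bar))
  cat(sprintf("  k_adapt=%g h_adapt=%g c_ratchet=%g\n",
              x$k_adapt, x$h_adapt, x$c_ratchet))
  cat(sprintf("  dt=%g n_steps=%d seed=%d\n", x$dt, x$n_steps, x$seed))
  invisible(x)
}
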