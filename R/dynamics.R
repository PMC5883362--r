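## Stochastic integrators for the extended system: underdamped Langevin
## (BAOAB splitting) on the physical coordinates under the restrained
## potential, and overdamped Langevin (Euler-Maruyama) on the CV targets.

#' Construct a potential
#'
#' A potential is a pair of functions on an n x 3 coordinate matrix:
#' `energy(x)` in kcal/mol and `forces(x)` returning the per-atom negative
#' gradient in kcal/(mol A).
#'
#' @param energy function(positions) -> scalar energy.
#' @param forces function(positions) -> n x 3 force matrix.
#' @param name label used in printing.
#' @return object of class `potential`.
#' @export
make_potential <- function(energy, forces, name = "potential") {
  stopifnot(is.function(energy), is.function(forces))
  structure(list(energy = energy, forces = forces, name = name),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat("potential:", x$name, "\n"); invisible(x)
}

#' Zero potential (free particles)
#' @return a [make_potential()] object with zero energy and forces.
#' @export
zero_potential <- function() {
  make_potential(function(x) 0, function(x) x * 0, name = "free")
}

#' Harmonic restraint energy between CVs and their targets
#'
#' The extended potential adds \eqn{\frac12 \kappa \|\theta(x) - z\|^2} to
#' the physical potential, with the squared norm running over all N x 3
#' CV components.
#'
#' @param theta N x 3 matrix of current CV values.
#' @param z N x 3 matrix of CV targets.
#' @param kappa spring constant, kcal/(mol A^2).
#' @return restraint energy in kcal/mol.
#' @export
restraint_energy <- function(theta, z, kappa) {
  theta <- as.matrix(theta); z <- as.matrix(z)
  if (!identical(dim(theta), dim(z)))
    stop("'theta' and 'z' must have identical dimensions")
  0.5 * kappa * sum((theta - z)^2)
}

## Restraint force only: -kappa (theta_a - z_a) grad theta_a, i.e. a pull
## of -kappa*delta/n on each member of a group of size n.
restraint_forces <- function(theta, z, cvdef, n_atoms, kappa) {
  F <- matrix(0, n_atoms, 3L)
  delta <- kappa * (theta - z)
  for (a in seq_len(cvdef$n_cvs)) {
    g <- cvdef$groups[[a]]
    w <- delta[a, ] / length(g)
    F[g, 1L] <- F[g, 1L] - w[1L]
    F[g, 2L] <- F[g, 2L] - w[2L]
    F[g, 3L] <- F[g, 3L] - w[3L]
  }
  F
}

#' Total force under the extended potential
#'
#' Physical forces plus the CV restraint contribution: an atom in group
#' alpha of size n feels an extra \eqn{-\kappa(\theta_\alpha - z_\alpha)/n}
#' per component; atoms in no group feel only the physical potential.
#'
#' @param positions n x 3 coordinate matrix.
#' @param potential a [make_potential()] object.
#' @param cvdef a [cv_definition()].
#' @param z N x 3 matrix of CV targets.
#' @param kappa spring constant.
#' @return n x 3 force matrix, kcal/(mol A).
#' @export
coupled_force <- function(positions, potential, cvdef, z, kappa) {
  theta <- evaluate_cvs(positions, cvdef)
  potential$forces(positions) +
    restraint_forces(theta, z, cvdef, nrow(positions), kappa)
}

#' Seeded noise model with independent substreams
#'
#' Draws of standard normal and uniform variates for the physical noise,
#' the CV-target noise and the ratchet acceptance tests come from three
#' independent, reproducible L'Ecuyer-CMRG substreams derived from one
#' master seed.  Keeping the streams separate means controller rejections
#' never desynchronize the physical trajectory.  The object is stateful:
#' successive draws continue each stream, so a simulation can be resumed
#' chunk-by-chunk with the same noise model.
#'
#' @param seed integer master seed.
#' @return an object of class `noise_model` with elements
#'   `normal(stream, n)` and `uniform(stream, n)`, where `stream` is one of
#'   `"x"`, `"z"`, `"u"`.
#' @export
noise_model <- function(seed) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  s_x <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  s_z <- parallel::nextRNGStream(s_x)
  s_u <- parallel::nextRNGStream(s_z)
  if (had) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  streams <- new.env(parent = emptyenv())
  streams$x <- s_x; streams$z <- s_z; streams$u <- s_u
  draw <- function(stream, n, rfun) {
    prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    assign(".Random.seed", streams[[stream]], envir = globalenv())
    val <- rfun(n)
    streams[[stream]] <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
    val
  }
  structure(list(
    seed = seed,
    normal = function(stream, n) draw(stream, n, stats::rnorm),
    uniform = function(stream, n) draw(stream, n, stats::runif)
  ), class = "noise_model")
}

#' One BAOAB Langevin step on the physical coordinates
#'
#' Underdamped Langevin dynamics at friction `gamma` and thermal energy
#' `beta_inv`, discretized with the BAOAB splitting (robust configurational
#' sampling at moderate timesteps; reduces to velocity Verlet as
#' `gamma -> 0` with zero noise).  Deterministic given the noise matrix.
#'
#' @param x,v n x 3 position and velocity matrices.
#' @param masses per-atom masses (amu).
#' @param force_fn function(positions) -> n x 3 forces, typically a
#'   [coupled_force()] closure.
#' @param dt timestep (ps).
#' @param gamma friction (ps^-1); `gamma = 0` gives deterministic dynamics.
#' @param beta_inv thermal energy (kcal/mol).
#' @param eta n x 3 matrix of standard normal draws (zeros for
#'   deterministic integration).
#' @param step step index reported in error messages.
#' @return list with updated `x`, `v` and the force at the new positions.
#' @export
step_physical <- function(x, v, masses, force_fn, dt, gamma, beta_inv,
                          eta = NULL, step = NA_integer_) {
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(eta)) eta <- matrix(0, nrow(x), 3L)
  F <- force_fn(x)
  if (!all(is.finite(F)))
    stop("non-finite forces encountered at step ", step)
  half <- dt / 2
  v <- v + half * F / masses
  x <- x + half * v
  c1 <- exp(-gamma * dt)
  sig <- sqrt((1 - c1^2) * beta_inv / masses)
  v <- c1 * v + sig * eta
  x <- x + half * v
  F <- force_fn(x)
  if (!all(is.finite(F)))
    stop("non-finite forces encountered at step ", step)
  v <- v + half * F / masses
  list(x = x, v = v, force = F)
}

#' One Euler-Maruyama step proposing new CV targets
#'
#' Overdamped Langevin dynamics on the targets:
#' \eqn{z' = z + (dt/\bar\gamma)\,\kappa(\theta - z) +
#' \sqrt{2\,dt\,\bar\beta^{-1}/\bar\gamma}\,\eta^z}.
#' The result is a proposal; acceptance is decided by the soft-ratcheting
#' controller.
#'
#' @param z,theta N x 3 matrices of targets and current CV values.
#' @param kappa spring constant.
#' @param gamma_bar target friction (positive).
#' @param beta_bar_inv artificial thermal energy (kcal/mol, >= 0).
#' @param dt timestep.
#' @param eta N x 3 matrix of standard normal draws (zeros if omitted).
#' @return proposed N x 3 target matrix.
#' @export
step_targets <- function(z, theta, kappa, gamma_bar, beta_bar_inv, dt,
                         eta = NULL) {
  if (dt <= 0) stop("'dt' must be positive")
  if (gamma_bar <= 0) stop("'gamma_bar' must be positive")
  if (!all(is.finite(z)) || !all(is.finite(theta)) || !is.finite(beta_bar_inv))
    stop("non-finite inputs to target step")
  if (is.null(eta)) eta <- matrix(0, nrow(z), 3L)
  z + (dt / gamma_bar) * kappa * (theta - z) +
    sqrt(2 * dt * beta_bar_inv / gamma_bar) * eta
}
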