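## The re-TAMD layer: distance-adaptive artificial temperature, the
## soft-ratcheting Monte Carlo filter on CV-target proposals, and the main
## simulation loops.

#' Distance-adaptive artificial thermal energy
#'
#' The artificial thermal energy driving the CV targets rises as the
#' ligand approaches the receptor:
#' \eqn{\bar\beta^{-1} = k/\min(D) + h},
#' where min(D) is the smallest ligand-receptor atom distance.  It is
#' strictly decreasing in the distance and tends to `h_adapt` far from the
#' receptor, so a bound ligand is pushed hard while a detached one cools
#' down.
#'
#' @param min_distance smallest ligand-receptor distance (Angstrom, > 0).
#' @param k_adapt numerator, Angstrom kcal/mol.
#' @param h_adapt offset, kcal/mol.
#' @return artificial thermal energy in kcal/mol.
#' @export
adaptive_beta_bar <- function(min_distance, k_adapt, h_adapt) {
  if (any(!is.na(min_distance) & min_distance <= 0))
    stop("'min_distance' must be strictly positive")
  k_adapt / min_distance + h_adapt
}

#' Soft-ratcheting factor for one collective variable
#'
#' For a target proposal that moves the i-th CV from receptor distance
#' `d_old` to `d_new`, the per-CV factor is
#' \eqn{f_i = \exp[-(D_i - D_i^{new})^2] / (c D_i^2)},
#' with distances as Angstrom numerics.  Larger strictness `c` shrinks the
#' factor, making outward moves less likely to be accepted.  The
#' alternative reading \eqn{\exp[-(\Delta D)^2/(c D^2)]} is available as
#' `form = "exponent"`.
#'
#' @param d_old,d_new previous and proposed CV-target receptor distances
#'   (Angstrom); `d_old` must be positive.
#' @param c_ratchet strictness coefficient (> 0).
#' @param form which algebraic reading of the factor to use.
#' @return non-negative factor(s), vectorized over the inputs.
#' @export
ratchet_factor <- function(d_old, d_new, c_ratchet,
                           form = c("literal", "exponent")) {
  form <- match.arg(form)
  if (any(d_old <= 0)) stop("'d_old' must be strictly positive")
  if (c_ratchet <= 0) stop("'c_ratchet' must be strictly positive")
  dd2 <- (d_old - d_new)^2
  if (form == "literal") {
    exp(-dd2) / (c_ratchet * d_old^2)
  } else {
    exp(-dd2 / (c_ratchet * d_old^2))
  }
}

#' Soft-ratcheting acceptance decision
#'
#' If at least one proposed distance is smaller than its previous value the
#' proposal is accepted unconditionally (probability 1).  Otherwise it is
#' accepted with probability \eqn{\min(1, f_1 f_2 \cdots f_N)} against the
#' supplied uniform draw.
#'
#' @param d_old,d_new numeric vectors of per-CV receptor distances (equal
#'   length N >= 1).
#' @param c_ratchet strictness coefficient.
#' @param uniform_draw a single U(0,1) variate.
#' @param form passed to [ratchet_factor()].
#' @return list with elements `accept` (logical) and `prob` (in `[0,1]`).
#' @export
soft_ratchet_decision <- function(d_old, d_new, c_ratchet, uniform_draw,
                                  form = c("literal", "exponent")) {
  if (length(d_old) != length(d_new))
    stop("'d_old' and 'd_new' must have the same length")
  if (length(d_old) < 1L) stop("at least one collective variable required")
  if (any(d_new < d_old)) return(list(accept = TRUE, prob = 1))
  p <- min(1, prod(ratchet_factor(d_old, d_new, c_ratchet, form = form)))
  list(accept = uniform_draw < p, prob = p)
}

## Shared argument checks + noise setup for the run loops.
.run_setup <- function(system, params, noise, x0, v0) {
  n <- nrow(system$positions)
  noise <- noise %||% noise_model(params$seed)
  x <- x0 %||% system$positions
  if (!identical(dim(x), dim(system$positions)))
    stop("'x0' must match the system's position matrix")
  v <- v0 %||% (sqrt(params$beta_inv / system$masses) *
                  matrix(noise$normal("x", n * 3L), n, 3L))
  list(n = n, noise = noise, x = x, v = v)
}

#' Run a re-TAMD simulation
#'
#' The main loop.  Per step: (1) integrate the physical coordinates one
#' BAOAB step under the current targets; (2) recompute the CV values, the
#' smallest ligand-receptor distance and the adaptive artificial thermal
#' energy; (3) propose new targets by one Euler-Maruyama step; (4) compute
#' the proposed targets' receptor distances and apply the soft-ratcheting
#' decision, keeping the previous targets on rejection; (5) record.
#'
#' With `ratchet = FALSE` and `adaptive = FALSE` (plus a constant
#' `beta_bar_inv` in `params`) the loop reduces to vanilla TAMD; with
#' `beta_bar_inv = beta_inv` that is plain sampling of the extended
#' potential.
#'
#' @param system a [particle_system()].
#' @param potential a [make_potential()] object for the physical forces.
#' @param cvdef a [cv_definition()].
#' @param params a [retamd_params()].
#' @param adaptive use the distance-adaptive artificial temperature?  If
#'   `FALSE`, `params$beta_bar_inv` must be set.
#' @param ratchet apply the soft-ratcheting filter to target proposals?
#' @param ratchet_form passed to [ratchet_factor()].
#' @param frame_stride emit a coordinate frame every this many steps.
#' @param record_stride record scalars every this many steps.
#' @param x0,v0,z0 optional initial positions, velocities and targets
#'   (defaults: system positions, Maxwell-Boltzmann velocities, targets at
#'   the initial CV values).  Together with `noise` these allow resuming a
#'   run chunk by chunk.
#' @param noise optional stateful [noise_model()]; defaults to a fresh one
#'   from `params$seed`.
#' @param starvation_window if no proposal is accepted over a window of
#'   this many steps, emit a warning (not an error).
#' @param time0,step0 time/step offsets used when resuming.
#' @param verbose log acceptance-rate summaries every 1000 steps.
#' @return an object of class `retamd_run`: coordinate `frames` (one row
#'   per frame, bio3d xyz order), per-step `records` (data frame with
#'   columns step, time, z/theta components, per-CV distances `D*`,
#'   `minD`, `beta_bar_inv`, `accepted`, `prob`), the `final_state`, and
#'   the overall `acceptance_rate`.
#' @export
run_retamd <- function(system, potential, cvdef, params,
                       adaptive = TRUE, ratchet = TRUE,
                       ratchet_form = c("literal", "exponent"),
                       frame_stride = 100L, record_stride = 1L,
                       x0 = NULL, v0 = NULL, z0 = NULL, noise = NULL,
                       starvation_window = 1000L,
                       time0 = 0, step0 = 0L, verbose = FALSE) {
  ratchet_form <- match.arg(ratchet_form)
  rec_idx <- receptor_atoms(system)
  lig_idx <- ligand_atoms(system)
  has_receptor <- length(rec_idx) > 0L
  if ((adaptive || ratchet) && !has_receptor)
    stop("adaptive temperature and ratcheting require a non-empty receptor")
  if (!adaptive && is.null(params$beta_bar_inv))
    stop("set 'beta_bar_inv' in params when 'adaptive' is FALSE")
  if (!all(unlist(cvdef$groups) %in% lig_idx))
    stop("CV groups must reference ligand atoms only")

  st <- .run_setup(system, params, noise, x0, v0)
  n <- st$n; noise <- st$noise; x <- st$x; v <- st$v
  N <- cvdef$n_cvs
  m <- system$masses
  dt <- params$dt; half <- dt / 2
  kappa <- params$kappa; gbar <- params$gamma_bar
  c1 <- exp(-params$gamma * dt)
  sigv <- sqrt((1 - c1^2) * params$beta_inv / m)
  nst <- params$n_steps
  n3 <- 3L * n; N3 <- 3L * N

  eta_x <- noise$normal("x", nst * n3)
  eta_z <- noise$normal("z", nst * N3)
  u_acc <- noise$uniform("u", nst)

  theta <- evaluate_cvs(x, cvdef)
  z <- z0 %||% theta
  z <- matrix(z, N, 3L)
  D <- if (has_receptor) cv_target_receptor_distances(z, system, x) else rep(NA_real_, N)
  F_V <- potential$forces(x)
  F <- F_V + restraint_forces(theta, z, cvdef, n, kappa)

  n_rec <- nst %/% record_stride
  n_frames <- nst %/% frame_stride
  rec <- matrix(NA_real_, n_rec, 6L + 2L * N3 + N)
  frames <- matrix(NA_real_, n_frames, n3)
  frame_steps <- integer(n_frames)
  ri <- 0L; fi <- 0L
  n_accept <- 0L; window_accept <- 0L; starved_warned <- FALSE
  mind <- NA_real_; bb <- NA_real_

  for (s in seq_len(nst)) {
    ## BAOAB, force cached from the end of the previous step
    v <- v + half * F / m
    x <- x + half * v
    base <- (s - 1L) * n3
    v <- c1 * v + sigv * matrix(eta_x[(base + 1L):(base + n3)], n, 3L)
    x <- x + half * v
    F_V <- potential$forces(x)
    theta <- evaluate_cvs(x, cvdef)
    F <- F_V + restraint_forces(theta, z, cvdef, n, kappa)
    if (!is.finite(sum(F)))
      stop("non-finite forces: simulation aborted at step ", step0 + s)
    v <- v + half * F / m

    ## adaptive artificial temperature from the instantaneous min distance
    mind <- if (has_receptor) min_ligand_receptor_distance(system, x) else Inf
    bb <- if (adaptive) params$k_adapt / mind + params$h_adapt else params$beta_bar_inv

    ## propose new targets
    zbase <- (s - 1L) * N3
    zp <- z + (dt / gbar) * kappa * (theta - z) +
      sqrt(2 * dt * bb / gbar) * matrix(eta_z[(zbase + 1L):(zbase + N3)], N, 3L)

    if (ratchet) {
      Dn <- cv_target_receptor_distances(zp, system, x)
      if (any(Dn < D)) {
        acc <- TRUE; p <- 1
      } else {
        p <- min(1, prod(ratchet_factor(D, Dn, params$c_ratchet, form = ratchet_form)))
        acc <- u_acc[s] < p
      }
      if (acc) {
        z <- zp; D <- Dn
        F <- F_V + restraint_forces(theta, z, cvdef, n, kappa)
      }
    } else {
      z <- zp
      if (has_receptor) D <- cv_target_receptor_distances(z, system, x)
      acc <- TRUE; p <- 1
      F <- F_V + restraint_forces(theta, z, cvdef, n, kappa)
    }
    if (acc) { n_accept <- n_accept + 1L; window_accept <- window_accept + 1L }

    if (s %% starvation_window == 0L) {
      if (window_accept == 0L && !starved_warned) {
        warning("acceptance starvation: no target proposal accepted over ",
                starvation_window, " steps (step ", step0 + s, ")")
        starved_warned <- TRUE
      }
      window_accept <- 0L
    }
    if (verbose && s %% 1000L == 0L) {
      message(sprintf("step %d: acc %.3f  beta_bar_inv %.2f  minD %.2f",
                      step0 + s, n_accept / s, bb, mind))
    }

    if (s %% record_stride == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(step0 + s, time0 + s * dt, t(z), t(theta), D, mind, bb,
                     as.numeric(acc), p)
    }
    if (s %% frame_stride == 0L) {
      fi <- fi + 1L
      frames[fi, ] <- t(x)
      frame_steps[fi] <- step0 + s
    }
  }

  records <- as.data.frame(rec)
  names(records) <- c("step", "time",
                      paste0("z", rep(seq_len(N), each = 3L), ".", c("x", "y", "z")),
                      paste0("theta", rep(seq_len(N), each = 3L), ".", c("x", "y", "z")),
                      paste0("D", seq_len(N)), "minD", "beta_bar_inv",
                      "accepted", "prob")
  records$accepted <- records$accepted > 0.5

  structure(list(
    kind = "retamd", system = system, cvdef = cvdef, params = params,
    adaptive = adaptive, ratchet = ratchet,
    frames = frames, frame_steps = frame_steps, records = records,
    acceptance_rate = n_accept / nst,
    final_state = list(x = x, v = v, z = z, theta = theta,
                       cv_receptor_distances = D, min_distance = mind,
                       beta_bar_inv = bb, time = time0 + nst * dt,
                       step = step0 + nst),
    noise = noise
  ), class = "retamd_run")
}

#' Run plain Langevin molecular dynamics
#'
#' The control simulation: BAOAB Langevin dynamics at the physical thermal
#' energy with no collective-variable coupling.  Used for baseline contact
#' tables and isolated-peptide runs.
#'
#' @inheritParams run_retamd
#' @return an object of class `retamd_run` with `kind = "md"`; records
#'   hold step, time and (when a receptor is present) the smallest
#'   ligand-receptor distance.
#' @export
run_plain_md <- function(system, potential, params,
                         frame_stride = 100L, record_stride = 1L,
                         x0 = NULL, v0 = NULL, noise = NULL,
                         time0 = 0, step0 = 0L) {
  has_receptor <- length(receptor_atoms(system)) > 0L &&
    length(ligand_atoms(system)) > 0L
  st <- .run_setup(system, params, noise, x0, v0)
  n <- st$n; noise <- st$noise; x <- st$x; v <- st$v
  m <- system$masses
  dt <- params$dt; half <- dt / 2
  c1 <- exp(-params$gamma * dt)
  sigv <- sqrt((1 - c1^2) * params$beta_inv / m)
  nst <- params$n_steps
  n3 <- 3L * n

  eta_x <- noise$normal("x", nst * n3)
  F <- potential$forces(x)

  n_rec <- nst %/% record_stride
  n_frames <- nst %/% frame_stride
  rec <- matrix(NA_real_, n_rec, 3L)
  frames <- matrix(NA_real_, n_frames, n3)
  frame_steps <- integer(n_frames)
  ri <- 0L; fi <- 0L

  for (s in seq_len(nst)) {
    v <- v + half * F / m
    x <- x + half * v
    base <- (s - 1L) * n3
    v <- c1 * v + sigv * matrix(eta_x[(base + 1L):(base + n3)], n, 3L)
    x <- x + half * v
    F <- potential$forces(x)
    if (!is.finite(sum(F)))
      stop("non-finite forces: simulation aborted at step ", step0 + s)
    v <- v + half * F / m

    if (s %% record_stride == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(step0 + s, time0 + s * dt,
                     if (has_receptor) min_ligand_receptor_distance(system, x) else NA_real_)
    }
    if (s %% frame_stride == 0L) {
      fi <- fi + 1L
      frames[fi, ] <- t(x)
      frame_steps[fi] <- step0 + s
    }
  }

  records <- as.data.frame(rec)
  names(records) <- c("step", "time", "minD")

  structure(list(
    kind = "md", system = system, cvdef = NULL, params = params,
    frames = frames, frame_steps = frame_steps, records = records,
    acceptance_rate = NA_real_,
    final_state = list(x = x, v = v, time = time0 + nst * dt,
                       step = step0 + nst),
    noise = noise
  ), class = "retamd_run")
}

#' @export
print.retamd_run <- function(x, ...) {
  cat(sprintf("retamd_run (%s): %d steps, %d frames", x$kind,
              x$params$n_steps, nrow(x$frames)))
  if (x$kind == "retamd")
    cat(sprintf(", acceptance rate %.3f", x$acceptance_rate))
  cat("\n")
  invisible(x)
}
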