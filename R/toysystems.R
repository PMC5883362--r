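## Built-in analytic landscapes and coarse-grained structure generators.
## These make every sampler and analysis feature testable without any
## external data: a 1-particle double well with a quadrature free energy,
## and a bead-model receptor-ligand complex with a binding pocket.

#' One-particle double-well landscape
#'
#' \eqn{V(x) = \Delta[(x_1/a)^2 - 1]^2 + \frac12 k_t (x_2^2 + x_3^2)}:
#' minima of depth 0 at \eqn{x_1 = \pm a}, barrier `barrier_height` at the
#' origin, harmonic confinement in the transverse coordinates.  The
#' returned free-energy function along the first CV component is computed
#' by numerical quadrature of the Boltzmann integral, including the
#' harmonic CV coupling when `kappa` is supplied (the mollified free
#' energy actually sampled by the target dynamics).
#'
#' @param barrier_height barrier at the origin, kcal/mol (> 0).
#' @param half_separation `a`, distance from the barrier top to each
#'   minimum (Angstrom).
#' @param k_transverse transverse harmonic constant, kcal/(mol A^2).
#' @param mass particle mass (amu).
#' @param x0 initial position (defaults to the left minimum).
#' @return list with `potential`, a 1-atom ligand `system`, the 1-group
#'   `cvdef`, the well parameters, and `free_energy(z1, beta_inv, kappa)`.
#' @export
make_double_well <- function(barrier_height = 2, half_separation = 1.5,
                             k_transverse = 5, mass = 1, x0 = NULL) {
  if (barrier_height <= 0) stop("'barrier_height' must be positive")
  a <- half_separation
  if (a <= 0) stop("'half_separation' must be positive")
  dd <- barrier_height; kt <- k_transverse

  energy <- function(x) {
    dd * sum(((x[, 1L] / a)^2 - 1)^2) + 0.5 * kt * sum(x[, 2:3]^2)
  }
  forces <- function(x) {
    x1 <- x[, 1L]
    f1 <- -4 * dd * ((x1 / a)^2 - 1) * x1 / a^2
    cbind(f1, -kt * x[, 2L], -kt * x[, 3L], deparse.level = 0)
  }
  pot <- make_potential(energy, forces, name = "double_well")

  vx <- function(x1) dd * ((x1 / a)^2 - 1)^2

  free_energy <- function(z1, beta_inv, kappa = NULL) {
    vapply(z1, function(zz) {
      if (is.null(kappa)) return(vx(zz))
      f <- function(x) exp(-(vx(x) + 0.5 * kappa * (x - zz)^2) / beta_inv)
      val <- stats::integrate(f, zz - 30, zz + 30, rel.tol = 1e-10)$value
      -beta_inv * log(val)
    }, numeric(1))
  }

  system <- particle_system(
    positions = matrix(x0 %||% c(-a, 0, 0), 1L, 3L),
    masses = mass, role = "ligand", atom_name = "CA", residue_name = "DWL"
  )
  cvdef <- cv_definition(list(1L), system = system)

  list(potential = pot, system = system, cvdef = cvdef,
       barrier_height = dd, half_separation = a,
       k_transverse = kt, free_energy = free_energy)
}

## Fibonacci sphere: n roughly evenly spaced points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  zc <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - zc^2))
  ang <- pi * (3 - sqrt(5)) * (i - 1)
  cbind(r * cos(ang), r * sin(ang), zc)
}

#' Generate a coarse-grained receptor-ligand complex
#'
#' A synthetic stand-in for a protein-peptide complex: a rigid-ish
#' receptor of beads harmonically anchored to reference sites on a sphere,
#' and a flexible ligand chain (bond and 1-3 distance springs) initially
#' laid over a binding pocket.  The binding site mimics a reader domain
#' recognizing one modified residue: the central ligand beads (the probe
#' segment, analogous to an acylated lysine) are attracted to the nearby
#' pocket beads through a finite Gaussian well, while the remaining
#' surface offers only weak background attraction.  All receptor-ligand
#' and non-local ligand pairs repel through a flat-bottom harmonic
#' excluded volume (forces stay bounded, so the integrator is stable under
#' strong target dragging), and a flat-bottom spherical restraint keeps
#' the ligand within a shell around the receptor.  Ligand bead charges
#' cycle through polar (|q| >= 0.2) and hydrophobic (|q| < 0.2) values of
#' both signs so every contact class is exercisable.
#'
#' The CV preset splits the ligand into 3 groups for chains of 10 or more
#' beads, 2 for chains of 5-9, and a single group below that, mirroring
#' the CV counts used for 13-, 7- and 3-residue peptides.
#'
#' @param n_receptor number of receptor beads (>= 12).
#' @param ligand_length number of ligand beads (>= 3).
#' @param seed integer; construction is deterministic given the seed.
#' @param receptor_radius sphere radius for the receptor shell (Angstrom).
#' @param bond_length ligand bond length (Angstrom).
#' @param pocket_depth Gaussian attraction depth per pocket-probe pair
#'   (kcal/mol); the default was fixed once so that the complex stays
#'   bound under plain dynamics at 0.6 kcal/mol thermal energy yet
#'   dissociates under the adaptive-temperature presets.
#' @param mass bead mass (amu).
#' @return list of class `cg_complex` with `system`, `potential`, `cvdef`,
#'   `pocket` (receptor atom indices forming the binding site), `probe`
#'   (the central ligand atom indices the site recognizes), `reference`
#'   (anchor sites), and `confinement_radius`.
#' @export
make_cg_complex <- function(n_receptor = 200L, ligand_length = 13L, seed = 1L,
                            receptor_radius = 15, bond_length = 3,
                            pocket_depth = 3, mass = 1) {
  n_receptor <- as.integer(n_receptor)
  ligand_length <- as.integer(ligand_length)
  if (n_receptor < 12L) stop("'n_receptor' must be at least 12")
  if (ligand_length < 3L) stop("'ligand_length' must be at least 3")

  R <- receptor_radius
  refs <- fibonacci_sphere(n_receptor) * R
  jitter <- with_preserved_seed(seed, matrix(stats::runif(n_receptor * 3L, -0.15, 0.15),
                                             n_receptor, 3L))
  refs <- refs + jitter

  ## ligand: arc in the xz-plane over the +x pole, radius R + 3
  Rl <- R + 3
  dphi <- 2 * asin(bond_length / (2 * Rl))
  phis <- (seq_len(ligand_length) - (ligand_length + 1) / 2) * dphi
  lig_pos <- cbind(Rl * cos(phis), 0, Rl * sin(phis))

  ## probe: the central ligand bead (acylated-residue analog)
  mid <- (ligand_length + 1L) %/% 2L
  probe_local <- mid
  probe <- n_receptor + probe_local

  ## pocket: sculpt a concave recognition site by drawing the three
  ## receptor beads nearest the probe onto a 3 A shell around it, then
  ## collect every receptor bead within the 4 A contact cutoff
  probe_pos <- lig_pos[probe_local, ]
  dp <- sqrt(rowSums(sweep(refs, 2L, probe_pos)^2))
  cup <- order(dp)[1:3]
  for (b in cup) {
    dir <- refs[b, ] - probe_pos
    refs[b, ] <- probe_pos + 3.0 * dir / sqrt(sum(dir^2))
  }
  d2 <- pair_dist2(refs, lig_pos[probe_local, , drop = FALSE])
  pocket <- which(apply(d2, 1L, min) < 16)

  positions <- rbind(refs, lig_pos)
  n <- n_receptor + ligand_length
  role <- c(rep("receptor", n_receptor), rep("ligand", ligand_length))

  ## charges: ligand cycles polar/hydrophobic of both signs; receptor gets
  ## a seeded mix guaranteed to contain both classes and both signs
  q_lig <- rep_len(c(0.45, -0.45, 0.1, -0.1), ligand_length)
  q_rec <- with_preserved_seed(seed + 1L,
                               round(stats::runif(n_receptor, -0.6, 0.6), 2))
  q_rec[1:4] <- c(0.5, -0.5, 0.15, -0.15)
  charges <- c(q_rec, q_lig)

  bonds <- cbind(n_receptor + seq_len(ligand_length - 1L),
                 n_receptor + seq_len(ligand_length - 1L) + 1L)

  system <- particle_system(
    positions = positions, masses = mass, role = role, charges = charges,
    residue_name = c(rep("REC", n_receptor), rep("LIG", ligand_length)),
    atom_name = "CA", bonds = bonds
  )

  potential <- .cg_potential(n, n_receptor, ligand_length, refs, pocket,
                             probe, bond_length, pocket_depth,
                             confinement_radius = R + 12)

  n_cvs <- if (ligand_length >= 10L) 3L else if (ligand_length >= 5L) 2L else 1L
  bounds <- floor(seq(0, ligand_length, length.out = n_cvs + 1L))
  splits <- lapply(seq_len(n_cvs), function(k)
    n_receptor + ((bounds[k] + 1L):bounds[k + 1L]))
  cvdef <- cv_definition(splits, system = system)

  structure(list(system = system, potential = potential, cvdef = cvdef,
                 pocket = pocket, probe = probe, reference = refs,
                 confinement_radius = R + 12, seed = seed),
            class = "cg_complex")
}

#' @export
print.cg_complex <- function(x, ...) {
  cat(sprintf("cg_complex: %d receptor + %d ligand beads, %d pocket beads, %d CVs\n",
              length(receptor_atoms(x$system)), length(ligand_atoms(x$system)),
              length(x$pocket), x$cvdef$n_cvs))
  invisible(x)
}

## Assemble the CG potential closures.  Parameters frozen after a one-time
## calibration; see the methods vignette.
.cg_potential <- function(n, n_rec, n_lig, refs, pocket, probe, bond_length,
                          pocket_depth, confinement_radius,
                          k_anchor = 25, k_bond = 100, k_13 = 2,
                          sigma = 3.2, k_rep = 25,
                          eps_bg = 0.05, r0_att = 3.0, w_att = 0.8,
                          k_conf = 10) {
  rec_idx <- seq_len(n_rec)
  lig_idx <- n_rec + seq_len(n_lig)
  b1 <- lig_idx[-n_lig]; b2 <- lig_idx[-1L]
  r13 <- 2 * bond_length * sin(pi / 3)
  t1 <- if (n_lig >= 3L) lig_idx[seq_len(n_lig - 2L)] else integer(0)
  t2 <- t1 + 2L
  ## receptor-ligand pairs
  rl <- expand.grid(i = rec_idx, j = lig_idx)
  rl_i <- rl$i; rl_j <- rl$j
  ## specific attraction only between pocket beads and the probe segment
  eps_pair <- eps_bg + pocket_depth * ((rl_i %in% pocket) & (rl_j %in% probe))
  ## non-local ligand-ligand pairs (|i - j| >= 3)
  if (n_lig >= 4L) {
    ll <- expand.grid(i = lig_idx, j = lig_idx)
    keep <- (ll$j - ll$i) >= 3L
    ll_i <- ll$i[keep]; ll_j <- ll$j[keep]
  } else {
    ll_i <- integer(0); ll_j <- integer(0)
  }

  pair_terms <- function(x) {
    dxy <- x[rl_i, , drop = FALSE] - x[rl_j, , drop = FALSE]
    r <- sqrt(rowSums(dxy^2))
    list(dxy = dxy, r = r)
  }

  energy <- function(x) {
    e <- 0
    dR <- x[rec_idx, , drop = FALSE] - refs
    e <- e + 0.5 * k_anchor * sum(dR^2)
    db <- x[b2, , drop = FALSE] - x[b1, , drop = FALSE]
    rb <- sqrt(rowSums(db^2))
    e <- e + 0.5 * k_bond * sum((rb - bond_length)^2)
    if (length(t1)) {
      dtv <- x[t2, , drop = FALSE] - x[t1, , drop = FALSE]
      rt <- sqrt(rowSums(dtv^2))
      e <- e + 0.5 * k_13 * sum((rt - r13)^2)
    }
    pt <- pair_terms(x)
    ov <- pt$r < sigma
    if (any(ov)) e <- e + 0.5 * k_rep * sum((pt$r[ov] - sigma)^2)
    e <- e - sum(eps_pair * exp(-(pt$r - r0_att)^2 / (2 * w_att^2)))
    if (length(ll_i)) {
      dll <- x[ll_i, , drop = FALSE] - x[ll_j, , drop = FALSE]
      rll <- sqrt(rowSums(dll^2))
      ovl <- rll < sigma
      if (any(ovl)) e <- e + 0.5 * k_rep * sum((rll[ovl] - sigma)^2)
    }
    rlig <- sqrt(rowSums(x[lig_idx, , drop = FALSE]^2))
    out <- rlig > confinement_radius
    if (any(out)) e <- e + 0.5 * k_conf * sum((rlig[out] - confinement_radius)^2)
    e
  }

  forces <- function(x) {
    F <- matrix(0, n, 3L)
    ## anchors
    dR <- x[rec_idx, , drop = FALSE] - refs
    F[rec_idx, ] <- F[rec_idx, ] - k_anchor * dR
    ## bonds (consecutive beads share atoms: accumulate via rowsum)
    db <- x[b2, , drop = FALSE] - x[b1, , drop = FALSE]
    rb <- sqrt(rowSums(db^2))
    fb <- (-k_bond * (rb - bond_length) / rb) * db # force on b2
    F <- accumulate_rows(F, b2, fb)
    F <- accumulate_rows(F, b1, -fb)
    ## 1-3 springs
    if (length(t1)) {
      dtv <- x[t2, , drop = FALSE] - x[t1, , drop = FALSE]
      rt <- sqrt(rowSums(dtv^2))
      ft <- (-k_13 * (rt - r13) / rt) * dtv
      F <- accumulate_rows(F, t2, ft)
      F <- accumulate_rows(F, t1, -ft)
    }
    ## receptor-ligand: excluded volume + Gaussian attraction
    pt <- pair_terms(x)
    r <- pt$r
    g <- exp(-(r - r0_att)^2 / (2 * w_att^2))
    dEdr <- eps_pair * g * (r - r0_att) / w_att^2 # from attraction
    ov <- r < sigma
    dEdr[ov] <- dEdr[ov] + k_rep * (r[ov] - sigma)
    fpair <- (-dEdr / r) * pt$dxy # force on atom i (receptor side)
    F <- accumulate_rows(F, rl_i, fpair)
    F <- accumulate_rows(F, rl_j, -fpair)
    ## ligand-ligand excluded volume
    if (length(ll_i)) {
      dll <- x[ll_i, , drop = FALSE] - x[ll_j, , drop = FALSE]
      rll <- sqrt(rowSums(dll^2))
      ovl <- rll < sigma
      if (any(ovl)) {
        fl <- (-k_rep * (rll[ovl] - sigma) / rll[ovl]) * dll[ovl, , drop = FALSE]
        F <- accumulate_rows(F, ll_i[ovl], fl)
        F <- accumulate_rows(F, ll_j[ovl], -fl)
      }
    }
    ## spherical confinement on the ligand
    xl <- x[lig_idx, , drop = FALSE]
    rlig <- sqrt(rowSums(xl^2))
    out <- rlig > confinement_radius
    if (any(out)) {
      fc <- (-k_conf * (rlig[out] - confinement_radius) / rlig[out]) * xl[out, , drop = FALSE]
      F[lig_idx[out], ] <- F[lig_idx[out], ] + fc
    }
    F
  }

  make_potential(energy, forces, name = "cg_complex")
}

#' Write a particle system as a PDB fixture with a sidecar charge table
#'
#' Writes a standard PDB (receptor chain R, ligand chain L, one residue
#' per bead group) through bio3d, plus a tab-separated per-atom partial
#' charge table keyed by atom serial, since the PDB format has no charge
#' field.  Round-trips through [read_structure()] at PDB coordinate
#' precision (1e-3 Angstrom).
#'
#' @param system a [particle_system()].
#' @param pdb_path output PDB path.
#' @param charge_path output TSV path; defaults to `pdb_path` with a
#'   `.charges.tsv` extension.
#' @return invisibly, the two paths.
#' @export
write_fixture_pdb <- function(system, pdb_path,
                              charge_path = sub("\\.pdb$", ".charges.tsv", pdb_path)) {
  n <- length(system$masses)
  chain <- ifelse(system$role == "receptor", "R", "L")
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(system$positions)),
                   resno = system$residue_index,
                   resid = system$residue_name,
                   eleno = seq_len(n),
                   elety = system$atom_name,
                   chain = chain,
                   o = rep(1, n), b = rep(0, n))
  utils::write.table(
    data.frame(serial = seq_len(n), charge = system$charges),
    charge_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(pdb = pdb_path, charges = charge_path))
}
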