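## Trajectory analysis: receptor-ligand contact detection and
## classification by partial charge, per-residue contact profiles and hot
## spots, per-frame site-contact fractions, and backbone phi/psi
## dihedral distributions.

## Coerce a trajectory argument to a frames matrix (n_frames x 3n, bio3d
## xyz ordering).
.traj_frames <- function(trajectory) {
  if (inherits(trajectory, "retamd_run")) return(trajectory$frames)
  if (is.matrix(trajectory)) return(trajectory)
  if (is.numeric(trajectory)) return(matrix(trajectory, nrow = 1L))
  stop("'trajectory' must be a retamd_run or a frames matrix")
}

.frame_xyz <- function(frames, f) {
  matrix(frames[f, ], ncol = 3L, byrow = TRUE)
}

#' Find receptor-ligand atomic contacts in one frame
#'
#' All receptor-atom/ligand-atom pairs at a distance strictly below the
#' cutoff.  Pairs within one partition are never reported.
#'
#' @param frame_positions n x 3 coordinate matrix.
#' @param receptor_idx,ligand_idx atom index vectors (non-empty,
#'   disjoint).
#' @param cutoff contact distance in Angstrom (default 4).
#' @return data frame with columns `atom_i` (receptor), `atom_j` (ligand)
#'   and `distance`.
#' @export
find_contacts <- function(frame_positions, receptor_idx, ligand_idx,
                          cutoff = 4.0) {
  if (length(receptor_idx) == 0L || length(ligand_idx) == 0L)
    stop("both partitions must be non-empty")
  d2 <- pair_dist2(frame_positions[receptor_idx, , drop = FALSE],
                   frame_positions[ligand_idx, , drop = FALSE])
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  data.frame(atom_i = receptor_idx[hit[, 1L]],
             atom_j = ligand_idx[hit[, 2L]],
             distance = sqrt(d2[hit]))
}

#' Classify a contact by the partial charges of its atoms
#'
#' A pair is hydrophobic when both partial charges have absolute value
#' below the threshold, and polar when the charges have opposite signs.  A
#' pair may satisfy both rules, either one, or neither; every contact
#' counts towards the total regardless of class.  `disjoint = TRUE`
#' switches to the variant in which polar additionally requires both
#' magnitudes at or above the threshold, making the classes mutually
#' exclusive.
#'
#' @param q_i,q_j partial charges (elementary charge units); vectorized.
#' @param charge_threshold hydrophobicity threshold (default 0.2).
#' @param disjoint use the mutually exclusive variant?
#' @return data frame with logical columns `polar` and `hydrophobic`.
#' @export
classify_contact <- function(q_i, q_j, charge_threshold = 0.2,
                             disjoint = FALSE) {
  if (any(!is.finite(q_i)) || any(!is.finite(q_j)))
    stop("charges must be finite")
  hydro <- abs(q_i) < charge_threshold & abs(q_j) < charge_threshold
  polar <- q_i * q_j < 0
  if (disjoint) polar <- polar & !hydro
  data.frame(polar = polar, hydrophobic = hydro)
}

#' Per-residue contact profile over a trajectory
#'
#' Sums atomic contacts involving each residue of the chosen side over all
#' frames, per class (polar, hydrophobic, total), and rescales by the
#' largest per-residue total so the profile lies in [0, 1] with maximum
#' exactly 1 whenever any contact exists.  Per-atom totals (similarly
#' rescaled by the largest per-atom count) are retained for hot-spot
#' detection and surface mapping.
#'
#' @param trajectory a `retamd_run` or frames matrix.
#' @param system the matching [particle_system()].
#' @param by count contacts per `"receptor"` or `"ligand"` residue.
#' @param cutoff contact cutoff (Angstrom).
#' @param charge_threshold passed to [classify_contact()].
#' @param disjoint passed to [classify_contact()].
#' @return object of class `contact_profile`: data frame `residues`
#'   (residue, raw and scaled counts per class), data frame `atoms`
#'   (atom, residue, count, scaled), the normalization constant, and a
#'   `no_contacts` flag.
#' @export
residue_profile <- function(trajectory, system, by = c("receptor", "ligand"),
                            cutoff = 4.0, charge_threshold = 0.2,
                            disjoint = FALSE) {
  by <- match.arg(by)
  frames <- .traj_frames(trajectory)
  if (nrow(frames) < 1L) stop("trajectory has no frames")
  rec <- receptor_atoms(system); lig <- ligand_atoms(system)
  side_atoms <- if (by == "receptor") rec else lig
  side_res <- sort(unique(system$residue_index[side_atoms]))
  nr <- length(side_res)
  res_of <- match(system$residue_index, side_res)

  cnt <- matrix(0, nr, 3L, dimnames = list(NULL, c("total", "polar", "hydrophobic")))
  atom_cnt <- setNames(numeric(length(side_atoms)), side_atoms)

  for (f in seq_len(nrow(frames))) {
    xyz <- .frame_xyz(frames, f)
    cc <- find_contacts(xyz, rec, lig, cutoff = cutoff)
    if (nrow(cc) == 0L) next
    cls <- classify_contact(system$charges[cc$atom_i], system$charges[cc$atom_j],
                            charge_threshold = charge_threshold,
                            disjoint = disjoint)
    side_atom <- if (by == "receptor") cc$atom_i else cc$atom_j
    ri <- res_of[side_atom]
    cnt[, "total"] <- cnt[, "total"] + tabulate(ri, nr)
    cnt[, "polar"] <- cnt[, "polar"] + tabulate(ri[cls$polar], nr)
    cnt[, "hydrophobic"] <- cnt[, "hydrophobic"] + tabulate(ri[cls$hydrophobic], nr)
    ta <- table(factor(side_atom, levels = side_atoms))
    atom_cnt <- atom_cnt + as.numeric(ta)
  }

  norm <- max(cnt[, "total"])
  no_contacts <- norm == 0
  sc <- if (no_contacts) cnt * 0 else cnt / norm
  atom_norm <- max(atom_cnt)
  atom_scaled <- if (atom_norm == 0) atom_cnt * 0 else atom_cnt / atom_norm

  structure(list(
    residues = data.frame(
      residue = side_res,
      total = cnt[, "total"], polar = cnt[, "polar"],
      hydrophobic = cnt[, "hydrophobic"],
      scaled_total = sc[, "total"], scaled_polar = sc[, "polar"],
      scaled_hydrophobic = sc[, "hydrophobic"]
    ),
    atoms = data.frame(
      atom = side_atoms,
      residue = system$residue_index[side_atoms],
      count = as.numeric(atom_cnt),
      scaled = as.numeric(atom_scaled)
    ),
    by = by, normalization = norm, n_frames = nrow(frames),
    no_contacts = no_contacts
  ), class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile (%s side): %d residues over %d frames%s\n",
              x$by, nrow(x$residues), x$n_frames,
              if (x$no_contacts) " [no contacts]" else ""))
  invisible(x)
}

#' Percentage of frames in which site residues contact a probe residue
#'
#' For each residue of a binding site, the percentage of trajectory frames
#' in which at least one of its atoms lies within the cutoff of any atom
#' of the probe residue (e.g. the acylated lysine of a histone tail).
#'
#' @param trajectory a `retamd_run` or frames matrix.
#' @param system the matching [particle_system()].
#' @param site_residues receptor residue indices of the binding site.
#' @param probe_residue a single ligand residue index.
#' @param cutoff contact cutoff (Angstrom).
#' @return data frame with columns `residue` and `percent` (0-100; report
#'   formatting rounds to one decimal place).
#' @export
contact_fraction_table <- function(trajectory, system, site_residues,
                                   probe_residue, cutoff = 4.0) {
  frames <- .traj_frames(trajectory)
  if (nrow(frames) < 1L) stop("trajectory has no frames")
  rec <- receptor_atoms(system); lig <- ligand_atoms(system)
  probe_atoms <- lig[system$residue_index[lig] == probe_residue]
  if (length(probe_atoms) == 0L)
    stop("unknown probe residue: ", probe_residue)
  site_atoms <- lapply(site_residues, function(r) {
    a <- rec[system$residue_index[rec] == r]
    if (length(a) == 0L) stop("unknown site residue: ", r)
    a
  })
  hits <- matrix(FALSE, nrow(frames), length(site_residues))
  for (f in seq_len(nrow(frames))) {
    xyz <- .frame_xyz(frames, f)
    for (k in seq_along(site_atoms)) {
      d2 <- pair_dist2(xyz[site_atoms[[k]], , drop = FALSE],
                       xyz[probe_atoms, , drop = FALSE])
      hits[f, k] <- any(d2 < cutoff^2)
    }
  }
  data.frame(residue = site_residues,
             percent = 100 * colMeans(hits))
}

#' Per-frame fraction of site beads in contact with the ligand
#'
#' A compact dissociation readout for the toy complexes: for each frame,
#' the fraction of the given receptor atoms (typically the pocket beads)
#' within the cutoff of at least one ligand atom.
#'
#' @param trajectory a `retamd_run` or frames matrix.
#' @param system the matching [particle_system()].
#' @param site_atoms receptor atom indices (e.g. `complex$pocket`).
#' @param probe_atoms ligand atom indices to test against (e.g.
#'   `complex$probe`, the recognized residue analog); defaults to the
#'   whole ligand.
#' @param cutoff contact cutoff (Angstrom).
#' @return numeric vector, one fraction in [0, 1] per frame.
#' @export
pocket_contact_fraction <- function(trajectory, system, site_atoms,
                                    probe_atoms = NULL, cutoff = 4.0) {
  frames <- .traj_frames(trajectory)
  probe_atoms <- probe_atoms %||% ligand_atoms(system)
  vapply(seq_len(nrow(frames)), function(f) {
    xyz <- .frame_xyz(frames, f)
    d2 <- pair_dist2(xyz[site_atoms, , drop = FALSE],
                     xyz[probe_atoms, , drop = FALSE])
    mean(apply(d2, 1L, min) < cutoff^2)
  }, numeric(1))
}

#' Residues whose scaled atomic contact exceeds a threshold
#'
#' Lists the residues containing at least one atom whose rescaled contact
#' count exceeds the threshold: 0.5 for reporting contact lists,
#' 0.8 for hot spots.
#'
#' @param profile a [residue_profile()] result.
#' @param threshold value in [0, 1].
#' @return integer vector of residue indices.
#' @export
hotspot_residues <- function(profile, threshold = 0.5) {
  if (!inherits(profile, "contact_profile")) stop("'profile' must be a contact_profile")
  if (threshold < 0 || threshold > 1) stop("'threshold' must lie in [0, 1]")
  hot <- profile$atoms$scaled > threshold
  sort(unique(profile$atoms$residue[hot]))
}

#' Backbone phi/psi dihedral series over a trajectory
#'
#' Computes the signed backbone dihedrals per residue and frame from
#' N/CA/C atom naming (phi: C(i-1)-N(i)-CA(i)-C(i); psi:
#' N(i)-CA(i)-C(i)-N(i+1)), in degrees in (-180, 180], right-handed IUPAC
#' sign convention.  The first residue carries no phi and the last no psi;
#' residues with missing backbone atoms are skipped with a warning.
#'
#' @param trajectory a `retamd_run` or frames matrix.
#' @param system the matching [particle_system()]; dihedrals are computed
#'   for ligand residues.
#' @return data frame with columns `frame`, `residue`, `phi`, `psi`
#'   (degrees; `NA` where undefined).
#' @export
phi_psi <- function(trajectory, system) {
  frames <- .traj_frames(trajectory)
  lig <- ligand_atoms(system)
  res_ids <- sort(unique(system$residue_index[lig]))
  bb <- lapply(res_ids, function(r) {
    at <- lig[system$residue_index[lig] == r]
    list(N = at[system$atom_name[at] == "N"][1],
         CA = at[system$atom_name[at] == "CA"][1],
         C = at[system$atom_name[at] == "C"][1])
  })
  ok <- vapply(bb, function(b) !anyNA(c(b$N, b$CA, b$C)), logical(1))
  if (any(!ok))
    warning("skipping residues with missing backbone atoms: ",
            paste(res_ids[!ok], collapse = ", "))

  out <- vector("list", nrow(frames))
  for (f in seq_len(nrow(frames))) {
    xyz <- .frame_xyz(frames, f)
    phi <- psi <- rep(NA_real_, length(res_ids))
    for (i in seq_along(res_ids)) {
      if (!ok[i]) next
      b <- bb[[i]]
      if (i > 1L && ok[i - 1L]) {
        quad <- rbind(xyz[bb[[i - 1L]]$C, ], xyz[b$N, ], xyz[b$CA, ], xyz[b$C, ])
        phi[i] <- bio3d::torsion.xyz(as.numeric(t(quad)), atm.inc = 1)
      }
      if (i < length(res_ids) && ok[i + 1L]) {
        quad <- rbind(xyz[b$N, ], xyz[b$CA, ], xyz[b$C, ], xyz[bb[[i + 1L]]$N, ])
        psi[i] <- bio3d::torsion.xyz(as.numeric(t(quad)), atm.inc = 1)
      }
    }
    out[[f]] <- data.frame(frame = f, residue = res_ids, phi = phi, psi = psi)
  }
  do.call(rbind, out)
}

#' Write a per-residue contact map into PDB B-factors
#'
#' Annotates a reference structure with the scaled per-residue contact
#' value times 100 in the B-factor column; atoms with strictly zero
#' contacts throughout the trajectory are flagged with occupancy 0 (the
#' "never touched" class of surface maps).
#'
#' @param profile a [residue_profile()] result.
#' @param system the reference [particle_system()] to annotate.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
bfactor_contact_map <- function(profile, system, path) {
  n <- length(system$masses)
  side <- if (profile$by == "receptor") receptor_atoms(system) else ligand_atoms(system)
  idx <- match(system$residue_index[side], profile$residues$residue)
  if (anyNA(idx))
    stop("profile does not cover structure residues: ",
         paste(unique(system$residue_index[side][is.na(idx)]), collapse = ", "))
  b <- rep(0, n)
  b[side] <- 100 * profile$residues$scaled_total[idx]
  occ <- rep(1, n)
  zero_atoms <- profile$atoms$atom[profile$atoms$count == 0]
  occ[zero_atoms] <- 0
  chain <- ifelse(system$role == "receptor", "R", "L")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(system$positions)),
                   resno = system$residue_index,
                   resid = system$residue_name,
                   eleno = seq_len(n), elety = system$atom_name,
                   chain = chain, o = occ, b = b)
  invisible(path)
}
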