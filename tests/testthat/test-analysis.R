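# A tiny hand-built complex for contact bookkeeping: 3 receptor atoms in
# 2 residues, 2 ligand atoms in 1 residue, with known charges.
tiny_complex <- function(lig_shift = c(0, 0, 0)) {
  pos <- rbind(
    c(0, 0, 0), c(3, 0, 0), c(20, 0, 0), # receptor, residues 1, 1, 2
    c(0, 2, 0) + lig_shift, c(3, 2, 0) + lig_shift # ligand residue 1
  )
  particle_system(pos, masses = 1,
                  role = c(rep("receptor", 3), rep("ligand", 2)),
                  residue_index = c(1L, 1L, 2L, 1L, 1L),
                  charges = c(0.5, 0.1, -0.4, -0.3, 0.15))
}

frames_of <- function(...) {
  do.call(rbind, lapply(list(...), function(s) as.numeric(t(s$positions))))
}

test_that("contacts use a strict 4-Angstrom cutoff between partitions", {
  xyz <- rbind(c(0, 0, 0), c(3.9, 0, 0))
  got <- find_contacts(xyz, 1L, 2L)
  expect_equal(nrow(got), 1L)
  expect_equal(got$distance, 3.9)
  xyz2 <- rbind(c(0, 0, 0), c(4.0, 0, 0))
  expect_equal(nrow(find_contacts(xyz2, 1L, 2L)), 0L)
  # cutoff 0 finds nothing; growing cutoffs only add pairs
  set.seed(15)
  big <- matrix(runif(130 * 3, 0, 12), ncol = 3)
  expect_equal(nrow(find_contacts(big, 1:100, 101:130, cutoff = 0)), 0L)
  prev <- 0L
  for (co in c(2, 4, 6, 8)) {
    now <- nrow(find_contacts(big, 1:100, 101:130, cutoff = co))
    expect_gte(now, prev)
    prev <- now
  }
  expect_error(find_contacts(big, integer(0), 1:4), "non-empty")
})

test_that("contact sets equal the exhaustive quadratic scan", {
  set.seed(16)
  xyz <- matrix(runif(130 * 3, 0, 10), ncol = 3)
  got <- find_contacts(xyz, 1:100, 101:130, cutoff = 4)
  want <- bf_contacts(xyz, 1:100, 101:130, cutoff = 4)
  got <- got[order(got$atom_i, got$atom_j), ]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$atom_i, want[, 1])
  expect_equal(got$atom_j, want[, 2])
  expect_equal(got$distance, want[, 3], tolerance = 1e-12)
})

test_that("charge classification follows the threshold and sign rules", {
  expect_equal(classify_contact(0.5, -0.4), data.frame(polar = TRUE, hydrophobic = FALSE))
  expect_equal(classify_contact(0.1, 0.15), data.frame(polar = FALSE, hydrophobic = TRUE))
  expect_equal(classify_contact(0.1, -0.15), data.frame(polar = TRUE, hydrophobic = TRUE))
  expect_equal(classify_contact(0.5, 0.4), data.frame(polar = FALSE, hydrophobic = FALSE))
  # disjoint variant removes the doubly classified case
  expect_equal(classify_contact(0.1, -0.15, disjoint = TRUE),
               data.frame(polar = FALSE, hydrophobic = TRUE))
  expect_error(classify_contact(NA, 1), "finite")
})

test_that("residue profiles rescale by the largest per-residue total", {
  sys <- tiny_complex()
  prof <- residue_profile(frames_of(sys), sys)
  # residue 1 carries every contact, residue 2 none
  expect_equal(prof$residues$scaled_total, c(1, 0))
  expect_equal(max(prof$residues$scaled_total), 1)
  # duplicating frames leaves the scaled profile unchanged
  prof2 <- residue_profile(frames_of(sys, sys, sys), sys)
  expect_equal(prof2$residues$scaled_total, prof$residues$scaled_total)
  expect_equal(prof2$residues$scaled_polar, prof$residues$scaled_polar)
  expect_equal(prof2$normalization, 3 * prof$normalization)
  expect_error(residue_profile(matrix(0, 0, 15), sys), "frames")
})

test_that("a contact-free trajectory yields a flagged all-zero profile", {
  sys <- tiny_complex(lig_shift = c(0, 50, 0))
  prof <- residue_profile(frames_of(sys), sys)
  expect_true(prof$no_contacts)
  expect_true(all(prof$residues$scaled_total == 0))
})

test_that("per-residue tallies match an independent accumulation", {
  set.seed(18)
  nr <- 30; nl <- 10
  sys <- particle_system(matrix(runif((nr + nl) * 3, 0, 10), ncol = 3),
                         masses = 1,
                         role = c(rep("receptor", nr), rep("ligand", nl)),
                         residue_index = c(rep(1:6, each = 5), rep(1:2, each = 5)),
                         charges = round(runif(nr + nl, -0.5, 0.5), 2))
  nfr <- 4
  frames <- matrix(runif(nfr * (nr + nl) * 3, 0, 10), nrow = nfr)
  prof <- residue_profile(frames, sys)
  # naive recount
  tot <- pol <- hyd <- setNames(numeric(6), 1:6)
  for (f in seq_len(nfr)) {
    xyz <- matrix(frames[f, ], ncol = 3, byrow = TRUE)
    for (i in 1:nr) for (j in (nr + 1):(nr + nl)) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 4) {
        r <- as.character(sys$residue_index[i])
        tot[r] <- tot[r] + 1
        qi <- sys$charges[i]; qj <- sys$charges[j]
        if (qi * qj < 0) pol[r] <- pol[r] + 1
        if (abs(qi) < 0.2 && abs(qj) < 0.2) hyd[r] <- hyd[r] + 1
      }
    }
  }
  expect_equal(prof$residues$total, unname(tot))
  expect_equal(prof$residues$polar, unname(pol))
  expect_equal(prof$residues$hydrophobic, unname(hyd))
  expect_equal(prof$residues$scaled_total, unname(tot) / max(tot))
  # class counts never exceed totals
  expect_true(all(prof$residues$polar <= prof$residues$total))
  expect_true(all(prof$residues$hydrophobic <= prof$residues$total))
})

test_that("contact fraction tables count frames by construction", {
  sys <- tiny_complex()
  near <- frames_of(sys)
  far <- as.numeric(t(tiny_complex(lig_shift = c(0, 50, 0))$positions))
  frames <- rbind(near[rep(1, 3), ], matrix(far, 7, length(far), byrow = TRUE))
  tab <- contact_fraction_table(frames, sys, site_residues = c(1, 2),
                                probe_residue = 1)
  expect_equal(tab$percent[tab$residue == 1], 30.0)
  expect_equal(tab$percent[tab$residue == 2], 0.0)
  # always within cutoff -> 100
  tab2 <- contact_fraction_table(near[rep(1, 5), ], sys, 1, 1)
  expect_equal(tab2$percent, 100.0)
  expect_error(contact_fraction_table(frames, sys, 99, 1), "unknown site")
  expect_error(contact_fraction_table(frames, sys, 1, 99), "unknown probe")
  # equals 100 x mean of per-frame indicators, independent accumulation
  ind <- vapply(seq_len(nrow(frames)), function(f) {
    xyz <- matrix(frames[f, ], ncol = 3, byrow = TRUE)
    any(pmin(sqrt(colSums((t(xyz[c(1, 2), ]) - xyz[4, ])^2)),
             sqrt(colSums((t(xyz[c(1, 2), ]) - xyz[5, ])^2))) < 4)
  }, logical(1))
  expect_equal(tab$percent[1], 100 * mean(ind))
})

test_that("hot spots are residues with an atom above the scaled threshold", {
  # constructed so atoms accumulate known contact counts: receptor atoms
  # at increasing distance from a fixed ligand atom across frames
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(0, 1, 0))
  sys <- particle_system(pos, masses = 1,
                         role = c("receptor", "receptor", "receptor", "ligand"),
                         residue_index = c(1L, 2L, 3L, 1L),
                         charges = c(0.3, -0.3, 0.1, 0.2))
  # frame A: ligand near atom 1 only; frames B, C: near atom 2 only
  fA <- as.numeric(t(pos))
  posB <- pos; posB[4, ] <- c(10, 1, 0)
  fB <- as.numeric(t(posB))
  frames <- rbind(fA, fA, fA, fA, fA, fA, fA, fA, fA, # 9 contacts atom 1
                  fB, fB, fB, fB, fB, fB) # 6 contacts atom 2
  prof <- residue_profile(frames, sys)
  expect_equal(prof$atoms$scaled, c(1, 6 / 9, 0))
  expect_equal(hotspot_residues(prof, 0.5), c(1L, 2L))
  expect_equal(hotspot_residues(prof, 0.8), 1L)
  expect_equal(hotspot_residues(prof, 0.99), 1L)
  uniform <- prof
  uniform$atoms$scaled <- rep(0.4, 3)
  expect_equal(hotspot_residues(uniform, 0.5), integer(0))
  expect_error(hotspot_residues(prof, 1.5), "0, 1")
})

test_that("phi/psi match the analytic dihedral on constructed chains", {
  # planar all-trans zigzag: every phi and psi is 180 degrees
  n_res <- 4
  coords <- NULL
  x <- 0
  for (i in 1:(3 * n_res)) {
    coords <- rbind(coords, c(x, 0.5 * (i %% 2), 0))
    x <- x + 1
  }
  sys <- particle_system(coords, masses = 1, role = rep("ligand", 3 * n_res),
                         residue_index = rep(1:n_res, each = 3),
                         atom_name = rep(c("N", "CA", "C"), n_res))
  pp <- phi_psi(as.numeric(t(coords)), sys)
  expect_equal(abs(pp$phi[2:4]), rep(180, 3), tolerance = 1e-6)
  expect_equal(abs(pp$psi[1:3]), rep(180, 3), tolerance = 1e-6)
  expect_true(is.na(pp$phi[1]) && is.na(pp$psi[4]))

  # constructed +90 degree twist: psi of residue 1 from N-CA-C-N(2)
  quad <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  sys2 <- particle_system(rbind(quad, c(2, 1, 1), c(2, 2, 1)), masses = 1,
                          role = rep("ligand", 6),
                          residue_index = c(1L, 1L, 1L, 2L, 2L, 2L),
                          atom_name = c("N", "CA", "C", "N", "CA", "C"))
  pp2 <- phi_psi(as.numeric(t(sys2$positions)), sys2)
  expect_equal(pp2$psi[1], 90, tolerance = 1e-6)
  expect_equal(pp2$psi[1],
               bf_dihedral(quad[1, ], quad[2, ], quad[3, ], quad[4, ]),
               tolerance = 1e-6)

  # dihedrals are invariant under rigid rotation of all coordinates
  rot <- rigid_transform(sys2$positions)
  pp3 <- phi_psi(as.numeric(t(rot)), sys2)
  expect_equal(pp3$phi, pp2$phi, tolerance = 1e-9)
  expect_equal(pp3$psi, pp2$psi, tolerance = 1e-9)
})

test_that("phi/psi agree with the oracle on random backbones over frames", {
  set.seed(20)
  n_res <- 5
  sys <- particle_system(matrix(rnorm(n_res * 9, sd = 2), ncol = 3),
                         masses = 1, role = rep("ligand", 3 * n_res),
                         residue_index = rep(1:n_res, each = 3),
                         atom_name = rep(c("N", "CA", "C"), n_res))
  frames <- rbind(rnorm(n_res * 9, sd = 2), rnorm(n_res * 9, sd = 2))
  pp <- phi_psi(frames, sys)
  for (f in 1:2) {
    xyz <- matrix(frames[f, ], ncol = 3, byrow = TRUE)
    at <- function(r, nm) xyz[which(sys$residue_index == r &
                                      sys$atom_name == nm), ]
    for (r in 2:n_res) {
      want <- bf_dihedral(at(r - 1, "C"), at(r, "N"), at(r, "CA"), at(r, "C"))
      expect_equal(pp$phi[pp$frame == f & pp$residue == r], want,
                   tolerance = 1e-6)
    }
  }
})

test_that("missing backbone atoms skip the residue with a warning", {
  sys <- particle_system(matrix(rnorm(15), 5, 3), masses = 1,
                         role = rep("ligand", 5),
                         residue_index = c(1L, 1L, 1L, 2L, 2L),
                         atom_name = c("N", "CA", "C", "N", "CA"))
  expect_warning(pp <- phi_psi(as.numeric(t(matrix(rnorm(15), 5, 3))), sys),
                 "missing backbone")
  expect_true(all(is.na(pp$psi)))
})

test_that("B-factor maps encode scaled contacts and zero-contact flags", {
  sys <- tiny_complex()
  prof <- residue_profile(frames_of(sys), sys)
  tmp <- tempfile(fileext = ".pdb")
  bfactor_contact_map(prof, sys, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  rec <- pdb$atom$chain == "R"
  expect_equal(pdb$atom$b[rec], c(100, 100, 0))
  expect_equal(pdb$atom$o[rec], c(1, 1, 0)) # atom 3 never in contact
  # all-zero profile: B = 0 and occupancy 0 everywhere on the mapped side
  far <- tiny_complex(lig_shift = c(0, 50, 0))
  prof0 <- residue_profile(frames_of(far), far)
  bfactor_contact_map(prof0, far, tmp)
  pdb0 <- bio3d::read.pdb(tmp, verbose = FALSE)
  expect_true(all(pdb0$atom$b[pdb0$atom$chain == "R"] == 0))
  expect_true(all(pdb0$atom$o[pdb0$atom$chain == "R"] == 0))
})

test_that("analysis operations are pure", {
  cg <- make_cg_complex(n_receptor = 25, ligand_length = 4, seed = 6,
                        receptor_radius = 8)
  frames <- rbind(as.numeric(t(cg$system$positions)),
                  as.numeric(t(cg$system$positions)) + 0.05)
  p1 <- residue_profile(frames, cg$system)
  p2 <- residue_profile(frames, cg$system)
  expect_identical(p1$residues, p2$residues)
  expect_identical(p1$atoms, p2$atoms)
})
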