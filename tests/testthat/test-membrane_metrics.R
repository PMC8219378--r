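test_that("lipid contacts are molecule-level at the 5 A boundary", {
  s <- lipid_protein_structure(c("POPS", "POPC"))
  fr <- rbind(c(0, 0, 4.9), c(0, 0, 5.1), c(0, 0, 0)) # L1 in, L2 out
  traj <- toy_trajectory(s, list(fr))
  prof <- residue_lipid_contacts(traj, "chain A", "chain M", cutoff = 5,
                                 burn_in_fraction = 0)
  expect_equal(prof$mean_count, 1)

  # a lipid with two atoms inside the cutoff still counts once
  nl2 <- 2
  atoms <- rbind(
    make_atoms(matrix(0, 2, 3), resname = "POPS", resid = 1L, chain = "M"),
    make_atoms(matrix(0, 1, 3), resname = "GLY", resid = 1L, chain = "A"))
  atoms$serial <- 1:3
  s2 <- new_structure(atoms)
  fr2 <- rbind(c(0, 0, 4), c(1, 0, 4), c(0, 0, 0))
  prof2 <- residue_lipid_contacts(toy_trajectory(s2, list(fr2)),
                                  "chain A", "chain M", burn_in_fraction = 0)
  expect_equal(prof2$mean_count, 1)
})

test_that("burn-in discards ceil(f*n) frames before averaging", {
  traj <- ten_frame_fixture()
  prof <- residue_lipid_contacts(traj, "chain A", "chain M",
                                 burn_in_fraction = 0.3)
  expect_equal(prof$mean_count, 1.0) # frames 1-3 dropped, 4-10 all contact
  expect_equal(attr(prof, "n_frames_used"), 7)
  expect_error(residue_lipid_contacts(traj, "chain A", "chain M",
                                      burn_in_fraction = 0.999),
               "zero frames")
})

test_that("burn-in by fraction equals explicit truncation", {
  traj <- random_membrane_traj()
  full <- residue_lipid_contacts(traj, "chain A", "chain M",
                                 burn_in_fraction = 0.3)
  k <- ceiling(0.3 * n_frames(traj))
  trunc <- new_trajectory(traj$topology, traj$times[-seq_len(k)],
                          traj$frames[-seq_len(k)])
  manual <- residue_lipid_contacts(trunc, "chain A", "chain M",
                                   burn_in_fraction = 0)
  expect_equal(full$mean_count, manual$mean_count)
})

test_that("raising the cutoff never lowers a residue's mean count", {
  traj <- random_membrane_traj(seed = 77)
  prev <- NULL
  for (cut in c(3, 5, 8, 12)) {
    p <- residue_lipid_contacts(traj, "chain A", "chain M", cutoff = cut,
                                burn_in_fraction = 0)$mean_count
    if (!is.null(prev)) expect_true(all(p >= prev - 1e-12))
    prev <- p
  }
  # bounded by the number of lipid molecules
  expect_true(all(prev <= 12))
})

test_that("contact map row-means reproduce the residue profile exactly", {
  traj <- random_membrane_traj(seed = 55)
  cm <- contact_map(traj, "chain A", "chain M", cutoff = 5)
  expect_equal(dim(cm), c(3, n_frames(traj)))
  for (f in c(0, 0.3)) {
    prof <- residue_lipid_contacts(traj, "chain A", "chain M", cutoff = 5,
                                   burn_in_fraction = f)
    from <- if (f == 0) 1 else ceiling(f * n_frames(traj)) + 1
    expect_equal(unname(rowMeans(cm[, from:ncol(cm), drop = FALSE])),
                 prof$mean_count)
  }

  # hand enumeration on the 10-frame fixture
  cm10 <- contact_map(ten_frame_fixture(), "chain A", "chain M")
  expect_equal(unname(cm10[1, ]), c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1))

  # no contacts anywhere -> all-zero map
  far <- ten_frame_fixture()
  far$frames <- lapply(far$frames, function(fr) { fr[1, 3] <- 100; fr })
  expect_true(all(contact_map(far, "chain A", "chain M") == 0))
})

test_that("contact-residue count series matches hand-built frames", {
  types <- rep("POPC", 3)
  s <- lipid_protein_structure(types, n_res = 3)
  # protein residues at x = 0, 10, 20; lipids move under them
  prot <- cbind(c(0, 10, 20), 0, 3)
  f1 <- rbind(cbind(c(0, 10, 50), 0, 0), prot)   # r1, r2 in contact
  f2 <- rbind(cbind(c(0, 10, 20), 0, 0), prot)   # r1, r2, r3
  traj <- toy_trajectory(s, list(f1, f2))
  cnt <- contact_residue_count_series(traj, "chain A", "chain M", cutoff = 5)
  expect_equal(cnt$values, c(2, 3))
  expect_equal(cnt$times, traj$times)

  none <- toy_trajectory(s, list(rbind(cbind(c(0, 10, 20), 0, 40), prot)))
  expect_equal(contact_residue_count_series(none, "chain A", "chain M")$values, 0)

  # equals a brute-force recomputation via neighbor pairs
  traj2 <- random_membrane_traj(seed = 91)
  got <- contact_residue_count_series(traj2, "chain A", "chain M", 5)$values
  oracle <- vapply(traj2$frames, function(fr) {
    pl <- brute_pairs(fr[13:15, , drop = FALSE], fr[1:12, , drop = FALSE], 5)
    length(unique(pl[, 1]))
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("enrichment arithmetic, missing frames, and permutation null", {
  types <- c(rep("POPS", 3), rep("POPC", 7)) # baseline 0.3
  s <- lipid_protein_structure(types, n_res = 1)
  lip_far <- cbind(seq(0, 90, by = 10), 50, 0)
  # frame 1: only the three POPS molecules contact -> fraction 1
  f1 <- lip_far; f1[1:3, ] <- cbind(c(0, 2, 4), 0, 0)
  # frame 2: only two POPC molecules contact -> fraction 0
  f2 <- lip_far; f2[4:5, ] <- cbind(c(0, 2), 0, 0)
  # frame 3: nothing contacts -> missing
  prot <- matrix(c(0, 0, 3), 1, 3)
  traj <- toy_trajectory(s, list(rbind(f1, prot), rbind(f2, prot),
                                 rbind(lip_far, prot)))
  enr <- lipid_enrichment(traj, "chain A", "chain M", "POPS", cutoff = 5)
  expect_equal(enr$baseline, rep(0.3, 3))
  expect_equal(enr$fraction, c(1, 0, NA))
  expect_equal(enr$enrichment, c(1 / 0.3, 0, NA))
  expect_error(lipid_enrichment(traj, "chain A", "chain M", "CHOL"),
               "not present")

  # random type relabelling at fixed geometry: mean enrichment ~ 1
  set.seed(404)
  vals <- replicate(200, {
    sh <- lipid_protein_structure(sample(types), n_res = 1)
    tr <- toy_trajectory(sh, list(rbind(f1, prot)))
    lipid_enrichment(tr, "chain A", "chain M", "POPS")$enrichment[1]
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 2.1 * se + 1e-12)
})

test_that("membrane contact-area series is zero at 50 A separation", {
  s <- lipid_protein_structure(rep("POPC", 4), n_res = 1)
  lip <- cbind(c(0, 4, 8, 12), 0, 0)
  frames <- lapply(1:3, function(f) rbind(lip, c(6, 0, 50)))
  traj <- toy_trajectory(s, frames, times = c(0, 2, 4))
  ser <- membrane_contact_area_series(traj, "chain A", "chain M",
                                      n_points = 240)
  expect_equal(ser$values, c(0, 0, 0))
  expect_equal(ser$times, c(0, 2, 4))
  expect_length(ser$values, n_frames(traj))
})
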