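test_that("membrane planner reproduces the printed leaflet compositions", {
  counts <- plan_membrane(540, c(POPC = 0.70, POPS = 0.25, PIP2 = 0.05))
  expect_equal(unname(counts), c(378L, 135L, 27L))
  expect_equal(names(counts), c("POPC", "POPS", "PIP2"))

  counts2 <- plan_membrane(10, c(POPC = 0.7, POPS = 0.3))
  expect_equal(unname(counts2), c(7L, 3L))

  thirds <- plan_membrane(3, c(POPC = 1 / 3, POPS = 1 / 3, PIP2 = 1 / 3))
  expect_equal(unname(thirds), c(1L, 1L, 1L))

  expect_error(plan_membrane(10, c(POPC = 1.2, POPS = -0.2)), "negative")
  expect_error(plan_membrane(10, c(POPC = 0.6, POPS = 0.3)), "sum to 1")
})

test_that("plan -> build -> audit round-trips compositions exactly", {
  cfg <- synth_config(n_lipids_lower = 540, n_sweeps = 1)
  sys <- build_system(cfg)
  aud <- audit_membrane(sys$structure)
  expect_equal(aud$fraction[aud$resname == "PIP2"], 0.05)
  expect_equal(aud$count[aud$resname == "PIP2"], 27L)
  expect_equal(sum(aud$count), 540L)

  single <- build_system(synth_config(n_lipids_lower = 25,
                                      lipid_fractions = c(POPC = 1)))
  aud1 <- audit_membrane(single$structure)
  expect_equal(aud1$fraction, 1)

  set.seed(71)
  for (rep in 1:10) {
    fr <- stats::runif(3); fr <- fr / sum(fr)
    names(fr) <- c("POPC", "POPS", "PIP2")
    n <- sample(20:200, 1)
    planned <- plan_membrane(n, fr)
    s <- build_system(synth_config(n_lipids_lower = n, lipid_fractions = fr,
                                   seed = rep))$structure
    aud <- audit_membrane(s)
    expect_equal(stats::setNames(aud$count, aud$resname),
                 planned[planned > 0])
  }
})

test_that("ion planning is physiological and neutralizing", {
  # 55,345 waters at 150 mM: pairs = round(0.150 * 55345 / 55.345) = 150
  ions <- plan_ions(55345, 0.150)
  expect_equal(ions$pairs, 150L)
  expect_equal(ions$n_na, 150L)
  expect_equal(ions$n_cl, 150L)

  neut <- plan_ions(1000, 0, solute_charge = -4)
  expect_equal(neut$n_na, 4L)
  expect_equal(neut$n_cl, 0L)

  a <- plan_ions(10000, 0.15)$pairs
  b <- plan_ions(20000, 0.15)$pairs
  expect_lte(abs(b - 2 * a), 1) # linear within rounding
  expect_error(plan_ions(100, -0.1), ">= 0")
})

test_that("system construction is deterministic and structurally coherent", {
  cfg <- synth_config(n_lipids_lower = 64, n_domain_beads = 24,
                      tail_beads = 3, seed = 5)
  s1 <- build_system(cfg)
  s2 <- build_system(cfg)
  expect_identical(coords(s1$structure), coords(s2$structure))
  expect_identical(s1$charges, s2$charges)

  s3 <- build_system(synth_config(n_lipids_lower = 64, n_domain_beads = 24,
                                  tail_beads = 3, seed = 6))
  expect_false(identical(s1$structure$atoms$resname,
                         s3$structure$atoms$resname))

  # bead bookkeeping
  expect_length(s1$groups$lipid, 64)
  expect_length(s1$groups$domain, 24)
  expect_length(s1$groups$tail, 3)
  expect_equal(nrow(s1$bonds), 4) # anchor -> t1 -> t2 -> t3 -> attach
  expect_equal(sum(s1$charges[s1$groups$patch]),
               cfg$n_patch_beads * cfg$patch_charge_per_bead)
  # patch beads face the membrane: they are the lowest domain beads
  zdom <- coords(s1$structure)[s1$groups$domain, 3]
  expect_true(max(coords(s1$structure)[s1$groups$patch, 3]) <=
                sort(zdom)[cfg$n_patch_beads] + 1e-9)

  # degenerate tail: domain bonded directly to the anchor
  s0 <- build_system(synth_config(n_lipids_lower = 16, n_domain_beads = 12,
                                  tail_beads = 0))
  expect_equal(nrow(s0$bonds), 1)
  expect_equal(s0$bonds[1, 1], s0$groups$anchor)
  expect_equal(s0$bonds[1, 2], s0$groups$attach)
})

test_that("energy terms match closed forms", {
  # zero charges, no overlaps, relaxed bond -> total exactly 0
  cfg <- synth_config(n_lipids_lower = 16, n_domain_beads = 12,
                      tail_beads = 0, bond_length = 5,
                      lipid_fractions = c(POPC = 1),
                      patch_charge_per_bead = 0)
  sys <- build_system(cfg)
  xyz <- coords(sys$structure)
  shift <- xyz[sys$groups$anchor, ] + c(0, 0, 5) - xyz[sys$groups$attach, ]
  xyz[sys$groups$domain, ] <- sweep(xyz[sys$groups$domain, ], 2, shift, "+")
  e <- system_energy(sys, xyz)
  expect_equal(e$total, 0, tolerance = 1e-12)

  # screened Coulomb reduces to the bare hand formula at infinite screening
  cfg2 <- synth_config(n_lipids_lower = 1, lipid_fractions = c(POPS = 1),
                       n_domain_beads = 3, n_patch_beads = 1,
                       patch_charge_per_bead = 1, tail_beads = 0,
                       debye_length = 1e12)
  sys2 <- build_system(cfg2)
  xyz2 <- coords(sys2$structure)
  ch <- which(sys2$charges != 0)
  r <- sqrt(sum((xyz2[ch[1], ] - xyz2[ch[2], ])^2))
  hand <- 560.47 * (1) * (-1) / (cfg2$dielectric * r)
  expect_equal(system_energy(sys2, xyz2)$electrostatic, hand,
               tolerance = 1e-9)

  # breakdown parts sum to the total
  sys3 <- build_system(synth_config(n_lipids_lower = 36, n_domain_beads = 16,
                                    tail_beads = 2, seed = 2))
  e3 <- system_energy(sys3)
  expect_equal(e3$total,
               e3$electrostatic + e3$excluded_volume + e3$bonds,
               tolerance = 1e-9)
})

test_that("vectorized energy equals the explicit pair-loop oracle", {
  cfg <- synth_config(n_lipids_lower = 36, n_domain_beads = 16,
                      tail_beads = 3, seed = 9, n_sweeps = 60,
                      save_stride = 20)
  traj <- simulate_tether(cfg)
  sys <- attr(traj, "system")
  for (f in c(1, n_frames(traj))) {
    e <- system_energy(sys, traj$frames[[f]])
    o <- oracle_energy(sys, traj$frames[[f]])
    expect_equal(e$electrostatic, o$electrostatic, tolerance = 1e-9)
    expect_equal(e$excluded_volume, o$excluded_volume, tolerance = 1e-9)
    expect_equal(e$bonds, o$bonds, tolerance = 1e-9)
    expect_equal(e$total, o$total, tolerance = 1e-9)
  }
  # the Monte Carlo delta energy agrees with the full-energy difference
  x1 <- traj$frames[[1]]; x2 <- traj$frames[[n_frames(traj)]]
  dE_mobile <- memtether:::mobile_energy(x2, sys) -
    memtether:::mobile_energy(x1, sys)
  dE_full <- system_energy(sys, x2)$total - system_energy(sys, x1)$total
  expect_equal(dE_mobile, dE_full, tolerance = 1e-9)
})

test_that("Metropolis acceptance satisfies the detailed-balance ratio", {
  kT <- 0.7
  for (dE in c(-2, -0.3, 0.4, 1.5)) {
    p_fwd <- min(1, exp(-dE / kT))
    p_rev <- min(1, exp(dE / kT))
    expect_equal(p_fwd / p_rev, exp(-dE / kT), tolerance = 1e-12)
    set.seed(123)
    acc <- mean(replicate(4000, memtether:::metropolis_accept(dE, kT)))
    expect_lt(abs(acc - p_fwd), 0.03)
  }
})

test_that("simulation is reproducible and descends at zero temperature", {
  cfg <- synth_config(n_lipids_lower = 36, n_domain_beads = 16,
                      tail_beads = 2, seed = 13, n_sweeps = 120,
                      save_stride = 20)
  t1 <- simulate_tether(cfg)
  t2 <- simulate_tether(cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(attr(t1, "manifest")$energy_trace,
                   attr(t2, "manifest")$energy_trace)

  t3 <- simulate_tether(synth_config(n_lipids_lower = 36,
                                     n_domain_beads = 16, tail_beads = 2,
                                     seed = 14, n_sweeps = 120,
                                     save_stride = 20))
  expect_false(identical(t1$frames, t3$frames))

  # kT -> 0: the energy trace over saved frames never increases
  cold <- simulate_tether(synth_config(n_lipids_lower = 36,
                                       n_domain_beads = 16, tail_beads = 2,
                                       seed = 15, n_sweeps = 150,
                                       save_stride = 10,
                                       temperature_kT = 1e-8))
  expect_true(all(diff(attr(cold, "manifest")$energy_trace) <= 1e-9))

  expect_error(simulate_tether(synth_config(n_sweeps = 0)), "positive")
})

test_that("trajectories emit as multi-model PDB and re-analyse unchanged", {
  cfg <- synth_config(n_lipids_lower = 25, n_domain_beads = 12,
                      tail_beads = 2, seed = 4, n_sweeps = 40,
                      save_stride = 10)
  traj <- simulate_tether(cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  topo <- read_structure(f)
  expect_equal(audit_membrane(topo)$count,
               audit_membrane(traj$topology)$count)
  back <- read_trajectory(f, topo)
  expect_equal(n_frames(back), n_frames(traj))
  cnt1 <- contact_residue_count_series(traj, "chain A", "chain M")
  cnt2 <- contact_residue_count_series(back, "chain A", "chain M")
  expect_equal(cnt2$values, cnt1$values)
})
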