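# Coarse-grained stand-in for microsecond membrane MD: a rigid bead-shell
# domain with a tunable positively charged surface patch, tethered to a
# fixed membrane anchor by a flexible tail, above an immobile two-component
# (POPC/POPS/PIP2) lower-leaflet bead lattice. Sampling is Metropolis Monte
# Carlo under screened (Debye-Hueckel) electrostatics, a soft-core
# excluded-volume repulsion against the lipid beads and the z<0 half-space,
# and harmonic bonds along the tether. Lipids are immobile by design: the
# target is the analysis machinery, not membrane physics, and a frozen
# lipid field keeps an independent rejection-sampling oracle tractable.
#
# Nominal bead charges: POPC 0, POPS -1, PIP2 -4 (physiological net
# charges; only the relative ordering matters for the trend observables).

KT_COULOMB <- 560.47  # e^-2 * Angstrom * kT at 300 K (332.06 kcal/mol / 0.5925)

#' Configuration for the synthetic membrane-tether generator
#'
#' Defaults state the emulated world: a 540-lipid lower leaflet at
#' POPC:POPS:PIP2 = 70:25:5 (the composition used to study anionic-lipid
#' enrichment, giving 27 PIP2 molecules), a Debye length of 7.9 Angstrom
#' (150 mM monovalent salt), water dielectric 80, and a GTPase-sized bead
#' shell (radius 14 A, 60 beads) whose membrane-facing polar cap can carry
#' charge. Time is the Monte Carlo sweep index, labelled ns nominally.
#'
#' @param n_lipids_lower lipid beads in the lower leaflet.
#' @param lipid_fractions named fractions for POPC/POPS/PIP2; must sum to 1.
#' @param lipid_spacing lattice spacing in Angstrom (~ area per lipid 64 A^2).
#' @param domain_radius rigid domain shell radius, Angstrom.
#' @param n_domain_beads beads on the domain shell.
#' @param patch_charge_per_bead elementary charge per patch bead.
#' @param n_patch_beads beads in the membrane-facing polar cap that carry
#'   the patch charge.
#' @param tail_beads beads of the flexible C-terminal tail (0 = domain
#'   bonded directly to the anchor).
#' @param bond_length tether bond length, Angstrom (3.8: one residue per
#'   bead).
#' @param debye_length electrostatic screening length, Angstrom.
#' @param dielectric relative dielectric constant.
#' @param temperature_kT sampling temperature in units of kT.
#' @param n_sweeps Monte Carlo sweeps.
#' @param save_stride save a frame every this many sweeps.
#' @param seed integer seed; identical configurations reproduce the
#'   trajectory bit-for-bit.
#' @param bead_radius van der Waals radius of every bead, Angstrom.
#' @param k_bond harmonic bond constant, kT/A^2.
#' @param k_ev soft-core repulsion strength, kT.
#' @param max_translation,max_rotation_deg,max_crank_deg,max_displacement
#'   Monte Carlo move amplitudes (Angstrom / degrees / Angstrom). The
#'   per-bead displacement move is what samples the harmonic bond lengths:
#'   crankshaft rotations preserve the distances to both bonded neighbours,
#'   so without displacements the tail bond lengths would be frozen at
#'   their initial values and the chain would not be ergodic.
#' @return object of class `SynthConfig`.
#' @export
synth_config <- function(n_lipids_lower = 540,
                         lipid_fractions = c(POPC = 0.70, POPS = 0.25,
                                             PIP2 = 0.05),
                         lipid_spacing = 8,
                         domain_radius = 14,
                         n_domain_beads = 60,
                         patch_charge_per_bead = 1,
                         n_patch_beads = 12,
                         tail_beads = 4,
                         bond_length = 3.8,
                         debye_length = 7.9,
                         dielectric = 80,
                         temperature_kT = 1,
                         n_sweeps = 2000,
                         save_stride = 25,
                         seed = 1,
                         bead_radius = 2.2,
                         k_bond = 10,
                         k_ev = 10,
                         max_translation = 1,
                         max_rotation_deg = 5,
                         max_crank_deg = 30,
                         max_displacement = 0.5) {
  if (abs(sum(lipid_fractions) - 1) > 1e-9) {
    stop("lipid_fractions must sum to 1")
  }
  if (any(lipid_fractions < 0)) stop("negative fraction")
  if (tail_beads < 0) stop("tail_beads must be >= 0")
  if (n_patch_beads > n_domain_beads) stop("patch larger than domain")
  if (bead_radius <= 0.5 || bead_radius >= 3.0) {
    stop("bead_radius must lie in (0.5, 3.0) Angstrom")
  }
  cfg <- list(n_lipids_lower = as.integer(n_lipids_lower),
              lipid_fractions = lipid_fractions,
              lipid_spacing = lipid_spacing,
              domain_radius = domain_radius,
              n_domain_beads = as.integer(n_domain_beads),
              patch_charge_per_bead = patch_charge_per_bead,
              n_patch_beads = as.integer(n_patch_beads),
              tail_beads = as.integer(tail_beads),
              bond_length = bond_length,
              debye_length = debye_length,
              dielectric = dielectric,
              temperature_kT = temperature_kT,
              n_sweeps = as.integer(n_sweeps),
              save_stride = as.integer(save_stride),
              seed = as.integer(seed),
              bead_radius = bead_radius,
              k_bond = k_bond,
              k_ev = k_ev,
              max_translation = max_translation,
              max_rotation_deg = max_rotation_deg,
              max_crank_deg = max_crank_deg,
              max_displacement = max_displacement)
  structure(cfg, class = "SynthConfig")
}

#' RhoD-like generator preset: charged patch, short tail
#'
#' Twelve +1 patch beads on the membrane-facing cap and a 4-bead tail: the
#' short-tail, positive-interface phenotype.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synth_config()].
#' @return a `SynthConfig`.
#' @export
rhod_like_config <- function(seed = 1, ...) {
  synth_config(n_patch_beads = 12, patch_charge_per_bead = 1,
               tail_beads = 4, seed = seed, ...)
}

#' RND1-like generator preset: neutral interface, long tail
#'
#' No patch charge and a 14-bead tail: the long, flexible tether phenotype
#' with no specific membrane interface.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synth_config()].
#' @return a `SynthConfig`.
#' @export
rnd1_like_config <- function(seed = 1, ...) {
  synth_config(patch_charge_per_bead = 0, tail_beads = 14, seed = seed, ...)
}

# ---------------------------------------------------------------------------
# Composition and ion planning
# ---------------------------------------------------------------------------

#' Plan lipid counts for a leaflet composition
#'
#' Integer counts by largest-remainder rounding; counts always sum to
#' `n_lipids`. Remainder ties are broken by the order of `fractions`
#' (the fixed type order POPC > POPS > PIP2 for the default membrane).
#'
#' @param n_lipids total lipid count (> 0).
#' @param fractions named non-negative fractions summing to 1.
#' @return named integer vector of per-type counts.
#' @export
plan_membrane <- function(n_lipids, fractions) {
  if (n_lipids <= 0) stop("n_lipids must be positive")
  if (any(fractions < 0)) stop("negative fraction")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  exact <- n_lipids * fractions
  counts <- floor(exact)
  short <- n_lipids - sum(counts)
  if (short > 0) {
    rem <- exact - counts
    # order by remainder descending; ties resolved by input (type) order
    pick <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[pick] <- counts[pick] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Audit the lipid composition of a built structure
#'
#' Molecule-level counts and fractions per lipid residue name; the
#' round-trip check of [plan_membrane()].
#'
#' @param s a `Structure`.
#' @param lipid_resnames residue names regarded as lipids.
#' @return data.frame with columns `resname`, `count`, `fraction`.
#' @export
audit_membrane <- function(s, lipid_resnames = c("POPC", "POPS", "PIP2")) {
  at <- s$atoms
  lip <- at[at$resname %in% lipid_resnames, , drop = FALSE]
  if (nrow(lip) == 0L) stop("no lipid residues in structure")
  mols <- unique(lip[, c("chain", "resid", "resname")])
  levels <- intersect(lipid_resnames, unique(mols$resname))
  cnt <- table(factor(mols$resname, levels = levels))
  data.frame(resname = names(cnt), count = as.integer(cnt),
             fraction = as.integer(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Plan Na+/Cl- ion counts for a solvated system
#'
#' Salt pairs from the molar ratio of ions to water
#' (`round(concentration * n_waters / 55.345)`, 55.345 M being the molarity
#' of water), then the counter-ion count is raised to neutralize the net
#' solute charge.
#'
#' @param n_waters number of water molecules.
#' @param concentration salt concentration, mol/L (>= 0).
#' @param solute_charge net solute charge in elementary charges.
#' @return list with `n_na`, `n_cl`, `pairs`, `extra` (neutralizing ions).
#' @export
plan_ions <- function(n_waters, concentration, solute_charge = 0) {
  if (concentration < 0) stop("concentration must be >= 0")
  if (n_waters < 0) stop("n_waters must be >= 0")
  if (solute_charge != round(solute_charge)) {
    stop("solute_charge must be an integer charge")
  }
  pairs <- round(concentration * n_waters / 55.345)
  extra <- as.integer(abs(solute_charge))
  n_na <- pairs + if (solute_charge < 0) extra else 0L
  n_cl <- pairs + if (solute_charge > 0) extra else 0L
  if (n_na < 0 || n_cl < 0) stop("neutralization requires a negative ion count")
  list(n_na = as.integer(n_na), n_cl = as.integer(n_cl),
       pairs = as.integer(pairs), extra = extra)
}

# ---------------------------------------------------------------------------
# System construction
# ---------------------------------------------------------------------------

fibonacci_sphere <- function(n, radius) {
  radius * cpp_sphere_points(as.integer(n))
}

# evaluate f() under a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  f()
}

#' Build the synthetic membrane-tether system
#'
#' Lower leaflet: a square bead lattice at z = 0 whose types come from
#' [plan_membrane()] and are shuffled with the seeded generator. Domain: a
#' rigid golden-spiral bead shell; the `n_patch_beads` beads of its
#' membrane-facing polar cap carry `patch_charge_per_bead` each. Tail: a
#' freely jointed chain from a fixed membrane anchor bead at the lattice
#' center to the lowest domain bead. Initial pose: domain center at
#' `domain_radius + bond_length` above the plane, patch facing the
#' membrane.
#'
#' @param config a `SynthConfig`.
#' @return object of class `SynthSystem`: list with `structure` (the
#'   topology, lipids as POPC/POPS/PIP2 residues on chain M, tail/anchor on
#'   chain T, domain beads as single-residue protein beads on chain A),
#'   `charges`, `radii`, `bonds` (two-column index matrix), `groups`
#'   (index vectors `lipid`, `domain`, `tail`, `anchor`, `patch`) and
#'   `config`.
#' @export
build_system <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  nl <- config$n_lipids_lower
  counts <- plan_membrane(nl, config$lipid_fractions)
  types <- rep(names(counts), counts)
  types <- with_seed(config$seed, function() sample(types))

  side <- ceiling(sqrt(nl))
  ij <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(nl), ]
  lx <- (ij$ix - (side + 1) / 2) * config$lipid_spacing
  ly <- (ij$iy - (side + 1) / 2) * config$lipid_spacing
  lip_xyz <- cbind(lx, ly, 0)

  zc <- config$domain_radius + config$bond_length
  dom_xyz <- fibonacci_sphere(config$n_domain_beads, config$domain_radius)
  dom_xyz[, 3] <- dom_xyz[, 3] + zc
  if (zc - config$domain_radius < 0) {
    stop("domain overlaps the membrane at start")
  }
  patch_local <- order(dom_xyz[, 3])[seq_len(config$n_patch_beads)]
  attach_local <- which.min(dom_xyz[, 3])

  anchor_xyz <- c(config$lipid_spacing / 2, config$lipid_spacing / 2, 0)
  k <- config$tail_beads
  attach_pos <- dom_xyz[attach_local, ]
  tail_xyz <- if (k > 0) {
    f <- seq_len(k) / (k + 1)
    cbind(anchor_xyz[1] + f * (attach_pos[1] - anchor_xyz[1]),
          anchor_xyz[2] + f * (attach_pos[2] - anchor_xyz[2]),
          anchor_xyz[3] + f * (attach_pos[3] - anchor_xyz[3]))
  } else {
    matrix(numeric(0), 0, 3)
  }

  xyz <- rbind(lip_xyz, matrix(anchor_xyz, 1, 3), tail_xyz, dom_xyz)
  n_total <- nrow(xyz)
  lip_idx <- seq_len(nl)
  anchor_idx <- nl + 1L
  tail_idx <- if (k > 0) nl + 1L + seq_len(k) else integer(0)
  dom_idx <- nl + 1L + k + seq_len(config$n_domain_beads)
  patch_idx <- dom_idx[patch_local]
  attach_idx <- dom_idx[attach_local]

  atoms <- data.frame(
    serial = seq_len(n_total),
    name = "BD",
    element = "X",
    resname = c(types, "ANC", rep("TAI", k), rep("DOM", config$n_domain_beads)),
    resid = c(seq_len(nl), 1L, if (k > 0) 1L + seq_len(k) else integer(0),
              seq_len(config$n_domain_beads)),
    chain = c(rep("M", nl), rep("T", 1L + k),
              rep("A", config$n_domain_beads)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)

  box_l <- side * config$lipid_spacing
  s <- new_structure(atoms, box = c(box_l, box_l, 200))

  lipid_charge <- c(POPC = 0, POPS = -1, PIP2 = -4)
  charges <- numeric(n_total)
  charges[lip_idx] <- lipid_charge[types]
  charges[patch_idx] <- config$patch_charge_per_bead

  chain_idx <- c(anchor_idx, tail_idx, attach_idx)
  bonds <- cbind(chain_idx[-length(chain_idx)], chain_idx[-1])

  structure(list(structure = s, charges = charges,
                 radii = rep(config$bead_radius, n_total),
                 bonds = bonds,
                 groups = list(lipid = lip_idx, domain = dom_idx,
                               tail = tail_idx, anchor = anchor_idx,
                               patch = patch_idx, attach = attach_idx),
                 config = config),
            class = "SynthSystem")
}

#' Radius table for synthetic bead systems
#'
#' Beads are written with element `X`; this maps `X` to the configured bead
#' radius for SASA-based metrics.
#'
#' @param config a `SynthConfig`.
#' @return a radius table as returned by [bondi_radii()].
#' @export
synth_radius_table <- function(config) {
  bondi_radii(extra = c(X = config$bead_radius),
              default = config$bead_radius)
}

# ---------------------------------------------------------------------------
# Energy
# ---------------------------------------------------------------------------

bond_energy <- function(xyz, sys) {
  b <- sys$bonds
  if (nrow(b) == 0L) return(0)
  d <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                       xyz[b[, 2], , drop = FALSE])^2))
  sum(sys$config$k_bond * (d - sys$config$bond_length)^2)
}

# mobile-side energy used for Metropolis deltas: everything that can change
# under a domain/tail move (tether bonds, mobile-vs-lipid electrostatics and
# excluded volume, wall). Rigid-internal patch-patch electrostatics and the
# frozen lipid-lipid field are constant and omitted.
mobile_energy <- function(xyz, sys) {
  cfg <- sys$config
  prot <- c(sys$groups$domain, sys$groups$tail)
  lip <- sys$groups$lipid
  cpp_mobile_energy(xyz[prot, , drop = FALSE], sys$charges[prot],
                    xyz[lip, , drop = FALSE], sys$charges[lip],
                    cfg$debye_length, cfg$dielectric, KT_COULOMB,
                    2 * cfg$bead_radius, cfg$k_ev) +
    bond_energy(xyz, sys)
}

#' Full energy breakdown of a synthetic-system frame
#'
#' Terms (all in kT): `electrostatic`, the Debye-Hueckel screened Coulomb
#' sum over every charged bead pair (including the frozen lipid-lipid
#' field), with the pair distance clamped at the bead contact distance
#' `2 * bead_radius` so the attraction between finite beads stays bounded
#' and the soft core can genuinely exclude volume;
#' `excluded_volume`, the soft-core repulsion of domain/tail beads
#' against lipid beads plus the z < 0 half-space wall; `bonds`, the
#' harmonic tether; and their `total`. Energies are finite for any input
#' by construction of the soft core. Open boundaries: the lipid patch is
#' finite and no periodic images enter the energy.
#'
#' @param sys a `SynthSystem`.
#' @param xyz optional N x 3 coordinates (defaults to the built initial
#'   frame).
#' @return object of class `EnergyBreakdown`.
#' @export
system_energy <- function(sys, xyz = NULL) {
  stopifnot(inherits(sys, "SynthSystem"))
  cfg <- sys$config
  if (is.null(xyz)) xyz <- coords(sys$structure)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")

  ch <- which(sys$charges != 0)
  elec <- 0
  if (length(ch) > 1L) {
    q <- sys$charges[ch]
    p <- xyz[ch, , drop = FALSE]
    dmat <- as.matrix(stats::dist(p))
    iu <- which(upper.tri(dmat), arr.ind = TRUE)
    r <- pmax(dmat[upper.tri(dmat)], 2 * cfg$bead_radius)
    qq <- q[iu[, 1]] * q[iu[, 2]]
    elec <- sum(KT_COULOMB * qq * exp(-r / cfg$debye_length) /
                  (cfg$dielectric * r))
  }

  prot <- c(sys$groups$domain, sys$groups$tail)
  lip <- sys$groups$lipid
  sigma <- 2 * cfg$bead_radius
  pv <- xyz[prot, , drop = FALSE]
  lv <- xyz[lip, , drop = FALSE]
  ev <- 0
  for (i in seq_len(nrow(pv))) {
    dd <- sqrt(colSums((t(lv) - pv[i, ])^2))
    near <- dd < sigma
    if (any(near)) ev <- ev + sum(cfg$k_ev * (1 - dd[near] / sigma)^2)
  }
  zneg <- pv[, 3] < 0
  if (any(zneg)) ev <- ev + sum(cfg$k_ev * pv[zneg, 3]^2)

  bonds <- bond_energy(xyz, sys)
  structure(list(electrostatic = elec, excluded_volume = ev, bonds = bonds,
                 total = elec + ev + bonds),
            class = "EnergyBreakdown")
}

# ---------------------------------------------------------------------------
# Metropolis Monte Carlo
# ---------------------------------------------------------------------------

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

metropolis_accept <- function(dE, kT) {
  dE <= 0 || stats::runif(1) < exp(-dE / kT)
}

#' Run the Metropolis Monte Carlo tether simulation
#'
#' Per sweep: one rigid-body domain translation (uniform direction, length
#' up to `max_translation`), one rigid rotation about the domain center
#' (random axis, angle up to `max_rotation_deg`), and per tail bead one
#' crankshaft rotation (about the axis through the bead's two bonded
#' neighbours; bond-length preserving) plus one random displacement of up
#' to `max_displacement` (which samples the bond lengths themselves and
#' keeps the chain ergodic). All proposals are symmetric, so plain Metropolis
#' acceptance at `temperature_kT` samples the Boltzmann distribution of
#' [system_energy()] (up to the constant frozen-field terms). One seeded
#' generator stream drives lipid-type shuffling (inside [build_system()]),
#' move proposals and acceptance draws in documented order, so identical
#' configurations reproduce trajectories bit-for-bit.
#'
#' @param config a `SynthConfig`.
#' @return a `Trajectory` (frame 0 is the initial pose; one frame every
#'   `save_stride` sweeps; times are sweep indices, nominal ns). The
#'   attribute `manifest` records the seed, per-move acceptance rates and
#'   the saved-frame energy trace; `system` holds the `SynthSystem`.
#' @export
simulate_tether <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  if (config$n_sweeps <= 0) stop("n_sweeps must be positive")
  sys <- build_system(config)
  cfg <- config
  xyz <- coords(sys$structure)
  dom <- sys$groups$domain
  tail_i <- sys$groups$tail
  anchor <- sys$groups$anchor
  attach <- sys$groups$attach

  with_seed(cfg$seed + 1L, function() {
    E <- mobile_energy(xyz, sys)
    n_try <- c(trans = 0, rot = 0, crank = 0, disp = 0)
    n_acc <- c(trans = 0, rot = 0, crank = 0, disp = 0)
    frames <- list(xyz)
    times <- 0
    etrace <- E
    max_rot <- cfg$max_rotation_deg * pi / 180
    max_crank <- cfg$max_crank_deg * pi / 180
    chain <- c(anchor, tail_i, attach)

    for (sweep in seq_len(cfg$n_sweeps)) {
      # rigid translation of the domain
      prop <- xyz
      prop[dom, ] <- sweep(prop[dom, , drop = FALSE], 2,
                           random_unit_vector() *
                             stats::runif(1, 0, cfg$max_translation), "+")
      Ep <- mobile_energy(prop, sys)
      n_try["trans"] <- n_try["trans"] + 1
      if (metropolis_accept(Ep - E, cfg$temperature_kT)) {
        xyz <- prop; E <- Ep; n_acc["trans"] <- n_acc["trans"] + 1
      }

      # rigid rotation about the domain center
      prop <- xyz
      ctr <- colMeans(prop[dom, , drop = FALSE])
      R <- rotation_matrix(random_unit_vector(),
                           stats::runif(1, -max_rot, max_rot))
      prop[dom, ] <- sweep(sweep(prop[dom, , drop = FALSE], 2, ctr) %*% t(R),
                           2, ctr, "+")
      Ep <- mobile_energy(prop, sys)
      n_try["rot"] <- n_try["rot"] + 1
      if (metropolis_accept(Ep - E, cfg$temperature_kT)) {
        xyz <- prop; E <- Ep; n_acc["rot"] <- n_acc["rot"] + 1
      }

      # crankshaft moves: rotate each tail bead about its neighbour axis
      for (t in seq_along(tail_i)) {
        bead <- chain[t + 1L]
        a <- xyz[chain[t], ]
        b <- xyz[chain[t + 2L], ]
        axis <- b - a
        if (sum(axis^2) < 1e-12) next
        prop <- xyz
        R <- rotation_matrix(axis, stats::runif(1, -max_crank, max_crank))
        prop[bead, ] <- a + as.numeric(R %*% (xyz[bead, ] - a))
        Ep <- mobile_energy(prop, sys)
        n_try["crank"] <- n_try["crank"] + 1
        if (metropolis_accept(Ep - E, cfg$temperature_kT)) {
          xyz <- prop; E <- Ep; n_acc["crank"] <- n_acc["crank"] + 1
        }

        # single-bead displacement: samples the bond lengths
        prop <- xyz
        prop[bead, ] <- prop[bead, ] + random_unit_vector() *
          stats::runif(1, 0, cfg$max_displacement)
        Ep <- mobile_energy(prop, sys)
        n_try["disp"] <- n_try["disp"] + 1
        if (metropolis_accept(Ep - E, cfg$temperature_kT)) {
          xyz <- prop; E <- Ep; n_acc["disp"] <- n_acc["disp"] + 1
        }
      }

      if (sweep %% cfg$save_stride == 0L) {
        frames[[length(frames) + 1L]] <- xyz
        times <- c(times, sweep)
        etrace <- c(etrace, E)
      }
    }

    traj <- new_trajectory(sys$structure, times, frames)
    attr(traj, "manifest") <- list(
      seed = cfg$seed,
      acceptance = ifelse(n_try > 0, n_acc / n_try, NA_real_),
      energy_trace = etrace,
      n_sweeps = cfg$n_sweeps)
    attr(traj, "system") <- sys
    traj
  })
}
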