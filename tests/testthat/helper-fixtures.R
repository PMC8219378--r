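# Fixture builders: every fixture is constructed in code at test time.

# data.frame of atoms from a coordinate matrix plus metadata vectors
# (recycled to the atom count)
make_atoms <- function(xyz, name = "BD", element = "X", resname = "BEA",
                       resid = seq_len(nrow(xyz)), chain = "A") {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = rep_len(name, n), element = rep_len(element, n),
             resname = rep_len(resname, n),
             resid = rep_len(resid, n), chain = rep_len(chain, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

toy_structure <- function(xyz, ..., box = NULL) {
  new_structure(make_atoms(xyz, ...), box = box)
}

# trajectory over a topology from a list of coordinate matrices
toy_trajectory <- function(s, frames, times = seq_along(frames) - 1) {
  new_trajectory(s, times, frames)
}

# a protein residue (n_atoms beads around `center`) above a row of lipids;
# used by membrane-metric unit tests
membrane_fixture <- function(lipid_z = 0,
                             lipid_x = c(0, 6, 12, 18),
                             lipid_types = c("POPS", "POPC", "POPC", "PIP2"),
                             protein_z = 4) {
  nl <- length(lipid_x)
  lip <- cbind(lipid_x, 0, lipid_z)
  prot <- matrix(c(0, 0, protein_z), 1, 3)
  xyz <- rbind(lip, prot)
  atoms <- rbind(
    make_atoms(lip, resname = lipid_types, resid = seq_len(nl), chain = "M"),
    make_atoms(prot, resname = "GLY", resid = 1L, chain = "A"))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

random_rigid_motion <- function() {
  R <- random_rotation_matrix()
  t <- stats::runif(3, -10, 10)
  function(xyz) sweep(xyz %*% t(R), 2, t, "+")
}

# small hand-checkable MSA (ids A/B/C), used by several seqcharge tests
toy_msa <- function() {
  new_msa(c("A", "B", "C"),
          c("MK-RHDEG",
            "MKAR--EG",
            "M--RHD-G"))
}

# one-atom lipids (chain M) plus an n_res one-atom-residue protein (chain A)
lipid_protein_structure <- function(lipid_types, n_res = 1) {
  nl <- length(lipid_types)
  xyz <- matrix(0, nl + n_res, 3)
  atoms <- rbind(
    make_atoms(xyz[seq_len(nl), , drop = FALSE], resname = lipid_types,
               resid = seq_len(nl), chain = "M"),
    make_atoms(xyz[nl + seq_len(n_res), , drop = FALSE], resname = "GLY",
               resid = seq_len(n_res), chain = "A"))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

# 10-frame fixture: the single lipid touches the residue in frames 4-10 only
ten_frame_fixture <- function() {
  s <- lipid_protein_structure("POPS")
  frames <- lapply(1:10, function(f) {
    z <- if (f >= 4) 3 else 30
    rbind(c(0, 0, z), c(0, 0, 0))
  })
  toy_trajectory(s, frames)
}

random_membrane_traj <- function(n_frames = 8, nl = 12, seed = 31) {
  set.seed(seed)
  types <- sample(c("POPC", "POPS", "PIP2"), nl, replace = TRUE)
  s <- lipid_protein_structure(types, n_res = 3)
  frames <- lapply(seq_len(n_frames), function(f) {
    lip <- cbind(stats::runif(nl, 0, 20), stats::runif(nl, 0, 20), 0)
    prot <- cbind(stats::runif(3, 0, 20), stats::runif(3, 0, 20),
                  stats::runif(3, 0, 6))
    rbind(lip, prot)
  })
  toy_trajectory(s, frames)
}

# two 10-bead "domains" (chains G and Q) for alignment-frame RMSD tests
two_domain_structure <- function(n_each = 10, seed = 3) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(6 * n_each, sd = 6), 2 * n_each, 3)
  toy_structure(xyz, name = "CA", resname = "GLY",
                resid = seq_len(2 * n_each),
                chain = rep(c("G", "Q"), each = n_each))
}
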