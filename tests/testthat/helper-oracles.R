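# Independent oracle implementations used to cross-check the package's
# kernels. Each deliberately uses a different algorithm (or a brute-force
# formulation) than the code under test.

# --- Horn quaternion-eigenvalue superposition: minimal RMSD of A onto B ---
quaternion_min_rmsd <- function(A, B) {
  n <- nrow(A)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  S <- crossprod(A, B) # S[i,j] = sum_k A[k,i] * B[k,j]
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# --- brute-force O(N^2) minimum-image pair search ---
brute_pairs <- function(A, B, cutoff, box = NULL) {
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(A))) {
    d <- sweep(B, 2, A[i, ])
    if (!is.null(box)) {
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    j <- which(sqrt(rowSums(d^2)) <= cutoff)
    if (length(j) > 0L) out <- rbind(out, cbind(i, j))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# --- dense random-sampling SASA oracle (independent quadrature) ---
# per-atom accessible area from n seeded uniform random sphere points
random_sphere_points <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

oracle_sasa <- function(xyz, radii, probe, n = 1e5, seed = 42) {
  set.seed(seed)
  na <- nrow(xyz)
  R <- radii + probe
  out <- numeric(na)
  for (i in seq_len(na)) {
    pts <- sweep(random_sphere_points(n) * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(na)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  out
}

# --- explicit pair-loop energy oracle for the synthetic system ---
oracle_energy <- function(sys, xyz = NULL) {
  cfg <- sys$config
  if (is.null(xyz)) xyz <- memtether::coords(sys$structure)
  q <- sys$charges
  n <- nrow(xyz)
  elec <- 0
  for (i in seq_len(n - 1)) {
    if (q[i] == 0) next
    for (j in (i + 1):n) {
      if (q[j] == 0) next
      # contact-clamped screened Coulomb, as defined by the model
      r <- max(sqrt(sum((xyz[i, ] - xyz[j, ])^2)), 2 * cfg$bead_radius)
      elec <- elec + 560.47 * q[i] * q[j] * exp(-r / cfg$debye_length) /
        (cfg$dielectric * r)
    }
  }
  prot <- c(sys$groups$domain, sys$groups$tail)
  lip <- sys$groups$lipid
  sigma <- 2 * cfg$bead_radius
  ev <- 0
  for (i in prot) {
    for (j in lip) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r < sigma) ev <- ev + cfg$k_ev * (1 - r / sigma)^2
    }
    if (xyz[i, 3] < 0) ev <- ev + cfg$k_ev * xyz[i, 3]^2
  }
  bonds <- 0
  for (k in seq_len(nrow(sys$bonds))) {
    d <- sqrt(sum((xyz[sys$bonds[k, 1], ] - xyz[sys$bonds[k, 2], ])^2))
    bonds <- bonds + cfg$k_bond * (d - cfg$bond_length)^2
  }
  list(electrostatic = elec, excluded_volume = ev, bonds = bonds,
       total = elec + ev + bonds)
}

# --- direct (chain-growth + rejection) sampler for the tether model ------
# Valid when the protein carries no charge: bond Boltzmann factors are
# sampled exactly by construction (uniform direction, length ~ r^2-weighted
# Gaussian), and the residual excluded-volume/wall energy is handled by
# rejection. Returns domain-center heights.
random_rotation_matrix <- function() {
  qv <- stats::rnorm(4)
  qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

sample_bond_length <- function(b, kT, k_bond) {
  s <- sqrt(kT / (2 * k_bond))
  rmax <- b + 6 * s
  repeat {
    r <- stats::rnorm(1, b, s)
    if (r <= 0 || r > rmax) next
    if (stats::runif(1) < (r / rmax)^2) return(r)
  }
}

oracle_tether_heights <- function(sys, n_samples, seed = 99) {
  cfg <- sys$config
  stopifnot(all(sys$charges[c(sys$groups$domain, sys$groups$tail)] == 0))
  set.seed(seed)
  xyz0 <- memtether::coords(sys$structure)
  anchor <- xyz0[sys$groups$anchor, ]
  dom_rel <- sweep(xyz0[sys$groups$domain, , drop = FALSE], 2,
                   xyz0[sys$groups$attach, ])
  lip <- xyz0[sys$groups$lipid, , drop = FALSE]
  sigma <- 2 * cfg$bead_radius
  kT <- cfg$temperature_kT
  nb <- cfg$tail_beads + 1L # bonds anchor -> ... -> attach
  heights <- numeric(0)
  while (length(heights) < n_samples) {
    pos <- anchor
    tail_pos <- matrix(0, 0, 3)
    for (k in seq_len(nb)) {
      dirv <- stats::rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      pos <- pos + dirv * sample_bond_length(cfg$bond_length, kT, cfg$k_bond)
      if (k < nb) tail_pos <- rbind(tail_pos, pos)
    }
    R <- random_rotation_matrix()
    dom <- sweep(dom_rel %*% t(R), 2, pos, "+")
    prot <- rbind(tail_pos, dom)
    e <- 0
    for (i in seq_len(nrow(prot))) {
      d <- sqrt(rowSums(sweep(lip, 2, prot[i, ])^2))
      near <- d < sigma
      if (any(near)) e <- e + sum(cfg$k_ev * (1 - d[near] / sigma)^2)
      if (prot[i, 3] < 0) e <- e + cfg$k_ev * prot[i, 3]^2
    }
    if (stats::runif(1) < exp(-e / kT)) {
      ctr <- colMeans(dom)
      heights <- c(heights, ctr[3])
    }
  }
  heights
}
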