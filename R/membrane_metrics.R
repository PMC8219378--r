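# Protein-membrane observables: per-residue lipid-contact profiles, contact
# maps, membrane contact-area series, contact-residue counts and lipid-type
# enrichment. A lipid "molecule" is identified by (chain, resid, resname),
# the PDB convention of one residue per lipid; a molecule counts once for a
# residue when ANY of its atoms lies within the cutoff of ANY atom of that
# residue. Distances honour the minimum-image convention when the
# trajectory carries a box.

burn_in_start <- function(n_frames_total, burn_in_fraction) {
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must lie in [0, 1)")
  }
  drop <- as.integer(ceiling(burn_in_fraction * n_frames_total))
  if (drop >= n_frames_total) {
    stop("burn-in leaves zero frames")
  }
  drop + 1L
}

# Shared per-frame machinery: residue ids for protein atoms, molecule ids
# for lipid atoms, and a per-frame (residue x molecule) contact pair lister.
contact_context <- function(traj, protein_sel, lipid_sel, cutoff) {
  s <- traj$topology
  ps <- resolve_selection(protein_sel, s)
  ls <- resolve_selection(lipid_sel, s)
  if (length(ps$indices) == 0L) stop("protein selection is empty")
  if (length(ls$indices) == 0L) stop("lipid selection is empty")
  if (length(intersect(ps$indices, ls$indices)) > 0L) {
    stop("protein and lipid selections overlap")
  }
  at <- s$atoms
  pkey <- paste(at$chain[ps$indices], at$resid[ps$indices], sep = ":")
  pres <- unique(pkey)
  pres_of_atom <- match(pkey, pres)
  lkey <- paste(at$chain[ls$indices], at$resid[ls$indices],
                at$resname[ls$indices], sep = ":")
  lmol <- unique(lkey)
  lmol_of_atom <- match(lkey, lmol)
  mol_resname <- at$resname[ls$indices][match(lmol, lkey)]
  res_table <- unique(data.frame(chain = at$chain[ps$indices],
                                 resid = at$resid[ps$indices],
                                 stringsAsFactors = FALSE))
  list(
    prot_idx = ps$indices, lip_idx = ls$indices,
    pres = pres, pres_of_atom = pres_of_atom, res_table = res_table,
    lmol = lmol, lmol_of_atom = lmol_of_atom, mol_resname = mol_resname,
    box = traj$box, cutoff = cutoff,
    # unique (residue, molecule) contact pairs in one frame
    frame_pairs = function(xyz) {
      pl <- neighbor_pairs(xyz[ps$indices, , drop = FALSE],
                           xyz[ls$indices, , drop = FALSE],
                           cutoff, box = traj$box)
      if (nrow(pl$pairs) == 0L) {
        return(matrix(integer(0), 0, 2))
      }
      rp <- cbind(pres_of_atom[pl$pairs[, 1]], lmol_of_atom[pl$pairs[, 2]])
      unique(rp)
    })
}

#' Per-residue, per-frame lipid-molecule contact map
#'
#' The full residue x time table of lipid-molecule contact counts before any
#' time averaging: entry `(r, f)` is the number of distinct lipid molecules
#' with at least one atom within `cutoff` of any atom of residue `r` in
#' frame `f`.
#'
#' @param traj a `Trajectory`.
#' @param protein_sel,lipid_sel selections over the topology (disjoint).
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return object of class `ContactMap`: an integer matrix (residues x
#'   frames, rownames `chain:resid`) with attributes `times` and
#'   `residues` (data.frame chain/resid).
#' @export
contact_map <- function(traj, protein_sel, lipid_sel, cutoff = 5) {
  ctx <- contact_context(traj, protein_sel, lipid_sel, cutoff)
  nf <- n_frames(traj)
  m <- matrix(0L, nrow = length(ctx$pres), ncol = nf,
              dimnames = list(ctx$pres, NULL))
  for (f in seq_len(nf)) {
    rp <- ctx$frame_pairs(traj$frames[[f]])
    if (nrow(rp) > 0L) {
      cnt <- tabulate(rp[, 1], nbins = length(ctx$pres))
      m[, f] <- cnt
    }
  }
  structure(m, times = traj$times, residues = ctx$res_table,
            cutoff = cutoff, class = c("ContactMap", "matrix", "array"))
}

#' Per-residue mean lipid-contact profile
#'
#' For every protein residue, the number of distinct lipid molecules within
#' `cutoff` of any atom of the residue, averaged over the frames retained
#' after burn-in. The first `ceiling(burn_in_fraction * n_frames)` frames
#' are discarded (the convention of discarding the initial 30% of a run).
#'
#' @inheritParams contact_map
#' @param burn_in_fraction fraction of initial frames discarded, in `[0, 1)`.
#' @return object of class `ResidueContactProfile`: data.frame with columns
#'   `chain`, `resid`, `mean_count`, plus attributes `cutoff`,
#'   `burn_in_fraction`, `n_frames_used`.
#' @export
residue_lipid_contacts <- function(traj, protein_sel, lipid_sel, cutoff = 5,
                                   burn_in_fraction = 0.3) {
  cm <- contact_map(traj, protein_sel, lipid_sel, cutoff = cutoff)
  from <- burn_in_start(ncol(cm), burn_in_fraction)
  kept <- cm[, from:ncol(cm), drop = FALSE]
  res <- attr(cm, "residues")
  out <- data.frame(chain = res$chain, resid = res$resid,
                    mean_count = rowMeans(kept),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, burn_in_fraction = burn_in_fraction,
            n_frames_used = ncol(kept),
            class = c("ResidueContactProfile", "data.frame"))
}

#' Membrane contact-area time series
#'
#' Per-frame SASA-difference contact area ([contact_area()]) between the
#' protein and lipid selections. Negative values (adjacent but non-touching
#' groups) are retained, not clipped.
#'
#' @inheritParams contact_map
#' @param probe probe radius in Angstrom.
#' @param n_points SASA quadrature points per atom.
#' @param radius_table,radii radius lookup, see [sasa()].
#' @return a [metric_series()] (`MetricSeries`) in A^2.
#' @export
membrane_contact_area_series <- function(traj, protein_sel, lipid_sel,
                                         probe = 1.4, n_points = 960,
                                         radius_table = bondi_radii(),
                                         radii = NULL) {
  s <- traj$topology
  ps <- resolve_selection(protein_sel, s)
  ls <- resolve_selection(lipid_sel, s)
  vals <- vapply(traj$frames, function(fr) {
    contact_area(s, ps, ls, probe = probe, n_points = n_points, xyz = fr,
                 radius_table = radius_table, radii = radii)
  }, numeric(1))
  metric_series(traj$times, vals, label = "membrane_contact_area",
                units = "A^2")
}

#' Count of protein residues in membrane contact, per frame
#'
#' A residue is "in contact" in a frame when at least one lipid molecule has
#' an atom within `cutoff` of any of the residue's atoms.
#'
#' @inheritParams contact_map
#' @return a `MetricSeries` of residue counts (dimensionless).
#' @export
contact_residue_count_series <- function(traj, protein_sel, lipid_sel,
                                         cutoff = 5) {
  ctx <- contact_context(traj, protein_sel, lipid_sel, cutoff)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    rp <- ctx$frame_pairs(traj$frames[[f]])
    length(unique(rp[, 1]))
  }, numeric(1))
  metric_series(traj$times, vals, label = "contact_residue_count",
                units = "residues")
}

#' Lipid-type enrichment at the protein-membrane interface
#'
#' Per frame, the fraction of protein-contacting lipid molecules belonging
#' to `lipid_type`, against the baseline fraction of that type among all
#' molecules of the lipid selection; the enrichment ratio is
#' `fraction / baseline`. Frames with zero contacting lipids are recorded
#' as missing (`NA`), not zero: the composition of an empty contacting set
#' is undefined and treating it as zero would bias the baseline comparison.
#'
#' @inheritParams contact_map
#' @param lipid_type residue name(s) of the lipid class of interest (e.g.
#'   `"POPS"` or `c("POPS", "PIP2")` for all anionic lipids).
#' @return object of class `EnrichmentSeries`: data.frame with columns
#'   `time`, `fraction`, `baseline`, `enrichment`.
#' @export
lipid_enrichment <- function(traj, protein_sel, lipid_sel, lipid_type,
                             cutoff = 5) {
  ctx <- contact_context(traj, protein_sel, lipid_sel, cutoff)
  is_type <- ctx$mol_resname %in% lipid_type
  if (!any(is_type)) {
    stop("lipid_type not present in the lipid selection: ",
         paste(lipid_type, collapse = ", "))
  }
  baseline <- mean(is_type)
  nf <- n_frames(traj)
  fraction <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    rp <- ctx$frame_pairs(traj$frames[[f]])
    mols <- unique(rp[, 2])
    if (length(mols) > 0L) fraction[f] <- mean(is_type[mols])
  }
  out <- data.frame(time = traj$times, fraction = fraction,
                    baseline = baseline,
                    enrichment = fraction / baseline)
  structure(out, lipid_type = lipid_type, cutoff = cutoff,
            class = c("EnrichmentSeries", "data.frame"))
}

#' Export a contact map as TSV
#' @param cm a `ContactMap`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_contact_map <- function(cm, path) {
  res <- attr(cm, "residues")
  df <- data.frame(chain = res$chain, resid = res$resid,
                   as.data.frame(unclass(cm)[, , drop = FALSE]))
  names(df)[-(1:2)] <- sprintf("t_%g", attr(cm, "times"))
  write_table(df, path)
}
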