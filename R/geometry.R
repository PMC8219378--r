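# Rigid-body superposition, RMSD and cutoff neighbour search: the kernels
# behind every trajectory observable in the package.

check_coord_matrix <- function(m, what) {
  if (!is.matrix(m) || ncol(m) != 3L || !is.numeric(m)) {
    stop(what, " must be a numeric N x 3 matrix")
  }
  if (!all(is.finite(m))) stop(what, " contains non-finite coordinates")
  m
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference`. The reflection branch of the SVD solution is
#' corrected by sign-flipping the smallest singular vector, so chirality is
#' always preserved (`det(rotation) = +1`).
#'
#' @param mobile M x 3 coordinates (Angstrom), M >= 3 and non-collinear.
#' @param reference M x 3 coordinates.
#' @return list of class `RigidTransform` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd`, the minimized RMSD in Angstrom.
#'   The fit maps a point `x` to `rotation %*% x + translation`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- check_coord_matrix(mobile, "mobile")
  reference <- check_coord_matrix(reference, "reference")
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("degenerate input: need at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  for (nm in c("mobile", "reference")) {
    sv <- svd(if (nm == "mobile") P else Q, nu = 0, nv = 0)$d
    if (sv[2] <= 1e-8 * max(sv[1], 1)) {
      stop("degenerate input: ", nm, " points are collinear")
    }
  }
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  msd <- mean(rowSums((fitted - Q)^2))
  tr <- as.numeric(cr - R %*% cm)
  structure(list(rotation = R, translation = tr, rmsd = sqrt(max(msd, 0))),
            class = "RigidTransform")
}

#' Apply a RigidTransform to coordinates
#' @param tf a `RigidTransform` from [kabsch()].
#' @param xyz N x 3 coordinates.
#' @return transformed N x 3 coordinates.
#' @export
apply_transform <- function(tf, xyz) {
  xyz <- check_coord_matrix(xyz, "xyz")
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Root-mean-square deviation without fitting
#' @param a,b N x 3 coordinate matrices (Angstrom).
#' @return RMSD in Angstrom; no superposition is performed.
#' @export
rmsd <- function(a, b) {
  a <- check_coord_matrix(a, "a")
  b <- check_coord_matrix(b, "b")
  if (!all(dim(a) == dim(b))) stop("shape mismatch between coordinate sets")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose a frame on a reference using an alignment subset
#'
#' Fits the Kabsch transform on the `align` subset only and applies it to
#' all N atoms, reproducing the "align on one domain, measure another"
#' protocol of trajectory RMSD observables.
#'
#' @param frame N x 3 frame coordinates.
#' @param align `AtomIndexSet` (or indices) of alignment atoms.
#' @param reference N x 3 reference coordinates.
#' @return N x 3 superposed coordinates.
#' @export
superpose_frame <- function(frame, align, reference) {
  frame <- check_coord_matrix(frame, "frame")
  reference <- check_coord_matrix(reference, "reference")
  idx <- if (inherits(align, "AtomIndexSet")) align$indices else as.integer(align)
  if (length(idx) == 0L) stop("alignment selection is empty")
  tf <- kabsch(frame[idx, , drop = FALSE], reference[idx, , drop = FALSE])
  apply_transform(tf, frame)
}

#' Cutoff neighbour pairs between two point sets
#'
#' Exact pair list at `distance <= cutoff` (closed boundary: a pair at
#' exactly the cutoff is included) using a cell list, with the minimum-image
#' convention for orthorhombic periodic boxes.
#'
#' @param coords_a,coords_b numeric N x 3 point sets (Angstrom).
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param box optional length-3 orthorhombic box; when given, `cutoff` must
#'   not exceed half the shortest box length (minimum image validity).
#' @return object of class `PairList`: list with `pairs` (two-column integer
#'   matrix of 1-based indices into A and B, ordered by A then B) and
#'   `cutoff`.
#' @export
neighbor_pairs <- function(coords_a, coords_b, cutoff, box = NULL) {
  coords_a <- check_coord_matrix(coords_a, "coords_a")
  coords_b <- check_coord_matrix(coords_b, "coords_b")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive scalar")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths")
    }
    if (cutoff > min(box) / 2) {
      stop(sprintf("cutoff %.3f exceeds half the shortest box length %.3f: minimum image invalid",
                   cutoff, min(box) / 2))
    }
  }
  p <- cpp_neighbor_pairs(coords_a, coords_b, cutoff,
                          if (is.null(box)) numeric(0) else box)
  if (nrow(p) > 1L) p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  structure(list(pairs = p, cutoff = cutoff), class = "PairList")
}
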