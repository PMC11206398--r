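## Rigid superposition and RMSD.
##
## Two protocols are exposed: full Kabsch least-squares superposition, and
## plane-anchored alignment on three quinazoline-core atoms (the frame used
## when comparing crystal poses with the calculated global minimum, so that
## deviations read out in the side-chain torsions rather than being
## absorbed by the fit).

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    coords <- validate_coordinates(coords)
    m <- as.matrix(coords[, c("x", "y", "z")])
    rownames(m) <- NULL
    attr(m, "element") <- coords$element
    return(m)
  }
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  coords
}

#' Atom mapping between two structures
#'
#' @param a_idx,b_idx equal-length 1-based atom indices into structures A
#'   and B; at least 3 pairs, no duplicated pairs.
#' @param subset_policy one of `"all_atoms"`, `"heavy_atoms"`,
#'   `"explicit_list"`; bookkeeping carried into results.
#' @return an `atom_mapping` object.
#' @export
atom_mapping <- function(a_idx, b_idx,
                         subset_policy = c("explicit_list", "all_atoms",
                                           "heavy_atoms")) {
  subset_policy <- match.arg(subset_policy)
  a_idx <- as.integer(a_idx); b_idx <- as.integer(b_idx)
  if (length(a_idx) != length(b_idx))
    stop("a_idx and b_idx must have equal length")
  if (length(a_idx) < 3L) stop("superposition needs >= 3 mapped atom pairs")
  if (anyDuplicated(cbind(a_idx, b_idx)))
    stop("duplicated atom pairs in mapping")
  structure(list(a_idx = a_idx, b_idx = b_idx,
                 subset_policy = subset_policy), class = "atom_mapping")
}

collinear3 <- function(p) {
  ## TRUE if the centered point set has rank <= 1 (all points on a line)
  centered <- sweep(p, 2, colMeans(p))
  s <- svd(centered, nu = 0, nv = 0)$d
  s[2] < 1e-8 * max(s[1], 1e-12)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mapped atoms of `b` onto `a`, via SVD of the cross-covariance matrix.
#' If the unconstrained optimum is a reflection, the proper-rotation branch
#' is taken and flagged in the result.
#'
#' @param a,b coordinate data.frames (`element`, `x`, `y`, `z`) or plain
#'   n x 3 matrices, in angstrom.
#' @param mapping an [atom_mapping()]; default maps atom i to atom i over
#'   all atoms (requires equal atom counts).
#' @return an `alignment_result`: list with `rmsd` (angstrom), `rotation`
#'   (3 x 3, det +1), `translation` (length-3), `mapping`,
#'   `reflection_avoided` (logical), and `b_transformed` (all atoms of `b`
#'   moved by the fitted rigid motion).
#' @export
kabsch_superpose <- function(a, b, mapping = NULL) {
  pa <- as_coord_matrix(a)
  pb <- as_coord_matrix(b)
  if (is.null(mapping)) {
    if (nrow(pa) != nrow(pb))
      stop("atom-count mismatch (", nrow(pa), " vs ", nrow(pb),
           ") without an explicit mapping")
    mapping <- atom_mapping(seq_len(nrow(pa)), seq_len(nrow(pb)),
                            "all_atoms")
  }
  stopifnot(inherits(mapping, "atom_mapping"))
  if (max(mapping$a_idx) > nrow(pa) || max(mapping$b_idx) > nrow(pb) ||
      min(mapping$a_idx) < 1L || min(mapping$b_idx) < 1L)
    stop("mapping index out of range")
  qa <- pa[mapping$a_idx, , drop = FALSE]
  qb <- pb[mapping$b_idx, , drop = FALSE]
  if (collinear3(qa) || collinear3(qb))
    stop("degenerate (collinear) point set: superposition is ill-defined")
  ca <- colMeans(qa); cb <- colMeans(qb)
  h <- crossprod(sweep(qb, 2, cb), sweep(qa, 2, ca))
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  reflection_avoided <- d < 0
  s <- diag(c(1, 1, d))
  rot <- sv$u %*% s %*% t(sv$v)
  trans <- ca - as.vector(cb %*% rot)
  qb_fit <- qb %*% rot
  qb_fit <- sweep(qb_fit, 2, trans, `+`)
  rmsd <- sqrt(mean(rowSums((qb_fit - qa)^2)))
  b_tr <- sweep(pb %*% rot, 2, trans, `+`)
  structure(
    list(rmsd = rmsd, rotation = rot, translation = trans,
         mapping = mapping, reflection_avoided = reflection_avoided,
         b_transformed = b_tr),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> rmsd = %.4f A over %d atoms%s\n",
              x$rmsd, length(x$mapping$a_idx),
              if (x$reflection_avoided) " (reflection branch avoided)" else ""))
  invisible(x)
}

#' Plane-anchored alignment on three atoms
#'
#' Rigidly transforms a structure so that the plane through the three
#' anchor atoms coincides with z = 0, the first anchor sits at the origin,
#' and the second lies on the +x axis. Structures anchored on homologous
#' atoms (here the quinazoline-core carbons) become directly comparable
#' without any least-squares fit.
#'
#' @param coords coordinate data.frame or n x 3 matrix.
#' @param anchor_indices three distinct, non-collinear 1-based atom indices.
#' @return coordinates of the same type as the input, transformed.
#' @export
plane_anchor_align <- function(coords, anchor_indices) {
  p <- as_coord_matrix(coords)
  anchor_indices <- as.integer(anchor_indices)
  if (length(anchor_indices) != 3L || anyDuplicated(anchor_indices))
    stop("anchor_indices must be three distinct indices")
  if (min(anchor_indices) < 1L || max(anchor_indices) > nrow(p))
    stop("anchor index out of range")
  p1 <- p[anchor_indices[1], ]
  p2 <- p[anchor_indices[2], ]
  p3 <- p[anchor_indices[3], ]
  e1 <- p2 - p1
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-10) stop("coincident anchor atoms")
  e1 <- e1 / n1
  v <- p3 - p1
  e3 <- c(e1[2] * v[3] - e1[3] * v[2],
          e1[3] * v[1] - e1[1] * v[3],
          e1[1] * v[2] - e1[2] * v[1])
  n3 <- sqrt(sum(e3^2))
  if (n3 < 1e-10) stop("collinear anchor atoms: plane is undefined")
  e3 <- e3 / n3
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  rot <- cbind(e1, e2, e3)  # columns form the new frame
  dimnames(rot) <- NULL
  out <- sweep(p, 2, p1) %*% rot
  if (is.data.frame(coords)) {
    coords$x <- out[, 1]; coords$y <- out[, 2]; coords$z <- out[, 3]
    coords
  } else out
}

subset_indices <- function(elements, subset_policy) {
  switch(subset_policy,
         all_atoms = seq_along(elements),
         heavy_atoms = which(elements != "H"),
         stop("subset_policy must be 'all_atoms' or 'heavy_atoms' here"))
}

#' RMSD between the crystal pose and the global minimum
#'
#' Aligns the crystal-reference structure with the global-minimum conformer
#' and reports the RMSD over the chosen atom subset. Two protocols:
#'
#' * `"anchor"` (default): both structures are plane-anchored on the
#'   ensemble's three anchor atoms and compared with no further fitting, so
#'   the residual measures side-chain/torsional deviation in a common
#'   quinazoline frame.
#' * `"kabsch"`: full least-squares superposition over the subset.
#'
#' Both structures must have identical atom counts and element ordering
#' (the usual situation for one compound optimized from a common starting
#' geometry); otherwise supply an explicit [atom_mapping()].
#'
#' @param ensemble a [compound_ensemble()] holding both a
#'   `crystal_reference` and a `global_minimum`.
#' @param subset_policy `"heavy_atoms"` (default; hydrogen positions from
#'   QM optimizations are conformation-noisy) or `"all_atoms"`.
#' @param method `"anchor"` or `"kabsch"`.
#' @param anchors three 1-based atom indices; defaults to the ensemble's
#'   stored anchors. Required for `method = "anchor"`.
#' @param mapping optional explicit [atom_mapping()] (kabsch method only).
#' @return RMSD in angstrom (numeric scalar) with attribute `method`.
#' @export
crystal_vs_minimum_rmsd <- function(ensemble,
                                    subset_policy = c("heavy_atoms",
                                                      "all_atoms"),
                                    method = c("anchor", "kabsch"),
                                    anchors = NULL, mapping = NULL) {
  subset_policy <- match.arg(subset_policy)
  method <- match.arg(method)
  gm <- global_minimum(ensemble)
  cr <- crystal_reference(ensemble)
  ca <- gm$coordinates
  cb <- cr$coordinates
  if (is.null(mapping)) {
    if (nrow(ca) != nrow(cb) || any(ca$element != cb$element))
      stop("atom count/ordering mismatch between global minimum and ",
           "crystal reference; supply an explicit mapping")
  }
  idx <- subset_indices(ca$element, subset_policy)
  if (method == "anchor") {
    if (is.null(anchors)) anchors <- ensemble$anchors
    if (is.null(anchors))
      stop("method = 'anchor' needs anchor atom indices (none stored in ",
           "the ensemble)")
    pa <- plane_anchor_align(as_coord_matrix(ca), anchors)
    pb <- plane_anchor_align(as_coord_matrix(cb), anchors)
    d <- pa[idx, , drop = FALSE] - pb[idx, , drop = FALSE]
    rmsd <- sqrt(mean(rowSums(d^2)))
  } else {
    map <- mapping %||% atom_mapping(idx, idx, "explicit_list")
    rmsd <- kabsch_superpose(ca, cb, map)$rmsd
  }
  structure(rmsd, method = method)
}
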