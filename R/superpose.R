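#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) sum of squared deviations when `moving` is mapped onto
#' `reference`.  No scaling, no reflection: the rotation determinant is
#' forced to +1.
#'
#' @param reference,moving Numeric matrices of identical dimension (n x 3).
#' @param weights Optional nonnegative weights, one per point.
#' @return List with `rotation` (3x3), `translation` (length 3; the transform
#'   is `x %*% t(rotation) + translation`), and `rmsd`, the unweighted
#'   root-mean-square deviation after the transform.
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' superpose(pts, sweep(pts, 2, c(1, 2, 3), "+"))$rmsd  # ~0
#' @export
superpose <- function(reference, moving, weights = NULL) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (!all(dim(reference) == dim(moving))) {
    stop("reference and moving point sets must have identical dimensions")
  }
  n <- nrow(reference)
  if (n < 1) stop("need at least one point")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be nonnegative with positive sum")
  }
  w <- weights / sum(weights)
  cr <- colSums(reference * w)
  cm <- colSums(moving * w)
  R <- diag(3)
  if (n > 1) {
    A <- sweep(moving, 2, cm); B <- sweep(reference, 2, cr)
    H <- t(A * w) %*% B
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  translation <- as.numeric(cr - R %*% cm)
  fitted <- moving %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform returned by [superpose()]
#' @param xyz n x 3 coordinate matrix.
#' @param transform List with `rotation` and `translation`.
#' @return Transformed coordinate matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}
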