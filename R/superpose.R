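# Rigid-body superposition (Kabsch) and inter-domain rotation angle.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping the mobile point set
#' onto the reference in the least-squares sense, via SVD of the
#' cross-covariance with a determinant correction that forbids reflection.
#'
#' @param reference,mobile paired n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (applied after rotation), `rmsd` (angstrom). The fitted
#'   mobile coordinates are `mobile %*% t(rotation) + translation`.
#' @export
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superpose(a, a)$rmsd  # 0
superpose <- function(reference, mobile) {
  a <- as.matrix(reference); b <- as.matrix(mobile)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("point sets must be paired n x 3 matrices", call. = FALSE)
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 paired points", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  # collinearity check: rank of either centred set < 2
  if (svd(a0)$d[2L] < 1e-8 * max(1, svd(a0)$d[1L]) ||
      svd(b0)$d[2L] < 1e-8 * max(1, svd(b0)$d[1L]))
    stop("degenerate (collinear) point set", call. = FALSE)
  h <- t(b0) %*% a0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - a0)^2)))
  translation <- ca - as.numeric(rot %*% cb)
  structure(list(rotation = rot, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> RMSD ", format(x$rmsd, digits = 6), " A, rotation ",
      format(rotation_angle(x$rotation), digits = 4), " deg\n", sep = "")
  invisible(x)
}

#' Rotation angle of a rotation matrix
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return angle in degrees, from the matrix trace.
#' @export
rotation_angle <- function(rotation) {
  tr <- sum(diag(rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Inter-domain rotation angle between two models
#'
#' Superposes model B onto model A using the anchor selection (e.g. the
#' terminal fingers), then superposes the mobile selection (e.g. the middle
#' finger) of the anchored B onto that of A; the angle of the residual
#' rotation is the domain rotation. Invariant to any global rigid motion
#' applied to either model.
#'
#' @param anchor_a,anchor_b paired coordinates of the anchor region.
#' @param mobile_a,mobile_b paired coordinates of the mobile region.
#' @return rotation angle in degrees.
#' @export
domain_rotation_angle <- function(anchor_a, anchor_b,
                                  mobile_a, mobile_b) {
  if (nrow(as.matrix(anchor_a)) != nrow(as.matrix(anchor_b)) ||
      nrow(as.matrix(mobile_a)) != nrow(as.matrix(mobile_b)))
    stop("anchor/mobile selections must be paired across models",
         call. = FALSE)
  fit_anchor <- superpose(anchor_a, anchor_b)
  placed_mobile <- sweep(as.matrix(mobile_b) %*% t(fit_anchor$rotation),
                         2L, fit_anchor$translation, "+")
  fit_mobile <- superpose(mobile_a, placed_mobile)
  rotation_angle(fit_mobile$rotation)
}
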