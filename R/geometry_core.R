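# Rigid-body mathematics shared by every analysis: least-squares superposition,
# principal axes, and angle/torsion computation. Coordinates are n x 3 matrices
# of Angstrom values, points stored as rows. All angles are in degrees.

#' Rigid transform constructor
#'
#' A proper rigid transform (rotation with determinant +1 plus a translation)
#' acting on row-vector coordinates as `x %*% t(rotation) + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param x n x 3 coordinate matrix (or length-3 vector).
#' @param transform A [rigid_transform()].
#' @return Transformed coordinates with the same shape as `x`.
#' @export
apply_transform <- function(x, transform) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  out <- x %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3L, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Rotate a direction vector (no translation)
#' @param v length-3 vector.
#' @param transform A [rigid_transform()].
#' @return Rotated vector.
#' @export
rotate_vector <- function(v, transform) {
  as.numeric(transform$rotation %*% v)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `a` first and then `b`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the root-mean-square
#' deviation between `mobile` and `target`, with point correspondence given by
#' row order. Reflections are excluded by forcing the determinant of the
#' rotation to +1 via the sign of the smallest singular value.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @return A list with components `transform` (a [rigid_transform()] mapping
#'   `mobile` onto `target`) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target))) {
    stop("mobile and target must have identical dimensions")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points, got ", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  pm <- sweep(mobile, 2L, cm); pt <- sweep(target, 2L, ct)
  # a (near-)collinear target leaves rotation about the line undetermined
  sv_t <- svd(pt, nu = 0L, nv = 0L)$d
  if (sv_t[2L] < 1e-8 * max(sv_t[1L], 1e-12)) {
    stop("degenerate (collinear) target point set")
  }
  h <- crossprod(pm, pt)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ct - as.numeric(rot %*% cm)
  tr <- rigid_transform(rot, trans)
  dev <- apply_transform(mobile, tr) - target
  list(transform = tr, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Root-mean-square deviation between paired coordinates
#' @param a,b n x 3 coordinate matrices in correspondence.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Principal axes of a point cloud
#'
#' Eigenvectors of the coordinate covariance matrix, ordered by decreasing
#' variance. The first axis is oriented to have a positive projection onto the
#' vector from the first to the last input point (for a peptide given N to C,
#' this directs the major axis from the N to the C terminus).
#'
#' @param points n x 3 coordinate matrix, n >= 2.
#' @return List with `axes` (3x3 matrix, one unit axis per column), `values`
#'   (variances, decreasing) and `centroid`.
#' @export
principal_axes <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("principal axes need at least 2 points")
  centroid <- colMeans(points)
  centred <- sweep(points, 2L, centroid)
  if (max(abs(centred)) < 1e-9) stop("all points identical; axes undefined")
  ei <- eigen(crossprod(centred) / nrow(points), symmetric = TRUE)
  axes <- ei$vectors
  span <- points[nrow(points), ] - points[1L, ]
  if (sum(axes[, 1L] * span) < 0) axes[, 1L] <- -axes[, 1L]
  list(axes = axes, values = ei$values, centroid = centroid)
}

#' Angle between two vectors
#'
#' @param u,v length-3 vectors.
#' @return Angle in degrees in \[0, 180\].
#' @export
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length vector in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking along p2 -> p3, a clockwise rotation of the
#' far bond relative to the near bond is positive. Returned in degrees in
#' (-180, 180\]; the planar trans arrangement maps to +180.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return Torsion angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(sum(b1^2), sum(b2^2), sum(b3^2)) < 1e-20) {
    stop("coincident consecutive points; torsion undefined")
  }
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("collinear points; torsion undefined")
  }
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# wrap an angle difference into (-180, 180]
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180] <- x[x <= -180] + 360
  x
}
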