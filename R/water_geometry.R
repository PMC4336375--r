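# Rigid-body representation of water molecules and the configuration-space
# distance metrics. A pose is the oxygen position plus a unit quaternion for
# the rotation taking the laboratory frame to the molecular body frame.
#
# Body-frame convention: origin at the oxygen, z axis along the H-O-H
# bisector, molecule in the xz plane with hydrogen 1 on the +x side. Any
# fixed convention yields identical pose-pose distances; this one is chosen
# once and used everywhere.

.vnorm <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Raw atomic coordinates of a water molecule
#'
#' Light validation container for the three atom positions from which a
#' rigid-body pose is constructed. The O-H bond lengths must agree within
#' 20\% and the H-O-H angle must lie in (60, 180) degrees; this catches
#' mis-identified atoms without being strict about the exact model geometry.
#'
#' @param oxygen,hydrogen1,hydrogen2 numeric 3-vectors, Angstrom.
#' @return An object of class \code{water_atoms}.
#' @examples
#' water_atoms(c(0, 0, 0), c(0.76, 0, 0.59), c(-0.76, 0, 0.59))
#' @export
water_atoms <- function(oxygen, hydrogen1, hydrogen2) {
  oxygen <- as.numeric(oxygen); hydrogen1 <- as.numeric(hydrogen1)
  hydrogen2 <- as.numeric(hydrogen2)
  stopifnot(length(oxygen) == 3, length(hydrogen1) == 3, length(hydrogen2) == 3)
  b1 <- hydrogen1 - oxygen
  b2 <- hydrogen2 - oxygen
  r1 <- .vnorm(b1); r2 <- .vnorm(b2)
  if (r1 == 0 || r2 == 0)
    stop("degenerate water geometry: hydrogen coincides with oxygen")
  if (abs(r1 - r2) > 0.2 * min(r1, r2))
    stop("O-H bond lengths differ by more than 20%: not a rigid water")
  ang <- acos(max(-1, min(1, sum(b1 * b2) / (r1 * r2)))) * 180 / pi
  if (ang <= 60 || ang >= 180)
    stop(sprintf("H-O-H angle %.1f deg outside (60, 180): not a water geometry", ang))
  structure(list(oxygen = oxygen, hydrogen1 = hydrogen1, hydrogen2 = hydrogen2),
            class = "water_atoms")
}

#' Rigid-body pose of a water molecule
#'
#' @param position oxygen position, numeric 3-vector, Angstrom.
#' @param orientation unit quaternion (w, x, y, z); the norm must be 1 within
#'   1e-9.
#' @param frame_index non-negative integer frame label.
#' @return An object of class \code{water_pose}.
#' @seealso [body_frame_quaternion()] to construct the orientation from atoms.
#' @export
water_pose <- function(position, orientation, frame_index = 0L) {
  position <- as.numeric(position); orientation <- as.numeric(orientation)
  stopifnot(length(position) == 3, length(orientation) == 4)
  if (abs(.vnorm(orientation) - 1) > 1e-9)
    stop("orientation is not a unit quaternion (|norm - 1| > 1e-9)")
  frame_index <- as.integer(frame_index)
  if (frame_index < 0) stop("frame_index must be >= 0")
  structure(list(position = position, orientation = orientation,
                 frame_index = frame_index),
            class = "water_pose")
}

#' Series of water poses stored in matrix form
#'
#' The workhorse container: n poses as an n x 3 position matrix and an
#' n x 4 quaternion matrix, with a 0-based frame index per pose. All
#' estimators operate on this vectorized layout.
#'
#' @param position n x 3 numeric matrix, Angstrom.
#' @param quaternion n x 4 numeric matrix of unit quaternions (w, x, y, z).
#' @param frame integer vector of length n, non-negative frame indices.
#' @return An object of class \code{pose_series}.
#' @export
pose_series <- function(position, quaternion,
                        frame = seq_len(nrow(position)) - 1L) {
  position <- as.matrix(position); quaternion <- as.matrix(quaternion)
  stopifnot(ncol(position) == 3, ncol(quaternion) == 4,
            nrow(position) == nrow(quaternion),
            length(frame) == nrow(position))
  nrm <- sqrt(rowSums(quaternion^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("quaternion rows are not unit quaternions (|norm - 1| > 1e-9)")
  frame <- as.integer(frame)
  if (any(frame < 0)) stop("frame indices must be >= 0")
  structure(list(position = position, quaternion = quaternion, frame = frame),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("pose_series: %d poses, frames %d..%d\n",
              nrow(x$position),
              if (length(x$frame)) min(x$frame) else NA_integer_,
              if (length(x$frame)) max(x$frame) else NA_integer_))
  invisible(x)
}

#' Number of poses in a series
#' @param x a \code{pose_series}, \code{site_series} or \code{pair_series}.
#' @return integer count.
#' @export
n_poses <- function(x) {
  if (inherits(x, "pair_series")) return(nrow(x$a$position))
  nrow(x$position)
}

# convert rotation matrix (body -> lab, columns = body axes in lab coords)
# to a quaternion on the canonical hemisphere
.quat_from_matrix_one <- function(M) {
  tr <- M[1, 1] + M[2, 2] + M[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (M[3, 2] - M[2, 3]) / s,
           (M[1, 3] - M[3, 1]) / s,
           (M[2, 1] - M[1, 2]) / s)
  } else if (M[1, 1] >= M[2, 2] && M[1, 1] >= M[3, 3]) {
    s <- sqrt(1 + M[1, 1] - M[2, 2] - M[3, 3]) * 2
    q <- c((M[3, 2] - M[2, 3]) / s,
           0.25 * s,
           (M[1, 2] + M[2, 1]) / s,
           (M[1, 3] + M[3, 1]) / s)
  } else if (M[2, 2] >= M[3, 3]) {
    s <- sqrt(1 - M[1, 1] + M[2, 2] - M[3, 3]) * 2
    q <- c((M[1, 3] - M[3, 1]) / s,
           (M[1, 2] + M[2, 1]) / s,
           0.25 * s,
           (M[2, 3] + M[3, 2]) / s)
  } else {
    s <- sqrt(1 - M[1, 1] - M[2, 2] + M[3, 3]) * 2
    q <- c((M[2, 1] - M[1, 2]) / s,
           (M[1, 3] + M[3, 1]) / s,
           (M[2, 3] + M[3, 2]) / s,
           0.25 * s)
  }
  q <- q / .vnorm(q)
  canonical_quaternion(q)
}

#' Map a quaternion to the canonical hemisphere
#'
#' Quaternions q and -q represent the same rotation. The canonical
#' representative has a positive scalar part; when the scalar part is zero
#' the first nonzero component is made positive.
#'
#' @param q numeric 4-vector quaternion.
#' @return the canonical representative.
#' @export
canonical_quaternion <- function(q) {
  i <- which(abs(q) > 1e-12)[1]
  if (!is.na(i) && q[i] < 0) q <- -q
  q
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix R such that \code{R \%*\% v} rotates a
#'   body-frame vector into the laboratory frame.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quaternion of a rotation matrix
#'
#' Inverse of [quat_to_matrix()]; returns the canonical-hemisphere
#' representative.
#'
#' @param M 3 x 3 rotation matrix.
#' @return unit quaternion (w, x, y, z).
#' @export
quat_from_matrix <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  .quat_from_matrix_one(M)
}

#' Body-frame quaternion of a water molecule
#'
#' Returns the rotation taking the laboratory frame to the molecular body
#' frame (origin at oxygen, z along the H-O-H bisector, molecule in the xz
#' plane with hydrogen 1 at +x), as a canonical-hemisphere unit quaternion.
#' A water already in the body-frame orientation maps to the identity
#' quaternion (1, 0, 0, 0).
#'
#' @param atoms a \code{water_atoms} object.
#' @return unit quaternion (w, x, y, z).
#' @examples
#' ref <- water_atoms(c(0, 0, 0), c(0.757, 0, 0.586), c(-0.757, 0, 0.586))
#' body_frame_quaternion(ref)  # identity
#' @export
body_frame_quaternion <- function(atoms) {
  stopifnot(inherits(atoms, "water_atoms"))
  b1 <- atoms$hydrogen1 - atoms$oxygen
  b2 <- atoms$hydrogen2 - atoms$oxygen
  u1 <- b1 / .vnorm(b1); u2 <- b2 / .vnorm(b2)
  bis <- u1 + u2
  nb <- .vnorm(bis)
  if (nb < 1e-8)
    stop("degenerate water geometry: O, H1, H2 are collinear")
  ez <- bis / nb
  ex <- u1 - sum(u1 * ez) * ez
  nx <- .vnorm(ex)
  if (nx < 1e-8)
    stop("degenerate water geometry: O, H1, H2 are collinear")
  ex <- ex / nx
  ey <- .cross3(ez, ex)
  .quat_from_matrix_one(cbind(ex, ey, ez, deparse.level = 0))
}

# vectorized pose construction from coordinate matrices (one water per row)
.poses_from_atoms <- function(O, H1, H2, frame) {
  n <- nrow(O)
  quat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    quat[i, ] <- body_frame_quaternion(
      water_atoms(O[i, ], H1[i, ], H2[i, ]))
  }
  pose_series(O, quat, frame)
}

.pose_fields <- function(x) {
  if (inherits(x, "water_pose"))
    list(p = x$position, q = x$orientation)
  else if (is.list(x) && !is.null(x$position) && !is.null(x$orientation))
    list(p = x$position, q = x$orientation)
  else stop("expected a water_pose")
}

#' Translational distance between two poses
#'
#' Euclidean norm of the oxygen-position difference, in Angstrom.
#'
#' @param a,b \code{water_pose} objects.
#' @return distance in Angstrom.
#' @export
trans_distance <- function(a, b) {
  .vnorm(.pose_fields(a)$p - .pose_fields(b)$p)
}

#' Orientational distance between two rotations
#'
#' The geodesic rotation angle \eqn{2 \arccos |q_a \cdot q_b|} in radians,
#' in \[0, pi\]. The absolute value handles the quaternion double cover, so
#' the distance is invariant to negating either quaternion; the inner
#' product is clamped to \[0, 1\] to guard floating-point overshoot. The
#' twofold molecular symmetry of water is deliberately not folded in: the
#' symmetry number cancels between the absolute and uniform-reference
#' entropies.
#'
#' @param qa,qb unit quaternions (norm within 1e-6 of 1).
#' @return angle in radians.
#' @examples
#' orient_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))           # pi
#' orient_distance(c(1, 0, 0, 0), c(sqrt(2)/2, sqrt(2)/2, 0, 0))  # pi/2
#' @export
orient_distance <- function(qa, qb) {
  qa <- as.numeric(qa); qb <- as.numeric(qb)
  if (abs(.vnorm(qa) - 1) > 1e-6 || abs(.vnorm(qb) - 1) > 1e-6)
    stop("orient_distance requires unit quaternions")
  2 * acos(min(1, abs(sum(qa * qb))))
}

#' Total configuration-space distance between two poses
#'
#' \eqn{d_{total} = \sqrt{d_{trans}^2 + d_{orient}^2}}, with the
#' translational part in Angstrom and the orientational part in radians
#' added as raw numbers. The mixed units are the defining convention of the
#' 6D metric; the bulk density carries the dimensional bookkeeping in the
#' entropy formulas.
#'
#' @param a,b \code{water_pose} objects.
#' @return dimensionless mixed-metric distance.
#' @export
total_distance <- function(a, b) {
  fa <- .pose_fields(a); fb <- .pose_fields(b)
  dt <- .vnorm(fa$p - fb$p)
  do <- orient_distance(fa$q, fb$q)
  sqrt(dt^2 + do^2)
}

#' Twelve-dimensional distance between two pose pairs
#'
#' Combines the total distances of the site-1 poses and of the site-2 poses:
#' \eqn{d_{pair} = \sqrt{d_{total}^2 + d_{total}'^2}}. The site ordering
#' inside each pair is fixed; it is never swapped between frames.
#'
#' @param pairA,pairB lists of two \code{water_pose} objects (site 1,
#'   site 2).
#' @return dimensionless mixed-metric distance.
#' @export
pair_distance <- function(pairA, pairB) {
  sqrt(total_distance(pairA[[1]], pairB[[1]])^2 +
       total_distance(pairA[[2]], pairB[[2]])^2)
}

# vectorized metric between matched rows of two pose sets
.total_distance_rows <- function(p1, q1, p2, q2) {
  dt2 <- rowSums((p1 - p2)^2)
  adot <- pmin(1, abs(rowSums(q1 * q2)))
  sqrt(dt2 + (2 * acos(adot))^2)
}
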