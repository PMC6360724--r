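# Elementary rotations and Cardan (sequenced) angle decomposition.
#
# Convention: active rotations of column vectors in a right-handed frame,
# angles in radians internally; user-facing functions take/return degrees.

#' Elementary rotation matrices
#'
#' Active right-handed rotation about a lab axis.
#'
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

.axis_index <- c(x = 1L, y = 2L, z = 3L)
.rot_fun <- list(x = rot_x, y = rot_y, z = rot_z)

.check_sequence <- function(sequence) {
  ax <- strsplit(sequence, "")[[1]]
  if (length(ax) != 3L || !all(ax %in% c("x", "y", "z")) || anyDuplicated(ax))
    stop("Cardan sequence must be three distinct axes, e.g. 'yxz', got '",
         sequence, "'", call. = FALSE)
  ax
}

#' Compose a rotation from Cardan angles
#'
#' Builds `R = R_i(a1) %*% R_j(a2) %*% R_k(a3)` for the intrinsic axis
#' sequence `i-j-k`.
#'
#' @param angles_deg Numeric length-3, degrees, in sequence order.
#' @param sequence Three-letter axis string, e.g. `"yxz"`.
#' @return A 3x3 rotation matrix.
#' @export
cardan_compose <- function(angles_deg, sequence = "yxz") {
  ax <- .check_sequence(sequence)
  a <- angles_deg * pi / 180
  .rot_fun[[ax[1]]](a[1]) %*% .rot_fun[[ax[2]]](a[2]) %*% .rot_fun[[ax[3]]](a[3])
}

#' Decompose a rotation into Cardan angles
#'
#' Inverse of [cardan_compose()]. The middle angle lies in \[-90, 90\] degrees;
#' proximity to gimbal lock (|middle| > 85 deg) is flagged via the
#' `"gimbal"` attribute.
#'
#' @param R A 3x3 proper orthogonal matrix.
#' @param sequence Three-letter axis string.
#' @return Numeric length-3 (degrees, sequence order) with attribute `gimbal`.
#' @export
cardan_decompose <- function(R, sequence = "yxz") {
  check_rotation(R)
  ax <- .check_sequence(sequence)
  i <- .axis_index[ax[1]]; j <- .axis_index[ax[2]]; k <- .axis_index[ax[3]]
  # cyclic sequences (xyz, yzx, zxy) have eps = +1, anti-cyclic -1
  eps <- if (paste(ax, collapse = "") %in% c("xyz", "yzx", "zxy")) 1 else -1
  sb <- eps * R[i, k]
  sb <- max(-1, min(1, sb))
  beta <- asin(sb)
  alpha <- atan2(-eps * R[j, k], R[k, k])
  gamma <- atan2(-eps * R[i, j], R[i, i])
  out <- c(alpha, beta, gamma) * 180 / pi
  attr(out, "gimbal") <- abs(out[2]) > 85
  out
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis Unit length-3 axis.
#' @param theta Angle in radians.
#' @keywords internal
rot_axis <- function(axis, theta) {
  k <- unitize(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) * cos(theta) + sin(theta) * K + (1 - cos(theta)) * tcrossprod(k)
}

#' Validate a rotation matrix
#'
#' @param R Matrix to check.
#' @param tol Orthogonality/determinant tolerance.
#' @keywords internal
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L) || !all(is.finite(R)))
    stop("expected a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a proper rotation (orthogonality/determinant check failed)",
         call. = FALSE)
  invisible(R)
}

#' Normalise a vector to unit length
#' @keywords internal
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Root-mean-square
#' @keywords internal
rms <- function(x) sqrt(mean(x^2))
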