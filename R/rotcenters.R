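# Functional joint calibration from relative segment motion:
# symmetrical centre of rotation (SCoRE) and symmetrical axis of rotation
# (SARA), both as linear least squares over stacked per-frame equations.

.stack_joint_system <- function(parent_poses, child_poses) {
  np <- dim(parent_poses$rotations)[3]
  nc <- dim(child_poses$rotations)[3]
  if (np != nc) stop("input error: pose sequences differ in length", call. = FALSE)
  if (np < 10L) stop("conditioning error: need at least 10 frames", call. = FALSE)
  A <- matrix(NA_real_, 3 * np, 6)
  b <- numeric(3 * np)
  for (f in seq_len(np)) {
    r <- (3 * f - 2):(3 * f)
    A[r, 1:3] <- parent_poses$rotations[, , f]
    A[r, 4:6] <- -child_poses$rotations[, , f]
    b[r] <- child_poses$translations[f, ] - parent_poses$translations[f, ]
  }
  list(A = A, b = b, n = np)
}

#' Functional joint centre (SCoRE)
#'
#' Finds the points fixed in the parent and child technical frames that
#' coincide best in the lab over the trial: minimises the mean squared
#' distance between the two per-frame reconstructions, a linear least-squares
#' problem in the 6 unknown local coordinates.
#'
#' @param parent_poses,child_poses [cluster_poses()] results over the same
#'   calibration movement (e.g. hip circumduction).
#' @return An object of class `"functional_joint"` with `centre_parent`,
#'   `centre_child` (local mm), `residual` (rms mm between the two
#'   reconstructions), `condition` (condition number of the stacked system).
#' @export
score_centre <- function(parent_poses, child_poses) {
  sys <- .stack_joint_system(parent_poses, child_poses)
  sv <- svd(sys$A)
  cond <- sv$d[1] / sv$d[6]
  small <- sv$d < 1e-8 * sv$d[1]
  if (sum(small) > 1L)
    stop(sprintf(
      "conditioning error: insufficient relative rotation for SCoRE (condition number %.3g)",
      cond), call. = FALSE)
  # a single collapsed direction (perfect hinge) leaves a one-parameter
  # family of centres along the axis; take the minimum-norm member
  coef <- crossprod(sv$u, sys$b)
  coef <- ifelse(small, 0, coef / sv$d)
  x <- sv$v %*% coef
  resid <- sys$A %*% x - sys$b
  per_frame <- sqrt(rowSums(matrix(resid, ncol = 3, byrow = TRUE)^2))
  structure(list(centre_parent = x[1:3], centre_child = x[4:6],
                 axis_parent = NULL, axis_child = NULL,
                 residual = rms(per_frame), condition = cond),
            class = "functional_joint")
}

#' Functional joint axis (SARA)
#'
#' Least-squares estimate of the axis fixed in both segments during
#' hinge-dominant relative motion. The right singular vector of the stacked
#' system belonging to the smallest singular value carries the axis direction
#' in the parent and child technical frames; the centre estimates are the
#' truncated (minimum-norm) least-squares solution, a point on the axis.
#'
#' @inheritParams score_centre
#' @return A `"functional_joint"` with unit `axis_parent`/`axis_child`,
#'   `centre_parent`/`centre_child` (a point on the axis, local mm),
#'   `residual` (rms mm), and `ambiguous` (TRUE when the motion is ball-like
#'   and the axis is ill-defined).
#' @export
sara_axis <- function(parent_poses, child_poses) {
  sys <- .stack_joint_system(parent_poses, child_poses)
  sv <- svd(sys$A)
  ambiguous <- sv$d[5] < 2 * sv$d[6] + 1e-12 * sv$d[1]
  if (ambiguous)
    warning("ambiguity warning: relative motion is ball-like; SARA axis is ill-defined")
  v <- sv$v[, 6]
  # deterministic sign: largest-magnitude component of the parent-frame axis
  # is positive (flipping flips both frames' directions together)
  s <- sign(v[which.max(abs(v[1:3]))])
  v <- s * v
  ap <- unitize(v[1:3]); ac <- unitize(v[4:6])
  # truncated LS solution: a point on the axis in each frame
  dtr <- sv$d
  keep <- dtr > 1e-8 * dtr[1]
  keep[6] <- FALSE
  coef <- crossprod(sv$u, sys$b)
  coef <- ifelse(keep, coef / dtr, 0)
  x <- sv$v %*% coef
  resid <- sys$A %*% x - sys$b
  per_frame <- sqrt(rowSums(matrix(resid, ncol = 3, byrow = TRUE)^2))
  structure(list(centre_parent = x[1:3], centre_child = x[4:6],
                 axis_parent = ap, axis_child = ac,
                 residual = rms(per_frame), condition = sv$d[1] / sv$d[6],
                 ambiguous = ambiguous),
            class = "functional_joint")
}

#' @export
print.functional_joint <- function(x, ...) {
  cat("<functional_joint> residual", sprintf("%.3f", x$residual), "mm")
  if (!is.null(x$axis_parent))
    cat("; axis (parent frame)",
        paste(sprintf("%.3f", x$axis_parent), collapse = ", "))
  cat("\n")
  invisible(x)
}
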