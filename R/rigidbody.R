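# Least-squares rigid pose estimation (Soderkvist-Wedin / Kabsch) and CAST
# calibration/reconstruction of virtual markers.

#' Least-squares rigid pose from matched point clouds
#'
#' Finds the rotation `R` (det = +1) and translation `t` minimising
#' `sum_i ||obs_i - (R ref_i + t)||^2` via SVD of the cross-dispersion
#' matrix, with the reflection guard flipping the smallest singular
#' direction when needed.
#'
#' @param ref_cloud n x 3 matrix of reference (e.g. calibration) positions;
#'   n >= 3, non-collinear.
#' @param obs_cloud n x 3 matrix of observed positions, matched row-wise.
#' @return An object of class `"pose"`: list with `rotation` (3x3),
#'   `translation` (length 3, mm), `rms_residual` (mm).
#' @export
estimate_pose <- function(ref_cloud, obs_cloud) {
  ref_cloud <- as.matrix(ref_cloud); obs_cloud <- as.matrix(obs_cloud)
  if (ncol(ref_cloud) != 3L || ncol(obs_cloud) != 3L)
    stop("point clouds must be n x 3 matrices", call. = FALSE)
  if (nrow(ref_cloud) != nrow(obs_cloud))
    stop("input error: mismatched point counts (", nrow(ref_cloud), " vs ",
         nrow(obs_cloud), ")", call. = FALSE)
  n <- nrow(ref_cloud)
  if (n < 3L) stop("geometry error: need at least 3 points", call. = FALSE)
  if (!all(is.finite(ref_cloud)) || !all(is.finite(obs_cloud)))
    stop("point clouds contain non-finite values (gap?)", call. = FALSE)
  rc <- colMeans(ref_cloud); oc <- colMeans(obs_cloud)
  A <- sweep(ref_cloud, 2, rc); B <- sweep(obs_cloud, 2, oc)
  sv_ref <- svd(A, nu = 0, nv = 0)$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1))
    stop("geometry error: reference cloud is (near-)collinear", call. = FALSE)
  H <- crossprod(A, B)            # 3x3 cross-dispersion, ref -> obs
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- oc - as.vector(R %*% rc)
  fit <- B - A %*% t(R)
  structure(list(rotation = R, translation = t,
                 rms_residual = sqrt(mean(rowSums(fit^2)))),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  ang <- tryCatch(cardan_decompose(x$rotation), error = function(e) rep(NA, 3))
  cat("<pose> rms residual", sprintf("%.4g", x$rms_residual), "mm; angles (yxz)",
      paste(sprintf("%.2f", ang), collapse = "/"), "deg\n")
  invisible(x)
}

#' Apply a pose to points
#' @param pose A [estimate_pose()] result.
#' @param points n x 3 matrix (or length-3 vector) in the reference frame.
#' @return Transformed coordinates, same shape.
#' @keywords internal
apply_pose <- function(pose, points) {
  if (is.null(dim(points)))
    return(as.vector(pose$rotation %*% points) + pose$translation)
  sweep(points %*% t(pose$rotation), 2, pose$translation, `+`)
}

#' Store an anatomical point in a segment's technical frame (CAST)
#'
#' Expresses a globally digitised anatomical point in the owner segment's
#' technical (cluster) frame during the calibration trial:
#' `coords = R^-1 (p - t)`.
#'
#' @param anatomical_point Length-3 global position (mm) in the calibration
#'   frame.
#' @param cluster_pose The owner cluster's [estimate_pose()] in the same
#'   calibration frame.
#' @param owner_segment Segment name (metadata).
#' @param source_trial Calibration trial label (metadata).
#' @return An object of class `"local_point"`.
#' @export
calibrate_local <- function(anatomical_point, cluster_pose,
                            owner_segment = NA_character_,
                            source_trial = NA_character_) {
  if (!inherits(cluster_pose, "pose")) stop("cluster_pose must be a pose", call. = FALSE)
  check_rotation(cluster_pose$rotation)
  coords <- as.vector(crossprod(cluster_pose$rotation,
                                anatomical_point - cluster_pose$translation))
  structure(list(owner_segment = owner_segment, coords = coords,
                 source_trial = source_trial),
            class = "local_point")
}

#' Reconstruct a calibrated point in the global frame (CAST)
#'
#' Inverse of [calibrate_local()]: `p = R coords + t` with the cluster pose of
#' the current frame. Exact on rigid motion.
#'
#' @param local A [calibrate_local()] result.
#' @param cluster_pose The owner cluster's pose in the current frame.
#' @return Length-3 global position (mm).
#' @export
reconstruct_global <- function(local, cluster_pose) {
  if (!inherits(cluster_pose, "pose")) stop("cluster_pose must be a pose", call. = FALSE)
  as.vector(cluster_pose$rotation %*% local$coords) + cluster_pose$translation
}

#' Per-frame cluster poses over a trial
#'
#' Estimates the pose of one marker cluster in every frame of a trial against
#' a fixed reference cloud. Frames with gaps in any cluster marker raise an
#' error naming the marker.
#'
#' @param trial A [trial()] object.
#' @param markers Cluster marker names (>= 3).
#' @param ref_cloud n x 3 reference geometry, rows matching `markers`.
#' @return List with `rotations` (3 x 3 x F), `translations` (F x 3),
#'   `rms_residual` (length F).
#' @export
cluster_poses <- function(trial, markers, ref_cloud) {
  idx <- match(markers, trial$markers)
  if (anyNA(idx))
    stop("gap error: cluster markers missing from trial: ",
         paste(markers[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(trial$gaps[, idx]))
    stop("gap error: flagged gaps in cluster marker(s) ",
         paste(markers[colSums(trial$gaps[, idx, drop = FALSE]) > 0],
               collapse = ", "), call. = FALSE)
  nf <- n_frames(trial)
  rot <- array(NA_real_, c(3, 3, nf))
  tra <- matrix(NA_real_, nf, 3)
  res <- numeric(nf)
  for (f in seq_len(nf)) {
    p <- estimate_pose(ref_cloud, trial$data[f, idx, ])
    rot[, , f] <- p$rotation
    tra[f, ] <- p$translation
    res[f] <- p$rms_residual
  }
  list(rotations = rot, translations = tra, rms_residual = res)
}

#' Reconstruct a calibrated point across all frames
#'
#' @param local A [calibrate_local()] result.
#' @param poses A [cluster_poses()] result.
#' @return F x 3 matrix of global positions (mm).
#' @export
reconstruct_series <- function(local, poses) {
  nf <- dim(poses$rotations)[3]
  out <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf))
    out[f, ] <- as.vector(poses$rotations[, , f] %*% local$coords) +
      poses$translations[f, ]
  out
}
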