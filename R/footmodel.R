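# Anatomical segment frames for the multi-segment foot model: subject
# calibration (CAST reference clouds, virtual-marker local coordinates,
# stance-snapshotted vertical axes, functional knee/hip calibration) and
# per-frame frame construction with all virtual points.

.up_vec <- function(up_axis) {
  switch(up_axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         stop("unknown up axis '", up_axis, "'", call. = FALSE))
}

.cluster_segments <- c("pelvis", "thigh", "tibia", "hindfoot", "midfoot",
                       "forefoot", "first_metatarsal")

# orthonormal right-handed frames; the first argument named axis is kept exact
.gs_zx <- function(z, x_prov) { y <- unitize(cross3(z, x_prov)); cbind(cross3(y, z), y, z) }
.gs_zy <- function(z, y_prov) { x <- unitize(cross3(y_prov, z)); cbind(x, cross3(z, x), z) }
.gs_xz <- function(x, z_prov) { y <- unitize(cross3(z_prov, x)); cbind(x, y, cross3(x, y)) }

.mean_marker <- function(trial, name) {
  xyz <- marker_xyz(trial, name)
  if (anyNA(xyz))
    stop("calibration error: gaps in calibration marker ", name, call. = FALSE)
  colMeans(xyz)
}

#' Calibrate a subject from the static and functional calibration trials
#'
#' Builds the CAST calibration bundle: per-segment technical reference clouds
#' (mean natural-stance cluster geometry), local coordinates of the calibrated
#' anatomical points (malleoli LMAL/MMAL in the tibia cluster, heel offset
#' CALe in the hindfoot cluster, first metatarsal head MT1 in the
#' MTB1/MTS1/MTS2 cluster, knee joint centre KJC as the mid-point of the
#' femoral condyle markers from the lunge trial, hip centre from SCoRE), the
#' knee flexion axis from SARA, and each segment's stance vertical snapshot
#' carried by its technical frame.
#'
#' @param trials Named list of [trial()] objects; requires `natural`, `lunge`
#'   and `squat_circumduction`.
#' @param schema A [default_marker_schema()]; defaults to the trial side.
#' @param axis_len Length (mm) of the displayed X_MET anterior axis vector.
#' @return An object of class `"calibration"`.
#' @export
calibrate_subject <- function(trials, schema = NULL, axis_len = 50) {
  for (need in c("natural", "lunge", "squat_circumduction"))
    if (is.null(trials[[need]]))
      stop("calibration error: missing '", need, "' trial",
           if (need == "lunge") " (required for KJC)", call. = FALSE)
  stance <- trials$natural
  if (is.null(schema)) schema <- default_marker_schema(stance$side)
  chk <- validate_trial(stance, schema, calibration = TRUE)
  if (!chk$pass)
    stop("calibration error: stance trial fails validation (missing: ",
         paste(chk$missing, collapse = ", "), ")", call. = FALSE)
  up <- .up_vec(stance$up_axis)

  ref_clouds <- lapply(schema$segments[.cluster_segments], function(seg) {
    cloud <- t(vapply(seg$technical, function(m) .mean_marker(stance, m),
                      numeric(3)))
    rownames(cloud) <- seg$technical
    cloud
  })
  stance_pose <- lapply(.cluster_segments, function(s) {
    obs <- t(vapply(rownames(ref_clouds[[s]]),
                    function(m) .mean_marker(stance, m), numeric(3)))
    estimate_pose(ref_clouds[[s]], obs)
  })
  names(stance_pose) <- .cluster_segments

  loc <- function(marker, owner, tr = stance, pose = NULL) {
    if (is.null(pose)) pose <- stance_pose[[owner]]
    calibrate_local(.mean_marker(tr, marker), pose, owner_segment = owner,
                    source_trial = tr$label)
  }
  locals <- list(
    LMAL = loc("LMAL", "tibia"),
    MMAL = loc("MMAL", "tibia"),
    CALe = loc("CALe", "hindfoot"),
    MT1  = loc("MT1", "first_metatarsal")
  )

  # KJC from the lunge: mid-point of the femoral condyle markers, stored in
  # the thigh technical frame
  lunge <- trials$lunge
  thigh_markers <- rownames(ref_clouds$thigh)
  lunge_obs <- t(vapply(thigh_markers, function(m) .mean_marker(lunge, m),
                        numeric(3)))
  thigh_in_lunge <- estimate_pose(ref_clouds$thigh, lunge_obs)
  kjc_global <- (.mean_marker(lunge, "LFC") + .mean_marker(lunge, "MFC")) / 2
  locals$KJC <- calibrate_local(kjc_global, thigh_in_lunge,
                                owner_segment = "thigh", source_trial = "lunge")

  # functional calibration: hip SCoRE centre and knee SARA axis
  squat <- trials$squat_circumduction
  sq_poses <- lapply(c("pelvis", "thigh", "tibia"), function(s)
    cluster_poses(squat, rownames(ref_clouds[[s]]), ref_clouds[[s]]))
  names(sq_poses) <- c("pelvis", "thigh", "tibia")
  hip <- score_centre(sq_poses$pelvis, sq_poses$thigh)
  locals$HIP <- structure(list(owner_segment = "thigh",
                               coords = hip$centre_child,
                               source_trial = squat$label),
                          class = "local_point")
  knee <- sara_axis(sq_poses$thigh, sq_poses$tibia)
  axis_thigh <- knee$axis_parent
  # orient the flexion axis toward the subject's left (+y of the lab at
  # stance, where the thigh technical frame coincides with the lab)
  axis_lab <- as.vector(stance_pose$thigh$rotation %*% axis_thigh)
  if (sum(axis_lab * c(0, 1, 0)) < 0) axis_thigh <- -axis_thigh

  up_local <- lapply(stance_pose, function(p)
    as.vector(crossprod(p$rotation, up)))

  structure(list(schema = schema, side = schema$side, up = up,
                 up_axis = stance$up_axis, ref_clouds = ref_clouds,
                 locals = locals, up_local = up_local,
                 sara_axis_thigh = axis_thigh,
                 hip_residual = hip$residual, sara_residual = knee$residual,
                 axis_len = axis_len),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>", x$side, "side;", length(x$ref_clouds),
      "segment clusters;",
      "hip SCoRE residual", sprintf("%.3f", x$hip_residual), "mm;",
      "knee SARA residual", sprintf("%.3f", x$sara_residual), "mm\n")
  invisible(x)
}

#' Build per-frame anatomical frames and virtual points for a trial
#'
#' Reconstructs all virtual markers through the CAST chain, then constructs
#' anatomical coordinate systems for tibia, hindfoot, midfoot, forefoot,
#' first metatarsal, whole foot, thigh and pelvis. Every moving segment's
#' vertical axis is the stance-snapshotted lab vertical carried by its
#' technical frame, so all frames are level in the calibration posture by
#' construction; anterior axes come from the declared marker recipes. The
#' mediolateral axis always points to the subject's left, for either side.
#'
#' @param trial A [trial()] object (validated; filtered if dynamic).
#' @param calibration A [calibrate_subject()] bundle.
#' @return An object of class `"frame_set"`: list with `segments` (per
#'   segment: `R` 3x3xF rotation array, `origin` Fx3), `virtual` (per virtual
#'   point: Fx3), and trial metadata.
#' @export
build_frames <- function(trial, calibration) {
  cal <- calibration
  chk <- validate_trial(trial, cal$schema)
  if (!chk$pass)
    stop("gap error: trial '", trial$label, "' fails validation (missing: ",
         paste(chk$missing, collapse = ", "), "; ",
         paste(chk$warnings, collapse = "; "), ")", call. = FALSE)
  poses <- lapply(.cluster_segments, function(s)
    cluster_poses(trial, rownames(cal$ref_clouds[[s]]), cal$ref_clouds[[s]]))
  names(poses) <- .cluster_segments
  nf <- n_frames(trial)

  vs <- list(
    LMAL = reconstruct_series(cal$locals$LMAL, poses$tibia),
    MMAL = reconstruct_series(cal$locals$MMAL, poses$tibia),
    CALe = reconstruct_series(cal$locals$CALe, poses$hindfoot),
    MT1  = reconstruct_series(cal$locals$MT1, poses$first_metatarsal),
    KJC  = reconstruct_series(cal$locals$KJC, poses$thigh),
    HIP  = reconstruct_series(cal$locals$HIP, poses$thigh)
  )
  mk <- function(name) {
    m <- marker_xyz(trial, name)
    if (anyNA(m)) stop("gap error: gaps in marker ", name, call. = FALSE)
    m
  }
  MTB1 <- mk("MTB1"); MT5 <- mk("MT5"); MT2 <- mk("MT2"); FFM <- mk("FFM")
  CAL <- mk("CAL"); SUS <- mk("SUS"); HDL <- mk("HDL")
  NAV <- mk("NAV"); CUB <- mk("CUB"); MFM <- mk("MFM")
  vs$MidMet <- (MTB1 + vs$MT1) / 2
  vs$FTML <- (vs$MT1 + MT5) / 2
  met_dir <- vs$MT1 - MTB1
  vs$X_MET <- vs$MT1 + cal$axis_len * met_dir /
    sqrt(rowSums(met_dir^2))

  upseg <- function(seg, f)
    as.vector(poses[[seg]]$rotations[, , f] %*% cal$up_local[[seg]])
  ml_sign <- if (cal$side == "right") 1 else -1

  seg_names <- c("tibia", "hindfoot", "midfoot", "forefoot",
                 "first_metatarsal", "foot", "thigh", "pelvis")
  segs <- lapply(seg_names, function(s)
    list(R = array(NA_real_, c(3, 3, nf)), origin = matrix(NA_real_, nf, 3)))
  names(segs) <- seg_names

  for (f in seq_len(nf)) {
    # tibia: vertical from the stance snapshot, mediolateral from the malleoli
    ankle <- (vs$LMAL[f, ] + vs$MMAL[f, ]) / 2
    y_ml <- ml_sign * (vs$MMAL[f, ] - vs$LMAL[f, ])
    segs$tibia$R[, , f] <- .gs_zy(unitize(upseg("tibia", f)), y_ml)
    segs$tibia$origin[f, ] <- ankle
    # hindfoot: long axis CAL -> mid(SUS, HDL)
    segs$hindfoot$R[, , f] <-
      .gs_zx(unitize(upseg("hindfoot", f)), (SUS[f, ] + HDL[f, ]) / 2 - CAL[f, ])
    segs$hindfoot$origin[f, ] <- vs$CALe[f, ]
    # midfoot: anterior toward the dorsal mid marker
    segs$midfoot$R[, , f] <-
      .gs_zx(unitize(upseg("midfoot", f)), MFM[f, ] - (NAV[f, ] + CUB[f, ]) / 2)
    segs$midfoot$origin[f, ] <- (NAV[f, ] + CUB[f, ] + MFM[f, ]) / 3
    # forefoot
    segs$forefoot$R[, , f] <-
      .gs_zx(unitize(upseg("forefoot", f)), MT2[f, ] - FFM[f, ])
    segs$forefoot$origin[f, ] <- vs$FTML[f, ]
    # first metatarsal: exact anterior x along MTB1 -> MT1
    segs$first_metatarsal$R[, , f] <-
      .gs_xz(unitize(vs$MT1[f, ] - MTB1[f, ]),
             unitize(upseg("first_metatarsal", f)))
    segs$first_metatarsal$origin[f, ] <- vs$MT1[f, ]
    # whole foot: anterior CALe -> FTML, vertical carried by the hindfoot
    segs$foot$R[, , f] <-
      .gs_zx(unitize(upseg("hindfoot", f)), vs$FTML[f, ] - vs$CALe[f, ])
    segs$foot$origin[f, ] <- vs$CALe[f, ]
    # thigh: vertical along KJC -> hip, mediolateral along the SARA axis
    sara <- as.vector(poses$thigh$rotations[, , f] %*% cal$sara_axis_thigh)
    segs$thigh$R[, , f] <- .gs_zy(unitize(vs$HIP[f, ] - vs$KJC[f, ]), sara)
    segs$thigh$origin[f, ] <- vs$HIP[f, ]
    # pelvis: technical frame, centroid origin
    segs$pelvis$R[, , f] <- poses$pelvis$rotations[, , f]
  }
  pel_idx <- match(rownames(cal$ref_clouds$pelvis), trial$markers)
  segs$pelvis$origin <- t(apply(trial$data[, pel_idx, , drop = FALSE], 1,
                                function(m) colMeans(matrix(m, ncol = 3))))

  structure(list(segments = segs, virtual = vs, poses = poses,
                 side = cal$side, rate = trial$rate,
                 up_axis = trial$up_axis, label = trial$label),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set>", x$label, "|", nrow(x$virtual$MT1), "frames |",
      length(x$segments), "segments,", length(x$virtual), "virtual points\n")
  invisible(x)
}
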