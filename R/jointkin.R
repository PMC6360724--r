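# Joint-coordinate-system angles: Cardan decompositions per joint, the
# first-MTPJ transverse-plane angle, and per-trial angle streams.
#
# Axis convention: segment frames have x anterior, y toward the subject's
# left, z up (stance-level). Clinical signs are made side-invariant so that
# eversion, abduction and external rotation are positive for either limb.

.sign_eversion <- function(side) if (side == "right") 1 else -1
.sign_abduction <- function(side) if (side == "right") -1 else 1

#' Cardan joint angles between two segment frames
#'
#' Decomposes `R_rel = t(parent) %*% child` in the declared intrinsic Cardan
#' sequence. With the default `"yxz"` the components are, in order:
#' sagittal (flexion), frontal (inversion/eversion), transverse
#' (ab/adduction or axial rotation). Gimbal proximity (|middle| > 85 deg) is
#' flagged on the result.
#'
#' @param parent,child 3x3 proper orthogonal segment orientation matrices.
#' @param sequence Cardan sequence, see [cardan_decompose()].
#' @return Length-3 numeric (degrees, sequence order), attribute `gimbal`.
#' @export
jcs_angles <- function(parent, child, sequence = "yxz") {
  check_rotation(parent); check_rotation(child)
  cardan_decompose(crossprod(parent, child), sequence)
}

#' First-MTPJ transverse-plane angle
#'
#' Signed angle between the hallux vector (MT1 -> HAL) and the anterior
#' metatarsal axis (MTB1 -> MT1, the X_MET direction), both projected onto
#' the metatarsal transverse plane (perpendicular to the metatarsal vertical
#' axis). Positive = lateral deviation (abduction) for the declared side.
#'
#' @param MT1,MTB1,HAL Length-3 global positions (mm).
#' @param met_frame 3x3 first-metatarsal frame (column 3 = vertical axis).
#' @param side `"right"` or `"left"`.
#' @return Angle in degrees.
#' @export
mtpj_transverse_angle <- function(MT1, MTB1, HAL, met_frame, side = "right") {
  check_rotation(met_frame)
  z <- met_frame[, 3]
  proj <- function(v) v - sum(v * z) * z
  u <- proj(HAL - MT1)
  v <- proj(MT1 - MTB1)
  if (sqrt(sum(u^2)) < 1e-9)
    stop("undefined-angle error: HAL coincides with MT1 in the transverse plane",
         call. = FALSE)
  ang <- atan2(sum(cross3(v, u) * z), sum(v * u)) * 180 / pi
  .sign_abduction(side) * ang
}

#' Transverse-plane foot abduction (TIB-FOOT)
#'
#' Transverse component of the whole-foot-relative-to-tibia JCS
#' decomposition; positive = abduction (toes away from the midline).
#'
#' @param tibia_frame,foot_frame 3x3 orientation matrices.
#' @param side `"right"` or `"left"`.
#' @param sequence Cardan sequence.
#' @return Degrees.
#' @export
foot_abduction <- function(tibia_frame, foot_frame, side = "right",
                           sequence = "yxz") {
  .sign_abduction(side) * jcs_angles(tibia_frame, foot_frame, sequence)[3]
}

#' Transverse-plane knee rotation
#'
#' Transverse JCS component of the shank relative to the thigh, with the
#' thigh frame oriented by the knee joint centre, the hip centre and the SARA
#' flexion axis; positive = external tibiofemoral rotation.
#'
#' @param thigh_frame,shank_frame 3x3 orientation matrices.
#' @param side `"right"` or `"left"`.
#' @param sequence Cardan sequence.
#' @return Degrees.
#' @export
knee_transverse_angle <- function(thigh_frame, shank_frame, side = "right",
                                  sequence = "yxz") {
  .sign_abduction(side) * jcs_angles(thigh_frame, shank_frame, sequence)[3]
}

.joint_plan <- function() {
  # joint, parent segment, child segment, plane, component index in yxz,
  # sign map, convention string
  list(
    hindfoot_eversion = list(parent = "tibia", child = "hindfoot",
                             plane = "frontal", comp = 2L, sgn = .sign_eversion,
                             convention = "+ = eversion"),
    midfoot_abduction = list(parent = "hindfoot", child = "midfoot",
                             plane = "transverse", comp = 3L,
                             sgn = .sign_abduction, convention = "+ = abduction"),
    forefoot_abduction = list(parent = "midfoot", child = "forefoot",
                              plane = "transverse", comp = 3L,
                              sgn = .sign_abduction, convention = "+ = abduction"),
    foot_abduction = list(parent = "tibia", child = "foot",
                          plane = "transverse", comp = 3L,
                          sgn = .sign_abduction, convention = "+ = abduction"),
    knee_rotation = list(parent = "thigh", child = "tibia",
                         plane = "transverse", comp = 3L,
                         sgn = .sign_abduction,
                         convention = "+ = external tibiofemoral rotation")
  )
}

#' Per-frame angle streams for a trial
#'
#' Computes the study's angle set from a [build_frames()] result: hindfoot
#' eversion (TIB-HIND frontal), midfoot abduction (HIND-MIDF transverse),
#' forefoot abduction (MID-FORE transverse), foot abduction (TIB-FOOT
#' transverse), knee rotation (transverse), the first-MTPJ transverse-plane
#' angle, and the navicular tuberosity height.
#'
#' @param frames A [build_frames()] result.
#' @param trial The same [trial()] the frames were built from (for the NAV
#'   marker and HAL positions).
#' @param sequence Cardan sequence for the JCS joints.
#' @return An object of class `"angle_set"`: named list of per-frame numeric
#'   vectors (degrees; `navicular_height` in mm), with a `conventions`
#'   attribute.
#' @export
trial_angles <- function(frames, trial, sequence = "yxz") {
  nf <- nrow(frames$virtual$MT1)
  plan <- .joint_plan()
  out <- lapply(plan, function(p) numeric(nf))
  HAL <- marker_xyz(trial, "HAL")
  MTB1 <- marker_xyz(trial, "MTB1")
  mtpj <- numeric(nf)
  for (f in seq_len(nf)) {
    for (j in names(plan)) {
      p <- plan[[j]]
      a <- jcs_angles(frames$segments[[p$parent]]$R[, , f],
                      frames$segments[[p$child]]$R[, , f], sequence)
      out[[j]][f] <- p$sgn(frames$side) * a[p$comp]
    }
    mtpj[f] <- mtpj_transverse_angle(frames$virtual$MT1[f, ], MTB1[f, ],
                                     HAL[f, ],
                                     frames$segments$first_metatarsal$R[, , f],
                                     frames$side)
  }
  out$mtpj_abduction <- mtpj
  out$navicular_height <- marker_height(trial, "NAV")
  conventions <- c(vapply(plan, `[[`, character(1), "convention"),
                   mtpj_abduction = "+ = abduction (lateral deviation)",
                   navicular_height = "mm above lab origin")
  structure(out, conventions = conventions, side = frames$side,
            rate = frames$rate, label = frames$label, class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat("<angle_set>", attr(x, "label"), "|",
      length(x[[1]]), "frames |", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Export an angle set as a long-format data frame
#'
#' @param angles An [trial_angles()] result.
#' @return data.frame with columns trial, variable, frame, value.
#' @export
angles_long <- function(angles) {
  do.call(rbind, lapply(names(angles), function(v)
    data.frame(trial = attr(angles, "label"), variable = v,
               frame = seq_along(angles[[v]]) - 1L, value = angles[[v]])))
}
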