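# Shared fixtures: compact synthetic configurations and pose-sequence
# builders used across the test files.

zero_offsets <- function() {
  z <- c(hindfoot_eversion = 0, midfoot_abduction = 0,
         forefoot_abduction = 0, foot_abduction = 0,
         mtpj_abduction = 0, navicular_drop = 0)
  list(natural = z, functional = z, forced = z, saute = z)
}

# a small, fast config: neutral calibration posture, short statics
quick_config <- function(seed = 1, noise_sd = 0, side = "right",
                         conditions = zero_offsets(), ...) {
  synth_config(seed = seed, noise_sd = noise_sd, side = side,
               conditions = conditions, static_frames = 60L,
               squat_frames = 250L, seated_frames = 60L,
               repeat_jitter_deg = 0, ...)
}

# only the trials a given analysis needs (calibration set + extras)
quick_trials <- function(config, extra = character(0)) {
  labels <- unique(c("natural", "lunge", "squat_circumduction", extra))
  out <- lapply(labels, function(l) generate_trial(config, l))
  names(out) <- labels
  list(trials = lapply(out, `[[`, "trial"),
       truths = lapply(out, `[[`, "truth"))
}

# pose sequences for a synthetic spherical or hinge joint, built from noisy
# marker clouds so pose noise is realistic marker noise
joint_pose_pair <- function(n_frames = 500, noise_sd = 0,
                            type = c("ball", "hinge"), centre = c(50, -20, 100),
                            axis = c(0, 1, 0), range_deg = 60, seed = 1) {
  type <- match.arg(type)
  set.seed(seed)
  parent_ref <- matrix(c(0, 0, 0, 80, 0, 0, 0, 70, 10, 20, 30, 90),
                       4, 3, byrow = TRUE)
  child_ref0 <- matrix(c(100, 0, 50, 170, 10, 40, 110, 80, 60, 140, 40, 120),
                       4, 3, byrow = TRUE)
  prot <- array(NA_real_, c(3, 3, n_frames)); ptra <- matrix(NA_real_, n_frames, 3)
  crot <- array(NA_real_, c(3, 3, n_frames)); ctra <- matrix(NA_real_, n_frames, 3)
  for (f in seq_len(n_frames)) {
    th <- 2 * pi * f / n_frames
    R <- if (type == "ball")
      cardan_compose(c(range_deg / 2 * sin(th), range_deg / 2 * cos(th),
                       10 * sin(2 * th)), "yxz")
    else rot_axis(axis, range_deg * pi / 180 * sin(th) / 2)
    obs_c <- sweep((child_ref0 - rep(centre, each = 4)) %*% t(R), 2, centre, `+`)
    obs_p <- parent_ref
    if (noise_sd > 0) {
      obs_c <- obs_c + rnorm(length(obs_c), 0, noise_sd)
      obs_p <- obs_p + rnorm(length(obs_p), 0, noise_sd)
    }
    pp <- estimate_pose(parent_ref, obs_p)
    cp <- estimate_pose(child_ref0, obs_c)
    prot[, , f] <- pp$rotation; ptra[f, ] <- pp$translation
    crot[, , f] <- cp$rotation; ctra[f, ] <- cp$translation
  }
  list(parent = list(rotations = prot, translations = ptra),
       child = list(rotations = crot, translations = ctra),
       centre = centre, axis = unitize(axis),
       child_ref = child_ref0)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
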