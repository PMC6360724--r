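# End-to-end orchestration: calibrate -> filter -> frames -> angles ->
# events -> measures per subject, and cohort-level summaries and statistics.

.static_angle_means <- function(trial, calibration) {
  fr <- build_frames(trial, calibration)
  ang <- trial_angles(fr, trial)
  vapply(ang, mean, numeric(1))
}

#' Process one subject end to end
#'
#' Calibrates from the natural-stance, lunge and squat/circumduction trials,
#' averages the static conditions across frames (and the repeated turnout
#' trials across repeats), filters the saute trial (zero-lag Butterworth,
#' study default 26 Hz), detects the demi-plie events from the pelvis-height
#' minima, selects the three consecutive sautes with the most consistent
#' excursions, and averages each kinematic variable over the three
#' demi-plies. Navicular drop is referenced to the natural-stance navicular
#' height.
#'
#' @param trials Named list of [trial()] objects as produced by
#'   [generate_subject()]: `natural`, `functional_turnout` (list),
#'   `forced_turnout` (list), `saute`, `lunge`, `squat_circumduction`,
#'   `seated_passive_er`, `seated_active_er`.
#' @param subject Subject identifier stored in the output rows.
#' @param cutoff Low-pass cutoff (Hz) for dynamic trials.
#' @param filter_order Net Butterworth order.
#' @param tempo_bpm Saute tempo for the event-detection cycle gate.
#' @return An object of class `"subject_result"`: `values` (data.frame
#'   subject, condition, variable, value), `knee` (data.frame subject,
#'   measurement, value), `events`, `calibration`.
#' @export
run_subject <- function(trials, subject = 1L, cutoff = 26, filter_order = 4,
                        tempo_bpm = 95) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  cal <- stage("calibrate", calibrate_subject(trials))

  nat <- stage("natural", .static_angle_means(trials$natural, cal))
  rep_means <- function(lst, lab) {
    m <- vapply(lst, function(tr) stage(lab, .static_angle_means(tr, cal)),
                numeric(length(nat)))
    rowMeans(m)
  }
  fun <- rep_means(trials$functional_turnout, "functional_turnout")
  for_ <- rep_means(trials$forced_turnout, "forced_turnout")

  saute_raw <- trials$saute
  saute_f <- stage("filter", filter_trial(saute_raw, cutoff, filter_order))
  fr <- stage("frames", build_frames(saute_f, cal))
  ang <- stage("angles", trial_angles(fr, saute_f))
  up_idx <- c(x = 1L, y = 2L, z = 3L)[saute_f$up_axis]
  pelvis_h <- fr$segments$pelvis$origin[, up_idx]
  ev <- stage("events", detect_events(pelvis_h, saute_f$rate, tempo_bpm))
  saute_vals <- extract_at_events(ang, ev)

  vals <- function(v, condition) {
    data.frame(subject = subject, condition = condition,
               variable = c("hindfoot_eversion", "midfoot_abduction",
                            "forefoot_abduction", "foot_abduction",
                            "mtpj_abduction", "navicular_drop_mm"),
               value = unname(c(
                 v[c("hindfoot_eversion", "midfoot_abduction",
                     "forefoot_abduction", "foot_abduction",
                     "mtpj_abduction")],
                 navicular_drop(v["navicular_height"],
                                nat["navicular_height"]))))
  }
  values <- rbind(vals(nat, "natural"), vals(fun, "functional"),
                  vals(for_, "forced"), vals(saute_vals, "saute"))

  knee <- do.call(rbind, lapply(
    c(passive = "seated_passive_er", active = "seated_active_er"),
    function(lab) {
      m <- stage(lab, .static_angle_means(trials[[lab]], cal))
      data.frame(subject = subject,
                 measurement = sub("seated_(.*)_er", "\\1", lab),
                 value = unname(m["knee_rotation"]))
    }))

  structure(list(values = values, knee = knee, events = ev,
                 calibration = cal),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result> subject", x$values$subject[1], "|",
      nrow(x$values), "condition values;", length(x$events$minima_frames),
      "sautes detected\n")
  invisible(x)
}

#' Cohort-level summaries and statistics
#'
#' Assembles the per-subject condition values into the study report:
#' condition summary (mean, SE, 95% CI), pairwise condition deltas,
#' repeated-measures ANOVA with Greenhouse-Geisser correction and Bonferroni
#' pairwise comparisons per kinematic variable (navicular drop over the
#' three first-position conditions, its natural baseline being 0 by
#' definition), stepwise regression of foot abduction on the candidate
#' strategies per condition, and Pearson correlations of hindfoot eversion
#' with the seated external-rotation measurements.
#'
#' @param values Data frame `subject`, `condition`, `variable`, `value` —
#'   either from [run_subject()] results (rbind of `$values`) or from
#'   [generate_cohort()]`$values`.
#' @param knee Data frame `subject`, `measurement`, `value` of seated
#'   external tibiofemoral rotation, or `NULL` to skip correlations.
#' @return An object of class `"cohort_report"`: `summary`, `deltas`,
#'   `anova` (per variable), `regression` (per condition), `correlations`,
#'   `normality`.
#' @export
run_cohort <- function(values, knee = NULL) {
  values$variable <- sub("^navicular_drop$", "navicular_drop_mm",
                         values$variable)
  n_sub <- length(unique(values$subject))
  if (n_sub < 2)
    stop("cohort statistics need at least 2 complete subjects", call. = FALSE)
  summary <- summarise_conditions(values)
  deltas <- table2_deltas(summary)

  wide <- function(var, conds) {
    sub <- values[values$variable == var & values$condition %in% conds, ]
    m <- stats::reshape(sub[, c("subject", "condition", "value")],
                        idvar = "subject", timevar = "condition",
                        direction = "wide")
    out <- as.matrix(m[, paste0("value.", conds), drop = FALSE])
    colnames(out) <- conds
    out
  }
  anova_vars <- intersect(
    c("hindfoot_eversion", "midfoot_abduction", "forefoot_abduction",
      "navicular_drop_mm", "mtpj_abduction", "foot_abduction"),
    unique(values$variable))
  anova <- lapply(stats::setNames(nm = anova_vars), function(v) {
    conds <- if (v == "navicular_drop_mm")
      c("functional", "forced", "saute") else condition_levels()
    rm_anova_gg(wide(v, conds))
  })
  normality <- lapply(stats::setNames(nm = anova_vars), function(v) {
    conds <- if (v == "navicular_drop_mm")
      c("functional", "forced", "saute") else condition_levels()
    normality_screen(wide(v, conds))
  })

  predictors <- c("hindfoot_eversion", "midfoot_abduction",
                  "forefoot_abduction", "navicular_drop_mm")
  reg_conds <- c("functional", "forced", "saute")
  regression <- lapply(stats::setNames(nm = reg_conds), function(cn) {
    y <- wide("foot_abduction", cn)[, 1]
    X <- vapply(predictors, function(v) wide(v, cn)[, 1],
                numeric(length(y)))
    stepwise_regression(y, X)
  })

  correlations <- NULL
  if (!is.null(knee)) {
    correlations <- do.call(rbind, lapply(c("passive", "active"),
                                          function(ms) {
      k <- knee[knee$measurement == ms, ]
      k <- k[order(k$subject), ]
      do.call(rbind, lapply(reg_conds, function(cn) {
        hv <- values[values$variable == "hindfoot_eversion" &
                       values$condition == cn, ]
        hv <- hv[order(hv$subject), ]
        pr <- pearson_r(k$value, hv$value)
        data.frame(measurement = ms, condition = cn, r = pr$r, p = pr$p,
                   n = pr$n)
      }))
    }))
  }
  structure(list(summary = summary, deltas = deltas, anova = anova,
                 regression = regression, correlations = correlations,
                 normality = normality, n_subjects = n_sub),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", x$n_subjects, "subjects\n")
  for (v in names(x$anova)) {
    a <- x$anova[[v]]
    cat(sprintf("  %-20s F(%d,%d) = %6.2f, GG eps = %.3f, p = %.4g\n",
                v, a$df_num, a$df_den, a$F, a$epsilon_gg, a$p_gg))
  }
  for (cn in names(x$regression)) {
    r <- x$regression[[cn]]
    cat(sprintf("  foot abduction ~ %s [%s]: R2 = %.2f\n",
                if (length(r$selected)) paste(r$selected, collapse = " + ")
                else "(none)", cn, r$r_squared))
  }
  invisible(x)
}

#' Process a full synthetic cohort end to end
#'
#' Runs [run_subject()] on every subject of a [generate_cohort()] result (full
#' marker mode) and assembles the [run_cohort()] report from the recovered —
#' not the generative — values.
#'
#' @param cohort A [generate_cohort()] result with `subjects`.
#' @param ... Passed to [run_subject()].
#' @return List with `report` (a [run_cohort()] result), `values`, `knee`.
#' @export
process_cohort <- function(cohort, ...) {
  if (is.null(cohort$subjects))
    stop("cohort was generated with values_only = TRUE; no marker trials",
         call. = FALSE)
  res <- lapply(seq_along(cohort$subjects), function(s)
    run_subject(cohort$subjects[[s]]$trials, subject = s, ...))
  values <- do.call(rbind, lapply(res, `[[`, "values"))
  knee <- do.call(rbind, lapply(res, `[[`, "knee"))
  list(report = run_cohort(values, knee), values = values, knee = knee)
}
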