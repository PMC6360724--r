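# Study-level measures: navicular drop and arch-stability classes, hallux
# valgus severity classes, per-condition cohort summaries, and the printed
# pairwise condition deltas.

#' Navicular drop
#'
#' Decrease in navicular tuberosity height relative to the natural double-leg
#' upright posture; negative values mean the navicular rose.
#'
#' @param nav_height_condition Navicular height in the condition (mm).
#' @param nav_height_natural Navicular height in natural stance (mm), same
#'   lab vertical axis.
#' @return Drop in mm (natural - condition).
#' @export
navicular_drop <- function(nav_height_condition, nav_height_natural) {
  nav_height_natural - nav_height_condition
}

#' Arch-height stability class from navicular drop
#'
#' Gontijo-style classes: drop < 7 mm = `excellent`, 7-13 mm (closed
#' interval) = `stable`, > 13 mm = `unstable`.
#'
#' @param drop Navicular drop in mm (vectorised).
#' @return Factor with levels excellent/stable/unstable.
#' @export
classify_navicular <- function(drop) {
  stopifnot(all(is.finite(drop)))
  cut(drop, breaks = c(-Inf, 7, 13, Inf), right = FALSE,
      labels = c("excellent", "stable", "unstable")) ->
    out
  # 'from 7 to 13 mm' is closed on both ends: 13 itself is stable
  out[drop == 13] <- "stable"
  out
}

#' Hallux valgus severity class from the first-MTPJ transverse angle
#'
#' Pique-Vidal-style classes: < 15 deg normal, 15-20 mild, 21-39 moderate,
#' >= 40 severe. The printed scheme leaves (20, 21) unassigned; values there
#' map to `mild`.
#'
#' @param angle First-MTPJ transverse-plane angle, degrees (vectorised).
#' @return Factor with levels normal/mild/moderate/severe.
#' @export
classify_hallux_valgus <- function(angle) {
  stopifnot(all(is.finite(angle)))
  cut(angle, breaks = c(-Inf, 15, 21, 40, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Kinematic variables summarised per condition
#' @return Character vector of variable names.
#' @export
kinematic_variables <- function() {
  c("hindfoot_eversion", "midfoot_abduction", "forefoot_abduction",
    "navicular_drop_mm", "mtpj_abduction", "foot_abduction",
    "knee_external_rotation")
}

#' Condition labels used in summaries
#' @return Character vector.
#' @export
condition_levels <- function() c("natural", "functional", "forced", "saute")

#' Summarise per-subject values into a condition table
#'
#' Mean, standard error (sd/sqrt(n)) and 95% CI (mean +/- 1.96 SE, a declared
#' normal-quantile convention) per variable and condition.
#'
#' @param per_subject Data frame with columns `subject`, `condition`,
#'   `variable`, `value`; one row per cell (static conditions already
#'   averaged over repeated trials, sautes over the three demi-plies).
#' @return An object of class `"condition_summary"`: data frame with columns
#'   variable, condition, n, mean, se, ci_lo, ci_hi.
#' @export
summarise_conditions <- function(per_subject) {
  need <- c("subject", "condition", "variable", "value")
  if (!all(need %in% names(per_subject)))
    stop("per_subject must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(value ~ variable + condition, per_subject,
                          function(v) c(n = length(v), mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  out <- data.frame(variable = agg$variable, condition = agg$condition,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    se = agg$value[, "se"])
  if (any(out$n < 2))
    stop("completeness error: need at least 2 subjects per cell", call. = FALSE)
  counts <- table(per_subject$variable, per_subject$condition)
  if (length(unique(counts[counts > 0])) > 1)
    warning("unbalanced condition table: cells differ in subject counts")
  out$ci_lo <- out$mean - 1.96 * out$se
  out$ci_hi <- out$mean + 1.96 * out$se
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Pairwise condition mean differences (printed-delta layout)
#'
#' Reports, per variable, the functional-natural, forced-natural,
#' forced-functional and saute-functional mean differences, rounded to one
#' decimal for angles and to the nearest millimetre for navicular drop.
#'
#' @param summary A [summarise_conditions()] result or a data frame with
#'   columns `variable`, `condition`, `mean`.
#' @return Data frame with columns variable, contrast, delta, delta_rounded.
#' @export
table2_deltas <- function(summary) {
  contrasts <- list(functional_minus_natural = c("functional", "natural"),
                    forced_minus_natural = c("forced", "natural"),
                    forced_minus_functional = c("forced", "functional"),
                    saute_minus_functional = c("saute", "functional"))
  cell <- function(v, c) {
    m <- summary$mean[summary$variable == v & summary$condition == c]
    if (length(m) != 1L) NA_real_ else m
  }
  rows <- do.call(rbind, lapply(unique(as.character(summary$variable)),
                                function(v) {
    do.call(rbind, lapply(names(contrasts), function(ct) {
      d <- cell(v, contrasts[[ct]][1]) - cell(v, contrasts[[ct]][2])
      data.frame(variable = v, contrast = ct, delta = d)
    }))
  }))
  rows$delta_rounded <- ifelse(grepl("_mm$", rows$variable),
                               round(rows$delta), round(rows$delta, 1))
  rows[!is.na(rows$delta), , drop = FALSE]
}

#' Published per-condition cohort means
#'
#' Reads the per-condition mean table shipped with the package (the published
#' cohort means for each kinematic variable, with the natural-stance
#' navicular-drop baseline fixed at 0 by definition).
#'
#' @return Data frame with columns variable, condition, mean.
#' @export
table2_means_fixture <- function() {
  path <- system.file("extdata", "table2_means.tsv", package = "turnoutfoot",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
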