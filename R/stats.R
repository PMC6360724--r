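# Inferential statistics of the study, from first principles: one-way
# repeated-measures ANOVA with Greenhouse-Geisser correction and Bonferroni
# pairwise comparisons; stepwise (forward entry, backward removal) multiple
# linear regression; Pearson correlation with t-based p-values.

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way within-subjects ANOVA on a complete subjects x conditions matrix.
#' The Greenhouse-Geisser epsilon is computed from the double-centred
#' condition covariance, `eps = (tr S)^2 / ((k-1) tr S^2)`, and the p-value
#' taken from the F distribution at epsilon-deflated degrees of freedom.
#' Pairwise comparisons are paired t-tests with Bonferroni adjustment over
#' all k(k-1)/2 pairs.
#'
#' @param data Numeric matrix, subjects (rows) x conditions (columns),
#'   no missing cells; column names label the conditions.
#' @return An object of class `"rm_anova"`: `F`, `df_num`, `df_den`
#'   (uncorrected), `epsilon_gg`, `p_uncorrected`, `p_gg`, `pairwise`
#'   (data frame with raw and Bonferroni-adjusted p), `means`.
#' @export
rm_anova_gg <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("completeness error: missing cells", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (k < 2L) stop("input error: need at least 2 conditions", call. = FALSE)
  if (n < 2L) stop("input error: need at least 2 subjects", call. = FALSE)
  grand <- mean(data)
  col_m <- colMeans(data); row_m <- rowMeans(data)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  F <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(data)
  C <- diag(k) - matrix(1 / k, k, k)
  St <- C %*% S %*% C
  eps <- sum(diag(St))^2 / (df1 * sum(St * St))
  eps <- min(1, max(1 / df1, eps))
  p_unc <- stats::pf(F, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  cn <- if (is.null(colnames(data))) paste0("c", seq_len(k)) else colnames(data)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- data[, a] - data[, b]
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(abs(tt), n - 1L, lower.tail = FALSE)
    data.frame(a = cn[a], b = cn[b], mean_diff = mean(d), t = tt,
               p_raw = p, p_bonferroni = min(1, m * p))
  }))
  structure(list(F = F, df_num = df1, df_den = df2, epsilon_gg = eps,
                 p_uncorrected = p_unc, p_gg = p_gg, pairwise = pw,
                 means = stats::setNames(col_m, cn), n = n),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "<rm_anova> F(%d, %d) = %.2f, GG eps = %.3f, p(GG) = %.4g (n = %d)\n",
    x$df_num, x$df_den, x$F, x$epsilon_gg, x$p_gg, x$n))
  invisible(x)
}

.ols_fit <- function(y, X) {
  # X without intercept column; returns per-coefficient t p-values, R2, F
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi))
    stop("conditioning error: rank-deficient predictor matrix", call. = FALSE)
  coefs <- qr.coef(qrx, y)
  res <- y - Xi %*% coefs
  p <- ncol(Xi)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(0, diag(XtXinv)) * sigma2)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  Fov <- if (p > 1) ((tss - rss) / (p - 1)) / sigma2 else NA_real_
  list(coefficients = coefs, se = se, t = tval, p = pval, r_squared = r2,
       adj_r_squared = adj, F = Fov, df_num = p - 1L, df_den = n - p,
       rss = rss)
}

#' Stepwise multiple linear regression
#'
#' SPSS-style stepwise selection: forward entry of the candidate with the
#' smallest partial-F (equivalently t) p-value when it is at or below
#' `entry_p`, followed after each entry by backward removal of any retained
#' predictor whose p-value exceeds `removal_p`; terminates when no excluded
#' predictor meets entry and no included predictor meets removal.
#'
#' @param y Response vector.
#' @param X Numeric predictor matrix with column names.
#' @param entry_p Entry threshold (default 0.05).
#' @param removal_p Removal threshold (default 0.10).
#' @return An object of class `"stepwise_fit"`: `selected` (in entry order),
#'   `coefficients`, `r_squared`, `adj_r_squared`, `F`, `df_num`, `df_den`,
#'   `p_overall`.
#' @export
stepwise_regression <- function(y, X, entry_p = 0.05, removal_p = 0.10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) <= ncol(X) + 1L)
    stop("need n > number of candidates + 1", call. = FALSE)
  selected <- character(0)
  repeat {
    changed <- FALSE
    candidates <- setdiff(colnames(X), selected)
    if (length(candidates)) {
      entry <- vapply(candidates, function(v) {
        fit <- .ols_fit(y, X[, c(selected, v), drop = FALSE])
        fit$p[length(fit$p)]
      }, numeric(1))
      best <- names(which.min(entry))
      if (entry[best] <= entry_p) {
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    while (length(selected)) {
      fit <- .ols_fit(y, X[, selected, drop = FALSE])
      pv <- fit$p[-1]                      # drop intercept
      worst <- which.max(pv)
      if (pv[worst] > removal_p) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(selected)) {
    return(structure(list(selected = character(0),
                          coefficients = c(`(Intercept)` = mean(y)),
                          r_squared = 0, adj_r_squared = 0,
                          F = NA_real_, df_num = 0L,
                          df_den = length(y) - 1L, p_overall = NA_real_),
                     class = "stepwise_fit"))
  }
  fit <- .ols_fit(y, X[, selected, drop = FALSE])
  structure(list(selected = selected, coefficients = fit$coefficients,
                 r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
                 F = fit$F, df_num = fit$df_num, df_den = fit$df_den,
                 p_overall = stats::pf(fit$F, fit$df_num, fit$df_den,
                                       lower.tail = FALSE)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  if (!length(x$selected)) {
    cat("<stepwise_fit> empty model\n")
  } else {
    cat(sprintf(
      "<stepwise_fit> %s | R2 = %.3f (adj %.3f), F(%d, %d) = %.2f, p = %.4g\n",
      paste(x$selected, collapse = " + "), x$r_squared, x$adj_r_squared,
      x$df_num, x$df_den, x$F, x$p_overall))
  }
  invisible(x)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; two-sided p from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#'
#' @param x,y Numeric vectors, length >= 3, non-zero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("input error: length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("input error: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("input error: zero variance", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Shapiro-Wilk normality screen for a condition table
#'
#' Reported alongside the parametric tests (never gating them).
#'
#' @param data Subjects x conditions matrix.
#' @return Data frame with condition, W, p.
#' @export
normality_screen <- function(data) {
  data <- as.matrix(data)
  cn <- if (is.null(colnames(data))) paste0("c", seq_len(ncol(data))) else colnames(data)
  do.call(rbind, lapply(seq_len(ncol(data)), function(j) {
    sw <- stats::shapiro.test(data[, j])
    data.frame(condition = cn[j], W = unname(sw$statistic),
               p = sw$p.value)
  }))
}
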