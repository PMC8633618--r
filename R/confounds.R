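#' Mean amplitude over a time window and channel subset
#'
#' Extracts, from a per-subject condition average, the mean amplitude
#' over the channel x time submatrix defined by a window (ms) and a
#' channel set - the scalar used by the ECG-artifact confound
#' analyses.
#'
#' @param average a `hep_average`.
#' @param window_ms time window in ms (inclusive).
#' @param channels channel labels to average over; defaults to all.
#' @return scalar mean amplitude (uV).
#' @export
window_mean_amplitude <- function(average, window_ms, channels = NULL) {
  stopifnot(inherits(average, "hep_average"))
  channels <- channels %||% average$labels
  if (length(channels) == 0) stop("empty channel set")
  ch <- match(channels, average$labels)
  if (anyNA(ch)) stop("unknown channel(s): ",
                      paste(channels[is.na(ch)], collapse = ", "))
  sel <- average$times_ms >= window_ms[1] & average$times_ms <= window_ms[2]
  if (!any(sel)) stop("window contains no samples")
  mean(average$mean[ch, sel])
}

#' Compare paired per-subject scalars between conditions
#'
#' Shapiro-Wilk on the paired differences (alpha = 0.05) gates the
#' test: a paired t test with Cohen's d when normality is not rejected,
#' otherwise an exact Wilcoxon signed-rank test (exact null for
#' n <= 25, zero differences dropped) with a rank-biserial effect
#' size.
#'
#' @param x,y paired per-subject values (n >= 3).
#' @return list of class `condition_contrast`: `test`, `statistic`,
#'   `df` (t only), `p`, `effect_size`, `normality_p`, `n`.
#' @export
compare_conditions_scalar <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(test = "degenerate", statistic = 0, df = NA,
                          p = 1, effect_size = 0, normality_p = NA, n = n),
                     class = "condition_contrast"))
  }
  sw_p <- stats::shapiro.test(d)$p.value
  if (sw_p >= 0.05) {
    tt <- stats::t.test(x, y, paired = TRUE)
    out <- list(test = "paired t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                effect_size = mean(d) / stats::sd(d),
                effect_size_name = "Cohen's d",
                normality_p = sw_p, n = n)
  } else {
    dz <- d[d != 0]
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = length(dz) <= 25))
    nz <- length(dz)
    v <- unname(wt$statistic)
    rb <- 2 * v / (nz * (nz + 1) / 2) - 1  # rank-biserial correlation
    out <- list(test = "wilcoxon signed-rank", statistic = v, df = NA,
                p = wt$p.value, effect_size = rb,
                effect_size_name = "rank-biserial r",
                normality_p = sw_p, n = n)
  }
  structure(out, class = "condition_contrast")
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s = %.3f, n = %d)\n",
              x$test, x$statistic, x$p,
              x$effect_size_name %||% "effect", x$effect_size, x$n))
  invisible(x)
}

#' Repeated-measures ANCOVA for a two-level within-subject factor
#'
#' Tests the condition effect on paired per-subject means with a
#' subject-level covariate (here: the phasic minus tonic ECG amplitude
#' contrast). With a two-level factor the model reduces to a
#' regression of the difference scores on the centred covariate: the
#' condition main effect is the intercept test, F(1, n-2), evaluated
#' at the mean covariate; the covariate effect is the slope test. With
#' an uninformative (constant) covariate the model collapses to the
#' paired t test and the condition F equals its square, on F(1, n-1).
#'
#' @param hep_a,hep_b per-subject window means for the two conditions.
#' @param covariate per-subject covariate (e.g. ECG amplitude
#'   contrast).
#' @return list of class `rm_ancova`: condition `F`, `df`, `p`,
#'   `partial_eta_sq`, plus the covariate effect.
#' @export
rm_ancova_condition <- function(hep_a, hep_b, covariate) {
  n <- length(hep_a)
  if (length(hep_b) != n || length(covariate) != n) {
    stop("all inputs must have equal length")
  }
  if (n < 4) stop("need at least 4 subjects")
  d <- hep_a - hep_b
  if (stats::sd(d) == 0) {
    # identical conditions: no effect to test
    return(structure(
      list(F = 0, df = c(1, n - 1), p = 1, partial_eta_sq = 0,
           covariate = list(F = NA_real_, df = c(NA, NA), p = NA_real_,
                            partial_eta_sq = NA_real_),
           n = n, covariate_constant = TRUE),
      class = "rm_ancova"))
  }
  const_cov <- stats::sd(covariate) == 0
  if (const_cov) {
    fit <- stats::lm(d ~ 1)
    sm <- summary(fit)$coefficients
    f_cond <- sm[1, "t value"]^2
    df2 <- n - 1
    cov_eff <- list(F = NA_real_, df = c(NA, NA), p = NA_real_,
                    partial_eta_sq = NA_real_)
  } else {
    cc <- covariate - mean(covariate)
    fit <- stats::lm(d ~ cc)
    sm <- summary(fit)$coefficients
    f_cond <- sm[1, "t value"]^2
    df2 <- n - 2
    f_cov <- sm[2, "t value"]^2
    cov_eff <- list(F = f_cov, df = c(1, df2),
                    p = stats::pf(f_cov, 1, df2, lower.tail = FALSE),
                    partial_eta_sq = f_cov / (f_cov + df2))
  }
  structure(
    list(F = f_cond, df = c(1, df2),
         p = stats::pf(f_cond, 1, df2, lower.tail = FALSE),
         partial_eta_sq = f_cond / (f_cond + df2),
         covariate = cov_eff, n = n,
         covariate_constant = const_cov),
    class = "rm_ancova")
}

#' @export
print.rm_ancova <- function(x, ...) {
  cat(sprintf("Condition effect: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta_sq))
  if (!x$covariate_constant) {
    cat(sprintf("Covariate effect: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                x$covariate$df[1], x$covariate$df[2], x$covariate$F,
                x$covariate$p, x$covariate$partial_eta_sq))
  } else {
    cat("Covariate constant: covariate effect undefined\n")
  }
  invisible(x)
}

#' Pearson correlation between condition contrasts
#'
#' Correlates the per-subject HEP amplitude contrast with the ECG
#' amplitude contrast (two-tailed).
#'
#' @param hep_contrast,ecg_contrast per-subject contrast vectors
#'   (n >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_contrast_correlation <- function(hep_contrast, ecg_contrast) {
  n <- length(hep_contrast)
  if (length(ecg_contrast) != n) stop("contrast vectors must be paired")
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(hep_contrast) == 0 || stats::sd(ecg_contrast) == 0) {
    stop("correlation undefined: zero variance in a contrast vector")
  }
  ct <- stats::cor.test(hep_contrast, ecg_contrast)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
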