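# Instrument-agreement statistics for paired measurements from two systems
# (e.g. a video instrument vs a linear position transducer criterion).

icc_label <- function(icc) {
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good" else "excellent"
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation from the two-way ANOVA decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `n`
#' subjects (rows) and `k = 2` raters, where MSR, MSC and MSE are the row,
#' column and residual mean squares. The 95% confidence interval uses the
#' standard F-based method (McGraw & Wong), and the estimate is labelled
#' poor (<0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (>0.9).
#'
#' @param a,b paired measurements from the two systems.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci` (length 2), `label` and the mean squares.
#' @export
icc_2_1 <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("icc_2_1: need at least 3 paired repetitions")
  gm <- mean(x)
  if (sum((x - gm)^2) < 1e-300)
    stop("icc_2_1: zero total variance, ICC undefined")
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  # F-based CI (McGraw & Wong 1996, case 2A single measures)
  alpha <- 1 - conf
  aa <- k * icc / (n * (1 - icc))
  bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (aa * MSC + bb * MSE)^2 /
    ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- qf(1 - alpha / 2, n - 1, v)
  F2 <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  list(icc = icc, ci = c(lower, upper), label = icc_label(icc),
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k)
}

#' Cronbach's alpha for two items
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with `k = 2` and
#' `var_total` the variance of the item sums. Negative values are possible
#' (anti-correlated items) and returned as-is.
#'
#' @param a,b paired measurements.
#' @return alpha.
#' @export
cronbach_alpha <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  vt <- var(a + b)
  if (vt < 1e-300) stop("cronbach_alpha: zero total variance")
  2 * (1 - (var(a) + var(b)) / vt)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` against pair means: systematic bias (mean difference
#' with paired-t confidence interval and p value), 95% limits of agreement
#' `bias +/- 1.96 SD` of the differences, and an OLS regression of the
#' differences on the means whose `r^2 > 0.1` flags proportional bias.
#'
#' @param a,b paired measurements (`a` the practical instrument, `b` the
#'   criterion).
#' @param conf confidence level.
#' @return list of class `bland_altman`.
#' @export
bland_altman <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("bland_altman: need at least 3 pairs")
  d <- a - b; m <- (a + b) / 2
  bias <- mean(d); sd_d <- sd(d)
  z <- qnorm(0.975)
  loa <- c(low = bias - z * sd_d, high = bias + z * sd_d)
  if (sd_d > 1e-10 * max(1, abs(bias))) {
    tt <- t.test(d, conf.level = conf)
    bias_ci <- as.numeric(tt$conf.int); p_value <- tt$p.value
  } else {
    bias_ci <- c(bias, bias); p_value <- NA_real_  # constant differences
  }
  if (var(m) < 1e-300) {
    reg <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
    prop <- NA
  } else {
    slope <- cov(m, d) / var(m)
    intercept <- bias - slope * mean(m)
    r2 <- if (var(d) < 1e-20 * max(1, bias^2)) 0 else cor(m, d)^2
    reg <- list(slope = slope, intercept = intercept, r2 = r2)
    prop <- isTRUE(r2 > 0.1)
  }
  structure(list(bias = bias, sd_diff = sd_d, loa_low = unname(loa["low"]),
                 loa_high = unname(loa["high"]),
                 bias_ci = bias_ci, p_value = p_value,
                 regression = reg, proportional_bias = prop,
                 n = n, means = m, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g [%.4g, %.4g], LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high, x$n))
  if (!is.na(x$proportional_bias))
    cat(sprintf(" proportional bias: %s (r2 = %.3f)\n",
                ifelse(x$proportional_bias, "yes", "no"), x$regression$r2))
  invisible(x)
}

#' Smallest worthwhile change, typical error and usefulness ratio
#'
#' The smallest worthwhile change (SWC) is `swc_fraction` (default 0.2,
#' standardization) of the between-subject standard deviation of the subject
#' means. The typical error of measurement (SEM) is, by default, the
#' difference-score convention `SD(a - b) / sqrt(2)`; `sem_method = "anova"`
#' instead uses the root residual mean square of the two-way ICC
#' decomposition. The usefulness of the instrument is the SWC/SEM ratio:
#' good (>1), satisfactory (~1) or marginal (<1).
#'
#' @param a,b paired measurements.
#' @param subject subject identifier per pair (>= 2 distinct subjects).
#' @param swc_fraction fraction of the between-subject SD (default 0.2).
#' @param sem_method `"difference"` (default) or `"anova"`.
#' @return list with `swc`, `sem`, `ratio`, `label`.
#' @export
swc_sem_usefulness <- function(a, b, subject,
                               swc_fraction = 0.2,
                               sem_method = c("difference", "anova")) {
  sem_method <- match.arg(sem_method)
  stopifnot(length(a) == length(b), length(subject) == length(a))
  subject <- as.factor(subject)
  if (nlevels(subject) < 2)
    stop("swc_sem_usefulness: SWC undefined with a single subject")
  subj_means <- tapply((a + b) / 2, subject, mean)
  swc <- swc_fraction * sd(subj_means)
  sem <- if (sem_method == "difference") sd(a - b) / sqrt(2)
         else sqrt(icc_2_1(a, b)$ms["MSE"])
  res <- usefulness_ratio(swc, unname(sem))
  c(list(swc = swc, sem = unname(sem), method = sem_method), res)
}

#' SWC/SEM usefulness ratio
#'
#' @param swc smallest worthwhile change.
#' @param sem typical error of measurement, same units.
#' @return list with `ratio` and qualitative `label` (good > 1,
#'   satisfactory at 1, marginal < 1).
#' @export
usefulness_ratio <- function(swc, sem) {
  stopifnot(sem > 0)
  ratio <- swc / sem
  label <- if (abs(ratio - 1) < 1e-9) "satisfactory"
           else if (ratio > 1) "good" else "marginal"
  list(ratio = ratio, label = label)
}

see_label <- function(std) {
  if (std < 0.1) "trivial" else if (std < 0.3) "small"
  else if (std < 0.6) "moderate" else if (std < 1.0) "large"
  else if (std < 2.0) "very large" else "extremely large"
}

r_label <- function(r) {
  r <- abs(r)
  if (r < 0.1) "trivial" else if (r < 0.3) "small" else if (r < 0.5) "moderate"
  else if (r < 0.7) "high" else if (r < 0.9) "very high" else "practically perfect"
}

#' Pearson correlation with standard error of estimate
#'
#' Concurrent validity of the practical instrument against the criterion:
#' Pearson's r with a Fisher-z confidence interval, and the standard error
#' of estimate (residual SD, df = n - 2) of the OLS regression of `a` on
#' `b`, both raw and standardized by `SD(a)`. The standardized SEE is
#' labelled with half the thresholds of the modified Cohen scale (trivial
#' < 0.1, small 0.1-0.3, moderate 0.3-0.6, large 0.6-1.0, very large
#' 1.0-2.0, extremely large > 2.0).
#'
#' @param a,b paired measurements (`a` regressed on `b`).
#' @param conf confidence level.
#' @return list with `r`, `r_ci`, `r_label`, `see`, `see_standardized`,
#'   `see_label`.
#' @export
pearson_with_see <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("pearson_with_see: need at least 3 pairs")
  if (var(a) < 1e-300 || var(b) < 1e-300)
    stop("pearson_with_see: zero variance in a column")
  r <- cor(a, b)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(1 - (1 - conf) / 2) * se)
  fit <- lm(a ~ b)
  see <- sqrt(sum(fit$residuals^2) / (n - 2))
  std <- see / sd(a)
  list(r = r, r_ci = ci, r_label = r_label(r),
       see = see, see_standardized = std, see_label = see_label(std))
}

#' Full agreement report for one variable
#'
#' Assembles the validation statistics used for instrument comparison:
#' ICC(2,1) with CI, Cronbach's alpha, mean difference with paired-t CI and
#' p, SWC, SEM and their ratio, Bland-Altman bias and limits with
#' proportional-bias regression, and Pearson r with SEE.
#'
#' @param a,b paired per-repetition values from the two systems.
#' @param subject subject identifier per repetition.
#' @param variable variable name for printing (e.g. "velocity (m/s)").
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(a, b, subject, variable = "") {
  ba <- bland_altman(a, b)
  structure(list(variable = variable,
                 icc = icc_2_1(a, b),
                 cronbach_alpha = cronbach_alpha(a, b),
                 bland_altman = ba,
                 usefulness = swc_sem_usefulness(a, b, subject),
                 validity = pearson_with_see(a, b),
                 n = length(a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report%s (n = %d pairs)\n",
              ifelse(nzchar(x$variable), paste0(": ", x$variable), ""), x$n))
  cat(sprintf(" ICC(2,1)    %.3f (%.3f-%.3f) [%s]\n", x$icc$icc,
              x$icc$ci[1], x$icc$ci[2], x$icc$label))
  cat(sprintf(" Cronbach a  %.3f\n", x$cronbach_alpha))
  cat(sprintf(" Bias        %.4g (%.4g-%.4g), p = %.3g\n", x$bland_altman$bias,
              x$bland_altman$bias_ci[1], x$bland_altman$bias_ci[2],
              x$bland_altman$p_value))
  cat(sprintf(" LoA         [%.4g, %.4g]\n", x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  cat(sprintf(" SWC %.4g / SEM %.4g = %.2f [%s]\n", x$usefulness$swc,
              x$usefulness$sem, x$usefulness$ratio, x$usefulness$label))
  cat(sprintf(" Pearson r   %.3f (%.3f-%.3f) [%s], SEE %.4g (std %.3f, %s)\n",
              x$validity$r, x$validity$r_ci[1], x$validity$r_ci[2],
              x$validity$r_label, x$validity$see,
              x$validity$see_standardized, x$validity$see_label))
  invisible(x)
}

#' Write an agreement report to JSON
#' @param report [agreement_report()] output.
#' @param path output path.
#' @export
write_agreement_report <- function(report, path) {
  o <- report
  o$bland_altman$means <- NULL; o$bland_altman$diffs <- NULL
  jsonlite::write_json(lapply(unclass(o), function(e)
    if (is.list(e)) unclass(e) else e), path,
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
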