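# Pre-post inference: normality-gated paired test selection, effect sizes,
# descriptives, and design-stage power / sample-size from the noncentral t.

#' Normality gate for paired differences
#'
#' Shapiro-Wilk on the paired differences: `p >= alpha` routes to the
#' parametric branch (paired t), otherwise to the nonparametric branch
#' (Wilcoxon signed-rank). Constant differences are degenerate and routed to
#' the nonparametric branch with a `zero_variance` flag. The protocol also
#' prescribes visual histogram inspection; that step is out of scope and a
#' flag is attached instead.
#'
#' @param differences Numeric vector of paired differences, n >= 3.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`, with attributes
#'   `shapiro_p`, `zero_variance` and `visual_inspection` (always
#'   `"not performed"`).
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  if (length(differences) < 3L) stop("need n >= 3 paired differences", call. = FALSE)
  if (anyNA(differences)) stop("differences must be complete", call. = FALSE)
  if (stats::sd(differences) == 0) {
    return(structure("nonparametric", shapiro_p = NA_real_,
                     zero_variance = TRUE, visual_inspection = "not performed"))
  }
  p <- stats::shapiro.test(differences)$p.value
  structure(if (p >= alpha) "parametric" else "nonparametric",
            shapiro_p = p, zero_variance = FALSE,
            visual_inspection = "not performed")
}

# Wilcoxon signed-rank with Pratt handling of zero differences: zeros are
# ranked with the rest, then their ranks are dropped from both sums; normal
# approximation with tie correction and continuity correction.
wilcoxon_pratt <- function(d) {
  n_all <- length(d)
  nz <- sum(d == 0)
  if (nz == n_all) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  mu <- (n_all * (n_all + 1) / 2 - nz * (nz + 1) / 2) / 2
  ties <- table(r[d != 0])
  sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
               nz * (nz + 1) * (2 * nz + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(list(statistic = v_pos, p = 1))
  z <- (v_pos - mu - sign(v_pos - mu) * 0.5) / sqrt(sigma2)
  list(statistic = v_pos, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Paired pre-post comparison with normality-gated test selection
#'
#' Runs [normality_gate()] on the paired differences `m0 - m1`, then either
#' a paired t-test with Cohen's `d = t / sqrt(n)` and mean +- SD
#' descriptives, or a Wilcoxon signed-rank test (exact where no zero
#' differences occur, Pratt zero-handling otherwise) with median +- IQR
#' descriptives. The reported difference is the mean (parametric) or median
#' (nonparametric) of the paired differences.
#'
#' @param m0,m1 Paired numeric samples of equal length (n >= 3): baseline
#'   and post measurements.
#' @param outcome Outcome label carried into the result.
#' @param alpha Gate level for the Shapiro-Wilk test.
#' @return One-row data frame of class `scap_prepost`: `outcome`, `n`,
#'   `test`, `m0_center`, `m0_spread`, `m1_center`, `m1_spread`,
#'   `statistic`, `p`, `effect_d` (NA for the nonparametric branch),
#'   `difference`, `shapiro_p`.
#' @export
paired_compare <- function(m0, m1, outcome = "", alpha = 0.05) {
  if (length(m0) != length(m1)) stop("`m0` and `m1` must be paired (equal length)", call. = FALSE)
  n <- length(m0)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  d <- m0 - m1
  branch <- normality_gate(d, alpha = alpha)
  if (branch == "parametric") {
    tt <- stats::t.test(m0, m1, paired = TRUE)
    stat <- unname(tt$statistic)
    res <- data.frame(
      outcome = outcome, n = n, test = "paired_t",
      m0_center = mean(m0), m0_spread = stats::sd(m0),
      m1_center = mean(m1), m1_spread = stats::sd(m1),
      statistic = stat, p = tt$p.value,
      effect_d = cohens_d_from_t(stat, n), difference = mean(d),
      shapiro_p = attr(branch, "shapiro_p"))
  } else {
    if (any(d == 0)) {
      w <- wilcoxon_pratt(d)
    } else {
      wt <- stats::wilcox.test(m0, m1, paired = TRUE)
      w <- list(statistic = unname(wt$statistic), p = wt$p.value)
    }
    iqr <- function(x) stats::IQR(x, type = 7)
    res <- data.frame(
      outcome = outcome, n = n, test = "wilcoxon",
      m0_center = stats::median(m0), m0_spread = iqr(m0),
      m1_center = stats::median(m1), m1_spread = iqr(m1),
      statistic = w$statistic, p = w$p, effect_d = NA_real_,
      difference = stats::median(d),
      shapiro_p = attr(branch, "shapiro_p"))
  }
  class(res) <- c("scap_prepost", "data.frame")
  res
}

#' Cohen's d from a paired t statistic
#'
#' For a paired design, `d = t / sqrt(n)` (the standardized mean of the
#' paired differences).
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return Cohen's d (sign follows `t`).
#' @export
cohens_d_from_t <- function(t, n) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  t / sqrt(n)
}

#' Effect size from an MCID and a standard deviation
#'
#' Design-stage standardized effect `d = MCID / SD`, the smallest clinically
#' important difference expressed in SD units.
#'
#' @param mcid Minimal clinically important difference, outcome units.
#' @param sd Standard deviation of the outcome (> 0).
#' @return Cohen's d.
#' @export
effect_size_from_mcid <- function(mcid, sd) {
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  mcid / sd
}

#' Interpretation band of an effect size
#'
#' Magnitudes below 0.2 are small, 0.8 and above large, values between
#' moderate (cut-points at 0.2 and 0.8).
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector.
#' @export
effect_size_band <- function(d) {
  as.character(cut(abs(d), c(-Inf, 0.2, 0.8, Inf),
                   labels = c("small", "moderate", "large"), right = FALSE))
}

#' Power of a paired t-test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param n Number of pairs.
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, d, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  ncp <- d * sqrt(n); df <- n - 1
  if (tails == "one") {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    q <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(q, df, ncp) + stats::pt(-q, df, ncp)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest integer n such that the paired t-test attains the requested
#' power at level `alpha` for standardized effect `d`, by direct search over
#' the noncentral-t power curve. With `d = 0.63737`, `alpha = 0.05`
#' one-tailed and power 0.80 this yields n = 17.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @param n_max Search bound.
#' @return Required number of pairs (integer).
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 tails = c("one", "two"), n_max = 10000L) {
  tails <- match.arg(tails)
  if (!is.finite(d) || d <= 0) stop("`d` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  }
  for (n in 2:n_max) {
    if (paired_t_power(n, d, alpha, tails) >= power) return(as.integer(n))
  }
  stop("no n <= n_max reaches the requested power", call. = FALSE)
}

#' Descriptive summary for one branch
#'
#' Mean +- SD for the parametric branch, median +- IQR (type-7 quantiles)
#' for the nonparametric branch.
#'
#' @param x Non-empty numeric vector (n >= 2 for the parametric branch).
#' @param branch `"parametric"` or `"nonparametric"`.
#' @return Named numeric: `center`, `spread`.
#' @export
summarize_outcome <- function(x, branch = c("parametric", "nonparametric")) {
  branch <- match.arg(branch)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (branch == "parametric") {
    if (length(x) < 2L) stop("SD undefined for a single value", call. = FALSE)
    c(center = mean(x), spread = stats::sd(x))
  } else {
    c(center = stats::median(x), spread = stats::IQR(x, type = 7))
  }
}

#' Pre-post comparison table for many outcomes
#'
#' @param m0,m1 Data frames/matrices with one column per outcome and one row
#'   per subject (paired across the two).
#' @param adjust P-value adjustment: `"none"` (default, mirroring unadjusted
#'   reporting) or `"holm"`.
#' @param alpha Gate level.
#' @return Data frame with one [paired_compare()] row per outcome; if
#'   `adjust != "none"` an extra `p_adj` column.
#' @export
prepost_table <- function(m0, m1, adjust = c("none", "holm"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(identical(colnames(m0), colnames(m1)))
  if (nrow(m0) < 3L) stop("need at least 3 subjects for pre-post inference", call. = FALSE)
  rows <- lapply(colnames(m0), function(oc) {
    paired_compare(m0[[oc]], m1[[oc]], outcome = oc, alpha = alpha)
  })
  res <- do.call(rbind, rows)
  if (adjust == "holm") res$p_adj <- stats::p.adjust(res$p, method = "holm")
  rownames(res) <- NULL
  res
}
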