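# Intra-rater test-retest reliability: ICC(2,k) with a 95% CI, standard
# error of measurement, minimal detectable change, and interpretation bands.

#' Average-measures absolute-agreement intraclass correlation, ICC(2,k)
#'
#' Computed from the two-way ANOVA mean squares of an n-subjects-by-k
#' measurements matrix:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-measurement
#' and \eqn{MS_E} the residual mean square. The 95% CI follows the standard
#' F-based interval (single-measures bounds with a Satterthwaite df,
#' stepped up to average measures by the Spearman-Brown relation). Note the
#' two-way random and two-way mixed average-measure absolute-agreement
#' coefficients coincide numerically in this formula. Negative estimates
#' (no subject variance) are admissible and returned without error; on
#' pathological matrices where the residual mean square dwarfs the
#' between-subject mean square the raw estimator's denominator can turn
#' negative and the value escapes `[0, 1]` -- it is returned untruncated,
#' exactly as the ANOVA decomposition defines it.
#'
#' @param ratings Numeric matrix, subjects in rows (n >= 2), repeated
#'   measurements in columns (k >= 2), no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `icc`, `ci95` (length-2), `ms` (the three mean squares),
#'   `n`, `k`.
#' @export
icc_2k <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 measurements", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((x - grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- (ss_t - ss_r - ss_c) / ((n - 1) * (k - 1))
  icc_k <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)

  # F-based interval for the single-measures coefficient, then Spearman-Brown
  alpha <- 1 - conf_level
  icc_1 <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v_num <- (a * ms_c + b * ms_e)^2
  v_den <- (a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1))
  ci <- c(NA_real_, NA_real_)
  if (is.finite(v_num) && is.finite(v_den) && v_den > 0) {
    v <- v_num / v_den
    # qf can emit accuracy warnings at the extreme Satterthwaite df that
    # pathological matrices produce; the interval is approximate by design
    f_l <- suppressWarnings(stats::qf(1 - alpha / 2, n - 1, v))
    f_u <- suppressWarnings(stats::qf(1 - alpha / 2, v, n - 1))
    l1 <- n * (ms_r - f_l * ms_e) /
      (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
    u1 <- n * (f_u * ms_r - ms_e) /
      (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
    sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
    ci <- c(sb(l1), sb(u1))
  }
  list(icc = icc_k, ci95 = ci, ms = c(rows = ms_r, cols = ms_c, error = ms_e),
       n = n, k = k)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`. A negative ICC is permitted (the square root
#' is then of a value above one, inflating the SEM accordingly).
#'
#' @param sd Between-subject standard deviation in outcome units (>= 0).
#' @param icc Intraclass correlation (<= 1).
#' @return SEM in outcome units.
#' @export
sem_measurement <- function(sd, icc) {
  if (!is.finite(sd) || sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (!is.finite(icc) || icc > 1) stop("`icc` must be <= 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = SEM * sqrt(2) * 1.96` (constant 2.77185...): the smallest change
#' exceeding measurement error with 95% confidence in a test-retest design.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return MDC95 in outcome units.
#' @export
mdc95 <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) stop("`sem` must be >= 0", call. = FALSE)
  sem * sqrt(2) * 1.96
}

#' Interpretation band of an ICC value
#'
#' Vocabulary: little (< 0.16), low (0.16-0.49), moderate (0.50-0.69), high
#' (0.70-0.89), very high (>= 0.90). The published cut-points leave the gaps
#' between bands undefined; the convention here is
#' `little < 0.16 <= low < 0.50 <= moderate < 0.70 <= high < 0.90 <= very high`.
#'
#' @param icc Numeric vector of finite ICC values.
#' @return Character vector of bands.
#' @export
reliability_band <- function(icc) {
  if (any(!is.finite(icc))) stop("`icc` must be finite", call. = FALSE)
  cut_pts <- c(-Inf, 0.16, 0.50, 0.70, 0.90, Inf)
  bands <- c("little", "low", "moderate", "high", "very high")
  as.character(cut(icc, cut_pts, labels = bands, right = FALSE))
}

#' Test-retest reliability table for a set of outcomes
#'
#' One row per outcome mirroring the standard reporting layout: ICC(2,k),
#' its 95% CI, SEM, MDC95 and the interpretation band. The SD entering the
#' SEM is, by default, the between-subject SD of the first measurement
#' column (`sd_source = "session1"`); `"pooled"` uses the SD of all cells.
#'
#' @param data Long data frame with columns `outcome`, `subject`,
#'   `measurement` (repetition id) and `value`; complete crossing required.
#' @param sd_source `"session1"` or `"pooled"`.
#' @return Data frame: `outcome`, `icc`, `ci_lower`, `ci_upper`, `sem`,
#'   `mdc95`, `band`.
#' @export
reliability_table <- function(data, sd_source = c("session1", "pooled")) {
  sd_source <- match.arg(sd_source)
  stopifnot(all(c("outcome", "subject", "measurement", "value") %in% names(data)))
  out <- lapply(split(data, data$outcome), function(d) {
    wide <- stats::xtabs(value ~ subject + measurement, data = d)
    m <- matrix(as.numeric(wide), nrow = nrow(wide))
    fit <- icc_2k(m)
    sdv <- if (sd_source == "session1") stats::sd(m[, 1]) else stats::sd(as.vector(m))
    s <- sem_measurement(sdv, min(fit$icc, 1))
    data.frame(outcome = d$outcome[1], icc = fit$icc,
               ci_lower = fit$ci95[1], ci_upper = fit$ci95[2],
               sem = s, mdc95 = mdc95(s), band = reliability_band(fit$icc))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
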