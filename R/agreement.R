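check_paired <- function(x, y, n_min = 2L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < n_min) stop(sprintf("need at least %d pairs", n_min))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("volumes must be finite")
  list(x = x, y = y)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement methods on the same subjects,
#' combining precision (Pearson correlation) and accuracy (how far the
#' best-fit line is from the identity):
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with n-denominator moment estimators. Values lie in [-1, 1] with 1 at
#' perfect agreement. The 95\% confidence interval uses Lin's large-sample
#' variance on the Fisher z-transform of the estimate, back-transformed.
#'
#' @param x,y equal-length numeric vectors of paired measurements (cm^3).
#' @param conf_level confidence level for the interval.
#' @return list with `est`, `ci` (length-2), `pearson`, `c_b` (the bias
#'   correction factor, `est = pearson * c_b`), `n`.
#' @examples
#' lins_ccc(1:5, 1:5 + 10)$est  # 2*2 / (2 + 2 + 100)
#' @export
lins_ccc <- function(x, y, conf_level = 0.95) {
  p <- check_paired(x, y, 3L)
  x <- p$x; y <- p$y
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)            # n-denominator moments
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0)
    stop("both vectors are constant; concordance is undefined")
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  c_b <- if (r != 0) rho_c / r else NA_real_

  alpha <- 1 - conf_level
  if (abs(rho_c) >= 1 - 1e-12 || sx2 == 0 || sy2 == 0 || r == 0) {
    # degenerate: perfect agreement or zero correlation; the z-variance
    # formula blows up, report a point-mass interval
    ci <- c(rho_c, rho_c)
  } else {
    u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
    z <- atanh(rho_c)
    var_z <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
              2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
              rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
    se_z <- sqrt(max(0, var_z))
    q <- stats::qnorm(1 - alpha / 2)
    ci <- tanh(c(z - q * se_z, z + q * se_z))
  }
  list(est = rho_c, ci = ci, pearson = r, c_b = c_b, n = n,
       conf_level = conf_level)
}

#' Bland-Altman analysis of paired measurements
#'
#' Mean difference, sample SD of differences (n-1 denominator) and limits
#' of agreement `mean_diff +/- z * sd_diff` (z = 1.96 gives the usual 95\%
#' limits). The difference orientation is `x - y`, recorded in `labels`.
#' Per-subject (mean, difference) pairs are returned for plotting.
#'
#' @param x,y equal-length numeric vectors (cm^3).
#' @param z limits-of-agreement multiplier.
#' @param labels method names, difference = first minus second.
#' @return list with `mean_diff`, `sd_diff`, `loa` (lower, upper), `z`,
#'   `labels` and a data frame `points` with columns `mean` and `diff`.
#' @export
bland_altman <- function(x, y, z = 1.96, labels = c("x", "y")) {
  p <- check_paired(x, y, 2L)
  d <- p$x - p$y
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  list(mean_diff = mean_diff, sd_diff = sd_diff,
       loa = loa_from_summary(mean_diff, sd_diff, z),
       z = z, labels = labels,
       points = data.frame(mean = (p$x + p$y) / 2, diff = d))
}

#' Limits of agreement from printed summary statistics
#'
#' `mean_diff +/- z * sd_diff`. Useful to reconstruct limits of agreement
#' from a publication that prints only the mean and SD of the paired
#' differences.
#'
#' @param mean_diff mean of paired differences.
#' @param sd_diff SD of paired differences.
#' @param z multiplier (1.96 for 95\% limits).
#' @return named numeric `c(lower, upper)`.
#' @examples
#' loa_from_summary(4.19, 6.04)  # c(-7.65, 16.03)
#' @export
loa_from_summary <- function(mean_diff, sd_diff, z = 1.96) {
  if (sd_diff < 0) stop("sd_diff must be >= 0")
  c(lower = mean_diff - z * sd_diff, upper = mean_diff + z * sd_diff)
}

#' Mean squared paired difference
#'
#' `MSE = mean(d_i^2)` over the paired differences `d = x - y`
#' (n-denominator), which satisfies the identity
#' `MSE = mean_diff^2 + sd_diff^2 * (n-1)/n`. The n-1 variant
#' `mean_diff^2 + sd_diff^2` is exposed via [mse_from_summary()].
#'
#' @param x,y equal-length numeric vectors.
#' @return mean squared difference.
#' @export
mse_paired <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 1L) stop("need at least 1 pair")
  mean((x - y)^2)
}

#' Mean squared difference from printed summary statistics
#'
#' Closed form from the printed mean and SD of paired differences:
#' n-denominator `mean_diff^2 + sd_diff^2 (n-1)/n` (the default), or the
#' n-1 variant `mean_diff^2 + sd_diff^2`.
#'
#' @param mean_diff,sd_diff printed mean and SD of the differences.
#' @param n number of pairs.
#' @param variant `"n"` (default) or `"n-1"`.
#' @return the implied mean squared difference.
#' @examples
#' mse_from_summary(4.19, 6.04, 20)  # 52.22
#' @export
mse_from_summary <- function(mean_diff, sd_diff, n, variant = c("n", "n-1")) {
  variant <- match.arg(variant)
  mean_diff^2 + sd_diff^2 * if (variant == "n") (n - 1) / n else 1
}

#' Paired t-test on two measurement methods
#'
#' Two-tailed paired t: `t = mean(d) / (sd(d)/sqrt(n))`, df = n - 1, with
#' the confidence interval for the mean difference. Thin wrapper over
#' [stats::t.test()] with explicit handling of degenerate inputs: zero
#' difference SD with non-zero mean is an error (t undefined); all-zero
#' differences give t = 0 with a flag.
#'
#' @param x,y equal-length numeric vectors.
#' @param conf_level confidence level.
#' @return list with `t`, `df`, `p`, `mean_diff`, `ci`, `se`,
#'   `degenerate` (logical flag).
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  p <- check_paired(x, y, 2L)
  d <- p$x - p$y
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) != 0)
      stop("zero difference SD with non-zero mean difference: t is undefined")
    return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, ci = c(0, 0),
                se = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(p$x, p$y, paired = TRUE, conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       ci = as.numeric(tt$conf.int), se = unname(tt$stderr),
       degenerate = FALSE)
}

#' Recover a paired t statistic from a printed mean difference and CI
#'
#' Publications often print the mean paired difference with its 95\%
#' confidence interval but not the t statistic. Since the CI is
#' `mean_diff +/- t_{1-alpha/2, n-1} * SE`, the standard error is the CI
#' half-width divided by the t quantile, and `t = mean_diff / SE`.
#'
#' @param mean_diff printed mean difference.
#' @param ci_lower,ci_upper printed confidence bounds.
#' @param n number of pairs.
#' @param conf_level confidence level of the printed interval.
#' @return list with `t`, `df`, `se`, `p` (two-tailed).
#' @examples
#' t_from_summary(-18.18, -24.63, -11.73, 20)$t  # about -5.9
#' @export
t_from_summary <- function(mean_diff, ci_lower, ci_upper, n,
                           conf_level = 0.95) {
  if (n < 2) stop("need n >= 2")
  if (ci_upper <= ci_lower) stop("ci_upper must exceed ci_lower")
  df <- n - 1
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  se <- (ci_upper - ci_lower) / 2 / q
  t <- mean_diff / se
  list(t = t, df = df, se = se, p = 2 * stats::pt(-abs(t), df))
}

#' Shapiro-Wilk normality check
#'
#' Delegates to [stats::shapiro.test()] (3 <= n <= 5000). Constant input
#' is reported as an explicit error rather than a silent value.
#'
#' @param d numeric vector (typically paired differences).
#' @return list with `W` and `p`.
#' @export
normality_check <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 3L || length(d) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (!all(is.finite(d))) stop("values must be finite")
  if (stats::sd(d) == 0)
    stop("constant vector: Shapiro-Wilk W is undefined")
  sw <- stats::shapiro.test(d)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired method-agreement analysis
#'
#' Fits the full agreement battery for two measurement methods observed on
#' the same subjects: Lin's concordance correlation coefficient with 95\%
#' confidence interval, Bland-Altman mean difference, SD and limits of
#' agreement, mean squared paired difference, a two-tailed paired t-test
#' with confidence interval for the mean difference, and a Shapiro-Wilk
#' normality check of the differences. Differences are oriented
#' `x - y` = first method minus second, as recorded in `labels`.
#'
#' @param x,y equal-length numeric vectors of paired volumes (cm^3), or
#'   `x` a data frame with `x_col`/`y_col` naming its columns.
#' @param labels method names (difference = first minus second).
#' @param x_col,y_col column names when `x` is a data frame.
#' @param z limits-of-agreement multiplier (1.96 = 95\% limits).
#' @param conf_level confidence level for intervals.
#' @return An object of class `agreement` with components `ccc`,
#'   `ccc_ci`, `mean_diff`, `sd_diff`, `loa`, `mse`, `mse_unbiased`,
#'   `t_stat`, `df`, `p_value`, `mean_diff_ci`, `normality` (list `W`,
#'   `p`, possibly `NA` with a `note` for degenerate differences), `n`,
#'   `labels`, `points`. Methods: [print.agreement()],
#'   [summary.agreement()], [coef.agreement()], [plot.agreement()].
#' @examples
#' set.seed(1)
#' truth <- runif(20, 80, 230)
#' a <- agreement(truth + rnorm(20, 0, 5), truth + rnorm(20, 0, 5),
#'                labels = c("pdp", "vrps"))
#' a
#' coef(a)
#' @export
agreement <- function(x, y = NULL, labels = c("x", "y"),
                      x_col = NULL, y_col = NULL, z = 1.96,
                      conf_level = 0.95) {
  if (is.data.frame(x)) {
    if (is.null(x_col) || is.null(y_col))
      stop("with a data-frame input, give 'x_col' and 'y_col'")
    if (identical(labels, c("x", "y"))) labels <- c(x_col, y_col)
    y <- x[[y_col]]; x <- x[[x_col]]
  }
  p <- check_paired(x, y, 3L)
  x <- p$x; y <- p$y
  n <- length(x)
  d <- x - y

  ccc <- lins_ccc(x, y, conf_level)
  ba <- bland_altman(x, y, z = z, labels = labels)
  tt <- paired_t(x, y, conf_level)
  nrm <- tryCatch(c(normality_check(d), list(note = NA_character_)),
                  error = function(e) list(W = NA_real_, p = NA_real_,
                                           note = conditionMessage(e)))

  structure(list(
    ccc = ccc$est, ccc_ci = ccc$ci, pearson = ccc$pearson, c_b = ccc$c_b,
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff, loa = ba$loa, z = z,
    mse = mse_paired(x, y),
    mse_unbiased = ba$mean_diff^2 + ba$sd_diff^2,
    t_stat = tt$t, df = tt$df, p_value = tt$p, mean_diff_ci = tt$ci,
    t_degenerate = tt$degenerate,
    normality = nrm, n = n, labels = labels, conf_level = conf_level,
    points = ba$points
  ), class = "agreement")
}

#' @rdname agreement
#' @param object,... method arguments.
#' @export
summary.agreement <- function(object, ...) {
  structure(object, class = c("summary.agreement", "agreement"))
}

#' @export
print.summary.agreement <- function(x, ...) {
  print.agreement(x, ...)
  cat(sprintf("  Pearson r: %.4f, bias-correction factor C_b: %.4f\n",
              x$pearson, x$c_b))
  cat(sprintf("  MSE (n-1 variant): %.4f\n", x$mse_unbiased))
  if (!is.na(x$normality$note))
    cat("  normality check note:", x$normality$note, "\n")
  invisible(x)
}

#' @rdname agreement
#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Method agreement: %s vs %s (n = %d, differences = %s - %s)\n",
              x$labels[1L], x$labels[2L], x$n, x$labels[1L], x$labels[2L]))
  cat(sprintf("  Lin's rho_c: %.4f (%d%% CI %.4f, %.4f)\n",
              x$ccc, round(100 * x$conf_level), x$ccc_ci[1L], x$ccc_ci[2L]))
  cat(sprintf("  mean difference: %.3f cm^3 (SD %.3f), limits of agreement (%.3f, %.3f)\n",
              x$mean_diff, x$sd_diff, x$loa[["lower"]], x$loa[["upper"]]))
  cat(sprintf("  MSE: %.3f cm^6\n", x$mse))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.4g; mean-diff CI (%.3f, %.3f)\n",
              x$t_stat, x$df, x$p_value,
              x$mean_diff_ci[1L], x$mean_diff_ci[2L]))
  if (!is.na(x$normality$W))
    cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.4g\n",
                x$normality$W, x$normality$p))
  invisible(x)
}

#' @rdname agreement
#' @export
coef.agreement <- function(object, ...) {
  c(ccc = object$ccc, ccc_lo = object$ccc_ci[1L], ccc_hi = object$ccc_ci[2L],
    mean_diff = object$mean_diff, sd_diff = object$sd_diff,
    loa_lower = object$loa[["lower"]], loa_upper = object$loa[["upper"]],
    mse = object$mse, t = object$t_stat, df = object$df, p = object$p_value)
}

#' @rdname agreement
#' @export
residuals.agreement <- function(object, ...) object$points$diff

#' Bland-Altman plot of an agreement analysis
#'
#' Per-subject difference against per-subject mean, with the mean
#' difference (solid) and limits of agreement (dashed).
#'
#' @param x an [agreement()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement <- function(x, ...) {
  pts <- x$points
  ylim <- range(pts$diff, x$loa, 0)
  graphics::plot(pts$mean, pts$diff,
                 xlab = sprintf("mean of %s and %s (cm^3)",
                                x$labels[1L], x$labels[2L]),
                 ylab = sprintf("%s - %s (cm^3)", x$labels[1L], x$labels[2L]),
                 main = "Bland-Altman", ylim = ylim, pch = 19, ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Serialise an agreement analysis to JSON
#'
#' @param x an [agreement()] object.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
agreement_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "agreement"))
  payload <- unclass(x)
  payload$points <- NULL
  payload$loa <- as.list(payload$loa)
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                     na = "null")
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    invisible(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                               null = "null", na = "null"))
  }
}
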