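# Single-breakpoint piecewise regression with BIC model comparison.
#
# The search sorts the data by x and evaluates every admissible split
# between consecutive distinct x values, fitting each segment by OLS with
# its own intercept and slope, under the constraint that each segment
# holds at least ceil(min_segment_frac * n) observations. Two search
# paths are implemented -- an O(n) incremental scan on running sums
# ("dp") and a naive per-split lm() refit ("exhaustive") -- and must
# return identical optima.

segment_rss_from_sums <- function(n, sx, sy, sxx, syy, sxy) {
  # RSS of a simple OLS line through a segment given its running sums;
  # degenerate x (zero variance) falls back to the mean-only fit
  vx <- sxx - sx * sx / n
  vy <- syy - sy * sy / n
  cxy <- sxy - sx * sy / n
  if (vx <= .Machine$double.eps * (abs(sxx) + 1)) return(max(vy, 0))
  max(vy - cxy * cxy / vx, 0)
}

segment_coef <- function(x, y) {
  if (var(x) == 0) return(c(intercept = mean(y), slope = 0))
  f <- lm(y ~ x)
  c(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]))
}

gauss_profile_loglik <- function(rss, n) {
  # profile log-likelihood of a Gaussian regression at the MLE variance
  -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
}

#' Fit regressions with and without a single breakpoint
#'
#' Models reproductive isolation as a piecewise linear function of
#' genetic distance with one breakpoint, versus a single straight line.
#' Observations are sorted by `x`; every admissible split point (between
#' consecutive distinct `x` values, with each segment containing at least
#' `ceil(min_segment_frac * n)` observations) is evaluated, and the split
#' minimizing total residual sum of squares is selected (leftmost split
#' on ties). Both models are compared by BIC computed from the Gaussian
#' profile log-likelihood, counting k = 6 parameters for the breakpoint
#' model (2 coefficients per segment + breakpoint + error variance) and
#' k = 3 for the single line.
#'
#' @param x,y Numeric vectors of equal length (genetic distance and
#'   isolation); `x` may be on any scale (raw or standardized).
#' @param min_segment_frac Minimum fraction of the data per segment
#'   (default 0.15).
#' @param method `"dp"` (incremental running-sum scan, default) or
#'   `"exhaustive"` (per-split OLS refit); both give the same optimum.
#' @return Object of class `breakpoint_fit`: list with
#'   `breakpoint_index` (last x-sorted observation in the left segment),
#'   `breakpoint_x` (midpoint between the segments' adjacent x values),
#'   `left`/`right` (per-segment intercept and slope), `line` (single
#'   line coefficients), `rss_with`, `rss_without`, `bic_with`,
#'   `bic_without`, `breakpoint_favored` (logical, `bic_with <
#'   bic_without`), `min_segment_frac`, `n`, and the sorted data.
#' @export
fit_breakpoint_models <- function(x, y, min_segment_frac = 0.15,
                                  method = c("dp", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  m <- ceiling(min_segment_frac * n)
  if (n < 2 * m + 2 || n < 4)
    stop("too few observations for the segment-size constraint", call. = FALSE)
  if (var(x) == 0) stop("x values are all equal", call. = FALSE)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]

  # admissible splits: after index i, both segments >= m points, and
  # never inside a run of tied x values
  cand <- seq(m, n - m)
  cand <- cand[x[cand] < x[cand + 1]]
  if (!length(cand))
    stop("no admissible split point under the segment constraint",
         call. = FALSE)

  rss_at <- if (method == "dp") {
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
    vapply(cand, function(i) {
      left <- segment_rss_from_sums(i, cx[i], cy[i], cxx[i], cyy[i], cxy[i])
      nr <- n - i
      right <- segment_rss_from_sums(nr, cx[n] - cx[i], cy[n] - cy[i],
                                     cxx[n] - cxx[i], cyy[n] - cyy[i],
                                     cxy[n] - cxy[i])
      left + right
    }, numeric(1))
  } else {
    vapply(cand, function(i) {
      fl <- lm(y[1:i] ~ x[1:i])
      fr <- lm(y[(i + 1):n] ~ x[(i + 1):n])
      sum(resid(fl)^2) + sum(resid(fr)^2)
    }, numeric(1))
  }
  # leftmost split among near-ties, so both search paths agree even when
  # floating-point jitter breaks an exact tie differently
  rmin <- min(rss_at)
  best <- cand[which(rss_at <= rmin * (1 + 1e-10) + 1e-300)[1]]
  rss_with <- rss_at[match(best, cand)]

  fit0 <- lm(y ~ x)
  rss_without <- sum(resid(fit0)^2)
  # piecewise OLS can never fit worse than the single line; guard against
  # floating-point jitter in the running-sum path
  rss_with <- min(rss_with, rss_without)

  left <- segment_coef(x[1:best], y[1:best])
  right <- segment_coef(x[(best + 1):n], y[(best + 1):n])

  # floor RSS at numerical zero relative to the data scale so that on an
  # exactly-fit dataset both models share one likelihood and the penalty
  # alone decides
  rss_floor <- .Machine$double.eps * (sum(y^2) + 1)
  bic <- function(rss, k)
    -2 * gauss_profile_loglik(max(rss, rss_floor), n) + k * log(n)
  structure(list(
    breakpoint_index = best,
    breakpoint_x = (x[best] + x[best + 1]) / 2,
    left = left, right = right,
    line = segment_coef(x, y),
    rss_with = rss_with, rss_without = rss_without,
    bic_with = bic(rss_with, 6), bic_without = bic(rss_without, 3),
    breakpoint_favored = bic(rss_with, 6) < bic(rss_without, 3),
    min_segment_frac = min_segment_frac, n = n,
    x = x, y = y, method = method),
    class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("Breakpoint regression (n = %d):\n", x$n))
  cat(sprintf("  breakpoint at x = %.4f (after sorted obs %d)\n",
              x$breakpoint_x, x$breakpoint_index))
  cat(sprintf("  BIC without breakpoint = %.2f, with breakpoint = %.2f -> %s\n",
              x$bic_without, x$bic_with,
              if (x$breakpoint_favored) "breakpoint favored"
              else "no breakpoint favored"))
  cat(sprintf("  left: y = %.3f + %.3f x;  right: y = %.3f + %.3f x\n",
              x$left["intercept"], x$left["slope"],
              x$right["intercept"], x$right["slope"]))
  invisible(x)
}
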