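#' Pearson correlation test between two pair-level quantities
#'
#' Two-sided Pearson correlation test (t statistic on n - 2 degrees of
#' freedom) on pairwise-complete observations, e.g. habitat versus sexual
#' isolation across taxon pairs.
#'
#' @param x,y Numeric vectors of equal length; rows with a missing value
#'   in either are dropped.
#' @return List with `r`, `t_statistic`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector; correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), t_statistic = unname(ct$statistic),
       p_value = ct$p.value, n = length(x))
}

#' Polynomial least-squares regression with overall F test
#'
#' Fits y on raw powers of x up to `degree` by OLS and reports the model
#' r-squared and the F test of the full model against the intercept-only
#' model. Degree 2 is the default used for fits of genome-wide F_ST on
#' divergence time; degree 1 gives simple linear regression (including
#' the binary-predictor case, where r-squared equals the squared
#' point-biserial correlation).
#'
#' @param x,y Numeric vectors; rows with missing values dropped.
#' @param degree Polynomial degree (>= 1).
#' @param exclude Optional integer indices (into the original vectors) to
#'   drop before fitting, e.g. a known outlier.
#' @return Object of class `poly_fit`: list with `degree`, `coefficients`
#'   (length degree + 1, increasing powers), `r_squared`, `f_statistic`,
#'   `p_value`, `n`, and the `lm` fit in `$fit`.
#' @export
polynomial_fit <- function(x, y, degree = 2, exclude = NULL) {
  stopifnot(length(x) == length(y), degree >= 1)
  if (!is.null(exclude)) { x <- x[-exclude]; y <- y[-exclude] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < degree + 2)
    stop("need at least degree + 2 observations", call. = FALSE)
  X <- outer(x, seq_len(degree), `^`)
  colnames(X) <- paste0("x", seq_len(degree))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < degree + 1)
    stop("design matrix is rank deficient", call. = FALSE)
  fit <- lm(y ~ X)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(degree = degree,
                 coefficients = unname(coef(fit)),
                 r_squared = sm$r.squared,
                 f_statistic = unname(fstat[1]),
                 p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
                 n = n, fit = fit),
            class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Polynomial regression (degree %d, n = %d): r^2 = %.3f, F = %.2f, P = %.4g\n",
              x$degree, x$n, x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}

#' Association between an isolation index and a binary factor
#'
#' Degree-1 OLS of the index on a 0/1 indicator (e.g. allopatric vs
#' sympatric/parapatric geography), the screening analysis used to decide
#' whether a factor enters the core models.
#'
#' @param ri Numeric isolation values.
#' @param group Binary indicator (0/1, logical, or a 2-level factor or
#'   character vector).
#' @return A `poly_fit` (degree 1).
#' @export
binary_association <- function(ri, group) {
  if (is.character(group) || is.factor(group)) {
    lev <- sort(unique(as.character(group[!is.na(group)])))
    if (length(lev) != 2) stop("group must have exactly 2 levels", call. = FALSE)
    group <- as.numeric(as.character(group) == lev[2])
  }
  polynomial_fit(as.numeric(group), ri, degree = 1)
}
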