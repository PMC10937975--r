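#' Mean patristic distance between two sets of tree tips
#'
#' The patristic distance between two tips is the sum of branch lengths on
#' the path connecting them. For two populations each represented by a set
#' of sequences (tips), the pairwise genetic distance is the mean patristic
#' distance over all cross pairs (one tip from each set). The value is
#' symmetric in the two sets and invariant to re-rooting.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tips1,tips2 Non-empty, disjoint character vectors of tip labels.
#' @return Mean cross-set patristic distance (non-negative).
#' @export
mean_pair_patristic <- function(tree, tips1, tips2) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tips1) == 0 || length(tips2) == 0)
    stop("tip sets must be non-empty", call. = FALSE)
  if (length(intersect(tips1, tips2)))
    stop("tip sets must be disjoint", call. = FALSE)
  unknown <- setdiff(c(tips1, tips2), tree$tip.label)
  if (length(unknown))
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  mean(d[tips1, tips2, drop = FALSE])
}

#' Calibrate genome-wide F_ST against nuclear sequence divergence
#'
#' Ordinary least-squares regression of observed genome-wide F_ST (from
#' genotyping-by-sequencing) on per-pair nuclear sequence divergence, for
#' the subset of pairs with both measurements. The fitted line is then
#' used by [predict_fst()] to impute F_ST for pairs with sequence data
#' only.
#'
#' @param calib Data frame with numeric columns `nuc_divergence` and
#'   `fst_observed`; rows with either value missing are dropped.
#' @return Object of class `fst_calibration`: list with `intercept`,
#'   `slope`, `r_squared`, `pearson_r`, `p_value` (two-sided slope test),
#'   `n_pairs`, and the underlying `lm` fit in `$fit`.
#' @export
calibrate_fst <- function(calib) {
  stopifnot(all(c("nuc_divergence", "fst_observed") %in% names(calib)))
  use <- stats::complete.cases(calib[, c("nuc_divergence", "fst_observed")])
  calib <- calib[use, , drop = FALSE]
  if (nrow(calib) < 3)
    stop("need at least 3 pairs with both F_ST and sequence divergence",
         call. = FALSE)
  if (var(calib$nuc_divergence) == 0)
    stop("nuc_divergence is constant; calibration fit is singular",
         call. = FALSE)
  fit <- lm(fst_observed ~ nuc_divergence, data = calib)
  sm <- summary(fit)
  r <- cor(calib$nuc_divergence, calib$fst_observed)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r_squared = sm$r.squared,
                 pearson_r = r,
                 p_value = sm$coefficients["nuc_divergence", "Pr(>|t|)"],
                 n_pairs = nrow(calib),
                 fit = fit),
            class = "fst_calibration")
}

#' @export
print.fst_calibration <- function(x, ...) {
  cat(sprintf("F_ST calibration (n = %d pairs):\n", x$n_pairs))
  cat(sprintf("  F_ST = %.5f + %.5f * nuc_divergence\n", x$intercept, x$slope))
  cat(sprintf("  r = %.3f, r^2 = %.3f, slope P = %.4g\n",
              x$pearson_r, x$r_squared, x$p_value))
  invisible(x)
}

#' Predict genome-wide F_ST from nuclear sequence divergence
#'
#' Applies the raw linear predictor of a fitted calibration; predictions
#' are deliberately not clipped to \[0, 1\] (out-of-range values are
#' reported as-is and flagged with a warning).
#'
#' @param model A `fst_calibration` from [calibrate_fst()].
#' @param nuc_divergence Non-negative numeric vector.
#' @return Predicted F_ST values (same length).
#' @export
predict_fst <- function(model, nuc_divergence) {
  stopifnot(inherits(model, "fst_calibration"))
  pred <- model$intercept + model$slope * nuc_divergence
  out <- !is.na(pred) & (pred < 0 | pred > 1)
  if (any(out))
    warning(sum(out), " predicted F_ST value(s) outside [0, 1]; kept unclipped",
            call. = FALSE)
  pred
}

#' Fill in the final genetic distance for every pair
#'
#' `fst_final` is the observed genome-wide F_ST when available; otherwise
#' it is predicted from nuclear sequence divergence via the calibration
#' model. Pairs with neither measurement keep a missing value. When no
#' calibration model is supplied, one is fitted from the pairs in
#' `estimates` that carry both measurements.
#'
#' @param estimates Per-pair estimates data frame (needs columns
#'   `fst_observed` and `nuc_divergence`).
#' @param model Optional `fst_calibration`; fitted internally if `NULL`
#'   and any pair lacks observed F_ST but has sequence divergence.
#' @return `estimates` with columns `fst_final` and `fst_source`
#'   (`"observed"`, `"predicted"` or `NA`) appended; the calibration used
#'   (or `NULL`) is attached as attribute `"calibration"`.
#' @export
add_final_fst <- function(estimates, model = NULL) {
  need_pred <- is.na(estimates$fst_observed) & !is.na(estimates$nuc_divergence)
  if (is.null(model) && any(need_pred))
    model <- calibrate_fst(estimates)
  fst_final <- estimates$fst_observed
  src <- ifelse(is.na(fst_final), NA_character_, "observed")
  if (any(need_pred)) {
    fst_final[need_pred] <- predict_fst(model, estimates$nuc_divergence[need_pred])
    src[need_pred] <- "predicted"
  }
  estimates$fst_final <- fst_final
  estimates$fst_source <- src
  attr(estimates, "calibration") <- model
  estimates
}

#' Center and scale a vector of genetic distances
#'
#' Standardizes to sample mean 0 and sample standard deviation 1
#' (denominator n - 1), returning the transform parameters so values can
#' be mapped back to the original scale. Standardization is applied to
#' exactly the set of values passed in, i.e. the subset of pairs entering
#' a given model fit.
#'
#' @param values Numeric vector (length >= 2, non-constant); `NA`s are not
#'   allowed -- subset first.
#' @return List with `values` (standardized vector), `mean`, `sd`.
#' @export
standardize_distances <- function(values) {
  if (any(is.na(values))) stop("values must not contain NA", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("values are constant; cannot standardize", call. = FALSE)
  m <- mean(values)
  list(values = (values - m) / s, mean = m, sd = s)
}
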