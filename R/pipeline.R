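#' Run the full reproductive-isolation analysis pipeline
#'
#' Sequences the analysis end-to-end: load (or generate) the dataset,
#' estimate habitat and sexual isolation per pair, calibrate and fill in
#' genome-wide genetic distances, fit the five-model Bayesian mixed-model
#' suite for each response, fit breakpoint regressions, compute the
#' auxiliary association statistics, and write all artifacts (per-pair
#' estimates CSV, JSON results with provenance, manifest) to the output
#' directory. Stages that lack their inputs (e.g. no mating trials) are
#' skipped with a warning rather than failing the run.
#'
#' @param paths Named list of input paths (`pairs`, `host_trials`,
#'   optionally `mating_trials`, `tree`) -- or `NULL` to run on synthetic
#'   data.
#' @param synth A [synth_config()] used when `paths` is `NULL`. Exactly
#'   one of `paths` / `synth` must be supplied.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param responses Which responses to model.
#' @param spec Base [mm_spec()] shared by all model fits (its seed is
#'   overridden by `seed`).
#' @param min_segment_frac Breakpoint segment-size constraint.
#' @param seed Master seed for every stochastic stage.
#' @return Object of class `ri_pipeline_result`: list with `estimates`,
#'   `calibration`, `suites` (per response), `breakpoints` (per
#'   response), `associations`, `manifest` (or `NULL`), `seed`.
#' @export
run_pipeline <- function(paths = NULL, synth = NULL, out_dir = NULL,
                         responses = c("habitat", "sexual"),
                         spec = mm_spec(), min_segment_frac = 0.15,
                         seed = 1) {
  if (is.null(paths) == is.null(synth))
    stop("provide exactly one of `paths` or `synth`", call. = FALSE)
  responses <- match.arg(responses, several.ok = TRUE)
  spec$seed <- seed

  truth <- NULL
  if (!is.null(synth)) {
    synth$seed <- seed
    gen <- generate_dataset(synth)
    dataset <- gen$dataset
    truth <- gen$truth
  } else {
    dataset <- read_ri_dataset(
      pairs_path = paths$pairs, host_trials_path = paths$host_trials,
      mating_trials_path = paths$mating_trials, tree_path = paths$tree)
  }

  estimates <- estimate_all_pairs(dataset)
  estimates <- add_final_fst(estimates)
  calibration <- attr(estimates, "calibration")

  suites <- list(); breakpoints <- list()
  for (resp in responses) {
    ycol <- if (resp == "habitat") "habitat_isolation" else "sexual_isolation"
    usable <- sum(!is.na(estimates[[ycol]]) & !is.na(estimates$fst_final))
    if (usable < 5) {
      warning("skipping ", resp, " isolation stages: only ", usable,
              " usable pairs", call. = FALSE)
      next
    }
    suites[[resp]] <- fit_model_suite(estimates, resp, spec)
    keep <- !is.na(estimates[[ycol]]) & !is.na(estimates$fst_final)
    breakpoints[[resp]] <- fit_breakpoint_models(
      estimates$fst_final[keep], estimates[[ycol]][keep],
      min_segment_frac = min_segment_frac)
  }

  associations <- list()
  both <- !is.na(estimates$habitat_isolation) &
    !is.na(estimates$sexual_isolation)
  if (sum(both) >= 3 &&
      sd(estimates$habitat_isolation[both]) > 0 &&
      sd(estimates$sexual_isolation[both]) > 0)
    associations$habitat_vs_sexual <- pearson_test(
      estimates$habitat_isolation, estimates$sexual_isolation)
  known_geo <- estimates$geography %in% c("allopatric", "sympatric_parapatric")
  if (length(unique(estimates$geography[known_geo])) == 2) {
    for (resp in responses) {
      ycol <- if (resp == "habitat") "habitat_isolation" else "sexual_isolation"
      ok <- known_geo & !is.na(estimates[[ycol]])
      if (sum(ok) >= 4 && length(unique(estimates$geography[ok])) == 2) {
        f <- binary_association(estimates[[ycol]][ok],
                                estimates$geography[ok])
        associations[[paste0("geography_", resp)]] <-
          list(r_squared = f$r_squared, p_value = f$p_value, n = f$n)
      }
    }
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    results <- list()
    if (!is.null(calibration))
      results$fst_calibration <- calibration[c("intercept", "slope",
                                               "r_squared", "pearson_r",
                                               "p_value", "n_pairs")]
    for (resp in names(suites)) {
      results[[paste0("model_suite_", resp)]] <- list(
        table = suites[[resp]]$table,
        best_model = suites[[resp]]$table$model[1],
        summaries = lapply(suites[[resp]]$fits, function(f) f$summary))
      bp <- breakpoints[[resp]]
      results[[paste0("breakpoint_", resp)]] <-
        bp[c("breakpoint_index", "breakpoint_x", "left", "right", "line",
             "rss_with", "rss_without", "bic_with", "bic_without",
             "breakpoint_favored", "min_segment_frac", "n")]
    }
    if (length(associations)) results$associations <- associations
    manifest <- write_ri_outputs(
      estimates, results, out_dir,
      provenance = list(seed = seed,
                        mcmc = spec[c("n_chains", "n_iter", "burnin", "thin")],
                        input = if (is.null(synth)) "files" else "synthetic"))
  }

  structure(list(estimates = estimates, calibration = calibration,
                 suites = suites, breakpoints = breakpoints,
                 associations = associations, truth = truth,
                 manifest = manifest, seed = seed),
            class = "ri_pipeline_result")
}

#' @export
print.ri_pipeline_result <- function(x, ...) {
  cat("Reproductive-isolation pipeline result (seed ", x$seed, ")\n", sep = "")
  cat("  pairs: ", nrow(x$estimates), "\n", sep = "")
  for (resp in names(x$suites)) {
    cat(sprintf("  %s: best model '%s' (DIC %.2f), breakpoint %s\n",
                resp, x$suites[[resp]]$table$model[1],
                x$suites[[resp]]$table$dic[1],
                if (x$breakpoints[[resp]]$breakpoint_favored)
                  "favored" else "not favored"))
  }
  invisible(x)
}
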