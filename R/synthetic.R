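#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the study design: populations of stick-insect
#' species sampled in pairs spanning a speciation continuum, with
#' conspecific pairs drawing genome-wide F_ST from a low "within-species"
#' range and heterospecific pairs from a high "between-species" range,
#' true isolation values produced by the pairwise linear mixed model
#' (on standardized F_ST, with crossed species random effects), and
#' trial-level behavioral data sampled binomially around the truth.
#'
#' Defaults mirror the study scale: 9 species with 2 populations each,
#' 36 pairs (9 conspecific + 27 heterospecific, i.e. 75% heterospecific),
#' habitat-isolation coefficients (0.35, -0.04, 0.15, 0.27) for
#' (intercept, within-species slope, status offset, interaction) so the
#' within-species slope is flat and the between-species slope is
#' -0.04 + 0.27, and sexual-isolation coefficients (0.40, 0.31, 0, 0)
#' giving a single continuum-wide slope. 100 host trials per taxon, 15
#' mating trials per directional combination, homotypic mating
#' probability 0.5, a 5% rate of trials where neither host is chosen,
#' residual SD 0.1 and species random-effect SD 0.05.
#'
#' @param n_species Number of species.
#' @param populations_per_species Populations sampled per species (>= 2
#'   if any conspecific pairs are requested).
#' @param n_pairs Total number of taxon pairs.
#' @param frac_heterospecific Fraction of pairs that are heterospecific.
#' @param betas_habitat,betas_sexual Length-4 numeric vectors
#'   `(beta0, beta_gen_within, beta_taxon, beta_int)` on the standardized
#'   F_ST scale.
#' @param random_effect_sd,residual_sd Standard deviations of the species
#'   random effects and the pair-level residual.
#' @param host_trials_per_taxon Host-choice trials per taxon per pair.
#' @param mating_trials_per_combination Mating trials per directional
#'   combination.
#' @param homotypic_mating_prob Mating probability in homotypic pairings.
#' @param none_rate Probability a host trial ends with neither host
#'   chosen (such trials are excluded by the estimator).
#' @param fst_within_range,fst_between_range Uniform F_ST ranges for
#'   conspecific and heterospecific pairs.
#' @param frac_pairs_with_mating Fraction of pairs with mating trials
#'   (sexual isolation is typically assayed on a subset).
#' @param seed Master seed; every random quantity derives from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_species = 9, populations_per_species = 2,
                         n_pairs = 36, frac_heterospecific = 0.75,
                         betas_habitat = c(0.35, -0.04, 0.15, 0.27),
                         betas_sexual = c(0.40, 0.31, 0, 0),
                         random_effect_sd = 0.05, residual_sd = 0.1,
                         host_trials_per_taxon = 100,
                         mating_trials_per_combination = 15,
                         homotypic_mating_prob = 0.5,
                         none_rate = 0.05,
                         fst_within_range = c(0.0, 0.35),
                         fst_between_range = c(0.55, 0.95),
                         frac_pairs_with_mating = 0.75,
                         seed = 1) {
  stopifnot(length(betas_habitat) == 4, length(betas_sexual) == 4,
            random_effect_sd >= 0, residual_sd >= 0,
            homotypic_mating_prob > 0, homotypic_mating_prob <= 1,
            none_rate >= 0, none_rate < 1,
            fst_within_range[1] <= fst_within_range[2],
            fst_between_range[1] <= fst_between_range[2],
            frac_heterospecific >= 0, frac_heterospecific <= 1,
            frac_pairs_with_mating >= 0, frac_pairs_with_mating <= 1,
            host_trials_per_taxon >= 1, mating_trials_per_combination >= 1)
  n_con <- round(n_pairs * (1 - frac_heterospecific))
  n_het <- n_pairs - n_con
  max_con <- n_species * choose(populations_per_species, 2)
  if (n_con > max_con)
    stop("infeasible config: ", n_con, " conspecific pairs requested but only ",
         max_con, " distinct within-species population pairs exist",
         call. = FALSE)
  n_pop <- n_species * populations_per_species
  max_het <- choose(n_pop, 2) - n_species * choose(populations_per_species, 2)
  if (n_het > max_het)
    stop("infeasible config: too many heterospecific pairs requested",
         call. = FALSE)
  cfg <- as.list(environment())[c(
    "n_species", "populations_per_species", "n_pairs", "frac_heterospecific",
    "betas_habitat", "betas_sexual", "random_effect_sd", "residual_sd",
    "host_trials_per_taxon", "mating_trials_per_combination",
    "homotypic_mating_prob", "none_rate", "fst_within_range",
    "fst_between_range", "frac_pairs_with_mating", "seed")]
  cfg$n_conspecific <- n_con
  cfg$n_heterospecific <- n_het
  structure(cfg, class = "synth_config")
}

#' Simulate host-choice trials for one taxon pair
#'
#' Under the symmetric parameterization, taxon 1 chooses the reference
#' host with probability `0.5 + HI/2` and taxon 2 with `0.5 - HI/2`, so
#' the expected absolute difference in choice proportions equals the true
#' habitat isolation. Each trial independently ends with no choice with
#' probability `none_rate`; such trials are recorded and excluded
#' downstream.
#'
#' @param true_hi True habitat isolation in \[0, 1\].
#' @param n_per_taxon Trials per taxon.
#' @param taxa Character vector of the two taxon ids.
#' @param pair_id Pair identifier for the emitted rows.
#' @param none_rate Probability of a no-choice trial.
#' @param seed Optional integer seed for an isolated substream.
#' @return Data frame of trial rows (`pair_id, taxon_id, choice`).
#' @export
simulate_host_trials <- function(true_hi, n_per_taxon, taxa = c("t1", "t2"),
                                 pair_id = "pair", none_rate = 0, seed = NULL) {
  if (true_hi < 0 || true_hi > 1)
    stop("true_hi must lie in [0, 1]", call. = FALSE)
  stopifnot(n_per_taxon >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  p_ref <- c(0.5 + true_hi / 2, 0.5 - true_hi / 2)
  rows <- lapply(1:2, function(k) {
    u <- runif(n_per_taxon)
    choice <- ifelse(u < none_rate, "none",
                     ifelse(runif(n_per_taxon) < p_ref[k],
                            "reference", "alternative"))
    data.frame(pair_id = pair_id, taxon_id = taxa[k], choice = choice,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate mating trials for one taxon pair
#'
#' Homotypic pairings mate with probability `homotypic_prob`; heterotypic
#' pairings with probability `(1 - true_si) * homotypic_prob`, the
#' generative inverse of the index `1 - f_het / f_homo`. Four independent
#' binomial draws, one per directional combination.
#'
#' @param true_si True sexual isolation (at most 1; negative values give
#'   disassortative mating as long as the implied heterotypic probability
#'   stays within \[0, 1\]).
#' @param homotypic_prob Homotypic mating probability.
#' @param n_per_combination Trials per directional combination.
#' @param taxa Character vector of the two taxon ids.
#' @param pair_id Pair identifier for the emitted rows.
#' @param seed Optional integer seed for an isolated substream.
#' @return Data frame of trial rows
#'   (`pair_id, male_taxon, female_taxon, mated`).
#' @export
simulate_mating_trials <- function(true_si, homotypic_prob = 0.5,
                                   n_per_combination = 15,
                                   taxa = c("t1", "t2"), pair_id = "pair",
                                   seed = NULL) {
  p_het <- (1 - true_si) * homotypic_prob
  if (true_si > 1 || p_het < 0 || p_het > 1)
    stop("implied heterotypic mating probability outside [0, 1]",
         call. = FALSE)
  stopifnot(n_per_combination >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  combos <- data.frame(male = taxa[c(1, 2, 1, 2)],
                       female = taxa[c(1, 2, 2, 1)],
                       p = c(homotypic_prob, homotypic_prob, p_het, p_het),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(4), function(k)
    data.frame(pair_id = pair_id, male_taxon = combos$male[k],
               female_taxon = combos$female[k],
               mated = rbinom(n_per_combination, 1, combos$p[k]),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset with a truth record
#'
#' Builds the taxon and pair structure, draws per-pair F_ST uniformly
#' within the status-appropriate range, computes true habitat and sexual
#' isolation from the pairwise linear model (on F_ST standardized across
#' the generated pairs) with species random effects and residual noise --
#' truncating habitat isolation to \[0, 1\] and sexual isolation to the
#' feasible range -- and then emits trial-level host-choice and mating
#' records. Each pair's trials use their own seeded substream (recorded
#' in the truth table), so regenerating one pair does not perturb the
#' others. The whole bundle is a drop-in for the real-data pipeline.
#'
#' @param config A [synth_config()].
#' @return Object of class `ri_synth`: list with `dataset` (an
#'   `ri_dataset`), `truth` (data frame: pair-level true values, random
#'   effects, substream seeds), `lambda_habitat`/`lambda_sexual` (named
#'   species random-effect vectors), and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  species <- sprintf("sp%02d", seq_len(config$n_species))
  taxa <- data.frame(
    taxon_id = as.vector(t(outer(species, seq_len(config$populations_per_species),
                                 function(s, k) sprintf("%s_p%d", s, k)))),
    species_id = rep(species, each = config$populations_per_species),
    stringsAsFactors = FALSE)

  # candidate pairs by status
  all_pairs <- t(combn(taxa$taxon_id, 2))
  sp_of <- setNames(taxa$species_id, taxa$taxon_id)
  is_con <- sp_of[all_pairs[, 1]] == sp_of[all_pairs[, 2]]
  con_idx <- sample(which(is_con), config$n_conspecific)
  het_idx <- sample(which(!is_con), config$n_heterospecific)
  sel <- c(con_idx, het_idx)
  t1 <- all_pairs[sel, 1]; t2 <- all_pairs[sel, 2]
  status <- ifelse(sp_of[t1] == sp_of[t2], "conspecific", "heterospecific")
  n <- length(sel)
  pair_id <- sprintf("pair%02d", seq_len(n))

  # F_ST by status range
  fst <- numeric(n)
  con <- status == "conspecific"
  fst[con] <- runif(sum(con), config$fst_within_range[1],
                    config$fst_within_range[2])
  fst[!con] <- runif(sum(!con), config$fst_between_range[1],
                     config$fst_between_range[2])
  x_gen <- standardize_distances(fst)$values
  x_taxon <- as.numeric(!con)

  lambda_h <- setNames(rnorm(config$n_species, 0, config$random_effect_sd),
                       species)
  lambda_s <- setNames(rnorm(config$n_species, 0, config$random_effect_sd),
                       species)
  pair_lambda <- function(lam) lam[sp_of[t1]] + lam[sp_of[t2]]

  linpred <- function(b) b[1] + b[2] * x_gen + b[3] * x_taxon +
    b[4] * x_gen * x_taxon
  si_floor <- 1 - 1 / config$homotypic_mating_prob
  true_hi <- pmin(1, pmax(0, linpred(config$betas_habitat) +
                            pair_lambda(lambda_h) +
                            rnorm(n, 0, config$residual_sd)))
  true_si <- pmin(1, pmax(si_floor, linpred(config$betas_sexual) +
                            pair_lambda(lambda_s) +
                            rnorm(n, 0, config$residual_sd)))

  has_mating <- rep(FALSE, n)
  n_mating_pairs <- round(n * config$frac_pairs_with_mating)
  if (n_mating_pairs > 0)
    has_mating[sample.int(n, n_mating_pairs)] <- TRUE

  pair_seed <- sample.int(2147483646L, n)

  host_rows <- vector("list", n); mating_rows <- vector("list", n)
  for (i in seq_len(n)) {
    host_rows[[i]] <- simulate_host_trials(
      true_hi[i], config$host_trials_per_taxon, taxa = c(t1[i], t2[i]),
      pair_id = pair_id[i], none_rate = config$none_rate,
      seed = pair_seed[i])
    if (has_mating[i])
      mating_rows[[i]] <- simulate_mating_trials(
        true_si[i], config$homotypic_mating_prob,
        config$mating_trials_per_combination, taxa = c(t1[i], t2[i]),
        pair_id = pair_id[i], seed = (pair_seed[i] + 1L) %% 2147483647L)
  }
  host <- do.call(rbind, host_rows)
  mating_rows <- mating_rows[!vapply(mating_rows, is.null, logical(1))]
  mating <- if (length(mating_rows)) do.call(rbind, mating_rows) else NULL

  pairs <- data.frame(pair_id = pair_id, taxon1 = t1, taxon2 = t2,
                      species1 = unname(sp_of[t1]),
                      species2 = unname(sp_of[t2]),
                      fst_observed = fst,
                      nuc_divergence = NA_real_,
                      stringsAsFactors = FALSE)
  truth <- data.frame(pair_id = pair_id, status = status,
                      true_fst = fst, x_gen_std = x_gen,
                      true_habitat_isolation = true_hi,
                      true_sexual_isolation = true_si,
                      lambda_habitat_sum = unname(pair_lambda(lambda_h)),
                      lambda_sexual_sum = unname(pair_lambda(lambda_s)),
                      has_mating = has_mating,
                      pair_seed = pair_seed,
                      stringsAsFactors = FALSE)
  structure(list(dataset = ri_dataset(pairs, host, mating),
                 truth = truth,
                 lambda_habitat = lambda_h, lambda_sexual = lambda_s,
                 config = config),
            class = "ri_synth")
}

#' @export
print.ri_synth <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d pairs (%d conspecific), %d species, seed %d\n",
              nrow(x$truth), sum(x$truth$status == "conspecific"),
              x$config$n_species, x$config$seed))
  print(x$dataset)
  invisible(x)
}
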