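#' Habitat isolation from host-preference trials of one taxon pair
#'
#' Habitat isolation is the absolute difference between the two taxa of a
#' pair in the proportion of trials in which the individual was found on
#' the (arbitrarily chosen) reference host. Trials where neither host was
#' chosen are excluded before computing the proportions, so the index is
#' based on usable trials only. The index lies in \[0, 1\], is invariant
#' to which host is labeled the reference, and is symmetric in the two
#' taxa.
#'
#' @param trials Data frame of host trials for a single pair, columns
#'   `taxon_id` and `choice` (reference/alternative/none).
#' @param taxa Character vector of the pair's two taxon ids. Defaults to
#'   the taxa present in `trials`, which must then number exactly two.
#' @return Habitat isolation in \[0, 1\], or `NA` (with attribute
#'   `reason`) if either taxon has no usable trial.
#' @examples
#' tr <- data.frame(
#'   taxon_id = rep(c("a", "b"), each = 4),
#'   choice = c("reference", "reference", "reference", "alternative",
#'              "reference", "alternative", "alternative", "none"))
#' habitat_isolation(tr)  # |3/4 - 1/3|
#' @export
habitat_isolation <- function(trials, taxa = NULL) {
  if (is.null(taxa)) {
    taxa <- sort(unique(trials$taxon_id))
    if (length(taxa) != 2)
      stop("trials must involve exactly two taxa (or pass `taxa`)",
           call. = FALSE)
  }
  stopifnot(length(taxa) == 2)
  usable <- trials[trials$choice != "none", , drop = FALSE]
  p <- numeric(2)
  for (k in 1:2) {
    tk <- usable[usable$taxon_id == taxa[k], , drop = FALSE]
    if (nrow(tk) == 0)
      return(structure(NA_real_, reason = "no_usable_trials"))
    p[k] <- mean(tk$choice == "reference")
  }
  abs(p[1] - p[2])
}

#' Tabulate mating-trial counts for one taxon pair
#'
#' Collapses trial-level mating records into counts of trials and matings
#' for each of the four directional combinations: the two homotypic
#' combinations (male and female from the same taxon) and the two
#' heterotypic ones.
#'
#' @param trials Data frame of mating trials for a single pair, columns
#'   `male_taxon`, `female_taxon`, `mated` (0/1).
#' @param taxa Character vector of the pair's two taxon ids; defaults to
#'   the taxa present.
#' @return Object of class `mating_counts`: a list with integer vectors
#'   `n_trials` and `n_mated`, each named `hom1, hom2, het12, het21`
#'   (het12 = male taxon 1 x female taxon 2).
#' @export
mating_counts <- function(trials, taxa = NULL) {
  if (is.null(taxa)) {
    taxa <- sort(unique(c(trials$male_taxon, trials$female_taxon)))
    if (length(taxa) != 2)
      stop("trials must involve exactly two taxa (or pass `taxa`)",
           call. = FALSE)
  }
  combo <- function(m, f)
    trials$male_taxon == m & trials$female_taxon == f
  sel <- list(hom1 = combo(taxa[1], taxa[1]), hom2 = combo(taxa[2], taxa[2]),
              het12 = combo(taxa[1], taxa[2]), het21 = combo(taxa[2], taxa[1]))
  n_trials <- vapply(sel, sum, integer(1))
  n_mated <- vapply(sel, function(s) sum(trials$mated[s]), numeric(1))
  new_mating_counts(n_trials, as.integer(n_mated))
}

#' Construct a mating-counts object from raw counts
#'
#' @param n_trials Integer vector of trial counts, named or in the order
#'   `hom1, hom2, het12, het21`.
#' @param n_mated Integer vector of mating counts, same order.
#' @return Object of class `mating_counts`.
#' @export
new_mating_counts <- function(n_trials, n_mated) {
  nm <- c("hom1", "hom2", "het12", "het21")
  n_trials <- setNames(as.integer(n_trials), nm)
  n_mated <- setNames(as.integer(n_mated), nm)
  if (any(n_trials < 0) || any(n_mated < 0) || any(n_mated > n_trials))
    stop("need 0 <= n_mated <= n_trials for every combination", call. = FALSE)
  structure(list(n_trials = n_trials, n_mated = n_mated),
            class = "mating_counts")
}

pooled_freqs <- function(counts, method = c("pooled", "directional_mean")) {
  method <- match.arg(method)
  hom <- c("hom1", "hom2"); het <- c("het12", "het21")
  if (method == "pooled") {
    f_homo <- sum(counts$n_mated[hom]) / sum(counts$n_trials[hom])
    f_het <- sum(counts$n_mated[het]) / sum(counts$n_trials[het])
  } else {
    f_homo <- mean(counts$n_mated[hom] / counts$n_trials[hom])
    f_het <- mean(counts$n_mated[het] / counts$n_trials[het])
  }
  list(f_homo = f_homo, f_het = f_het)
}

#' Sexual isolation index from mating-trial counts
#'
#' The Coyne-Orr-style index `1 - f_het / f_homo`, where `f_homo` and
#' `f_het` are the mating frequencies in homotypic and heterotypic
#' pairings. By default frequencies pool counts across the two directional
#' combinations within each category; `method = "directional_mean"`
#' instead averages the two per-direction proportions. The index is 0
#' under random mating, 1 under complete assortment, and negative
#' (unbounded below) under disassortative mating.
#'
#' @param counts A `mating_counts` object (see [mating_counts()]).
#' @param method Frequency pooling convention; `"pooled"` (default) or
#'   `"directional_mean"`.
#' @return Sexual isolation (at most 1), or `NA` with attribute `reason`
#'   if undefined (`f_homo == 0`, or a required combination has no trial).
#' @examples
#' cnt <- new_mating_counts(n_trials = c(10, 10, 10, 10),
#'                          n_mated = c(7, 7, 4, 3))
#' sexual_isolation(cnt)  # 1 - 0.35/0.70 = 0.5
#' @export
sexual_isolation <- function(counts, method = c("pooled", "directional_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "mating_counts"))
  hom_n <- sum(counts$n_trials[c("hom1", "hom2")])
  het_n <- sum(counts$n_trials[c("het12", "het21")])
  if (hom_n == 0 || het_n == 0)
    return(structure(NA_real_, reason = "missing_combination"))
  if (method == "directional_mean" && any(counts$n_trials == 0))
    return(structure(NA_real_, reason = "missing_combination"))
  f <- pooled_freqs(counts, method)
  if (f$f_homo == 0)
    return(structure(NA_real_, reason = "f_homo_zero"))
  1 - f$f_het / f$f_homo
}

#' Posterior draws of sexual isolation under finite trial counts
#'
#' Propagates binomial sampling uncertainty in the mating frequencies into
#' the sexual-isolation index. Independent Beta(1 + mated, 1 + unmated)
#' posteriors (uniform priors) are placed on the pooled homotypic and
#' heterotypic mating probabilities, and each Monte-Carlo draw returns
#' `1 - theta_het / theta_homo`. Unlike the plug-in index this is defined
#' even when no homotypic matings were observed, because `theta_homo` is
#' almost surely positive.
#'
#' @param counts A `mating_counts` object.
#' @param n_draws Number of Monte-Carlo draws (positive integer).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Numeric vector of `n_draws` posterior draws of the index.
#' @export
sexual_isolation_posterior <- function(counts, n_draws = 4000, seed = 1) {
  stopifnot(inherits(counts, "mating_counts"))
  if (!is.numeric(n_draws) || n_draws < 1)
    stop("n_draws must be a positive integer", call. = FALSE)
  hom_trials <- sum(counts$n_trials[c("hom1", "hom2")])
  hom_mated <- sum(counts$n_mated[c("hom1", "hom2")])
  het_trials <- sum(counts$n_trials[c("het12", "het21")])
  het_mated <- sum(counts$n_mated[c("het12", "het21")])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  theta_homo <- rbeta(n_draws, 1 + hom_mated, 1 + hom_trials - hom_mated)
  theta_het <- rbeta(n_draws, 1 + het_mated, 1 + het_trials - het_mated)
  1 - theta_het / theta_homo
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-pair habitat and sexual isolation for a whole dataset
#'
#' Applies [habitat_isolation()] and [sexual_isolation()] to every taxon
#' pair. Pairs without usable trials get missing estimates with a reason
#' code, never an error, so partial datasets (e.g. mating trials assayed
#' on a subset of pairs) flow through.
#'
#' @param dataset An `ri_dataset` (see [read_ri_dataset()]), or a list
#'   with elements `pairs`, `host_trials`, `mating_trials`.
#' @param si_method Pooling convention passed to [sexual_isolation()].
#' @return Data frame with one row per pair: `pair_id, status, geography,
#'   species1, species2, habitat_isolation, sexual_isolation,
#'   n_host_trials, n_mating_trials,
#'   hi_reason, si_reason, fst_observed, nuc_divergence`.
#' @export
estimate_all_pairs <- function(dataset, si_method = "pooled") {
  pairs <- dataset$pairs
  host <- dataset$host_trials
  mating <- dataset$mating_trials
  n <- nrow(pairs)
  hi <- si <- rep(NA_real_, n)
  hi_reason <- si_reason <- rep(NA_character_, n)
  n_host <- n_mate <- integer(n)
  for (i in seq_len(n)) {
    taxa <- c(pairs$taxon1[i], pairs$taxon2[i])
    ht <- host[host$pair_id == pairs$pair_id[i], , drop = FALSE]
    n_host[i] <- nrow(ht)
    if (nrow(ht) > 0) {
      v <- habitat_isolation(ht, taxa)
      hi[i] <- as.numeric(v)
      if (is.na(v)) hi_reason[i] <- attr(v, "reason")
    } else hi_reason[i] <- "no_trials"
    if (!is.null(mating)) {
      mt <- mating[mating$pair_id == pairs$pair_id[i], , drop = FALSE]
      n_mate[i] <- nrow(mt)
      if (nrow(mt) > 0) {
        v <- sexual_isolation(mating_counts(mt, taxa), method = si_method)
        si[i] <- as.numeric(v)
        if (is.na(v)) si_reason[i] <- attr(v, "reason")
      } else si_reason[i] <- "no_trials"
    } else si_reason[i] <- "no_trials"
  }
  data.frame(pair_id = pairs$pair_id, status = pairs$status,
             geography = pairs$geography,
             species1 = pairs$species1, species2 = pairs$species2,
             habitat_isolation = hi, sexual_isolation = si,
             n_host_trials = n_host, n_mating_trials = n_mate,
             hi_reason = hi_reason, si_reason = si_reason,
             fst_observed = pairs$fst_observed,
             nuc_divergence = pairs$nuc_divergence,
             stringsAsFactors = FALSE)
}
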