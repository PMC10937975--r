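# Fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdir().

toy_pairs <- function() {
  data.frame(
    pair_id = c("pA", "pB", "pC"),
    taxon1 = c("cr_h1", "cr_h1", "po_h1"),
    taxon2 = c("cr_h2", "po_h1", "po_h2"),
    species1 = c("cristinae", "cristinae", "podura"),
    species2 = c("cristinae", "podura", "podura"),
    distance_m = c(100, 5000, NA),
    fst_observed = c(0.10, 0.80, NA),
    nuc_divergence = c(0.002, 0.030, 0.004),
    stringsAsFactors = FALSE)
}

# host trials with known proportions: pA taxa 15/20 vs 5/25 (HI 0.55),
# pB complete divergence, pC identical preferences
toy_host_trials <- function() {
  mk <- function(pair, taxon, ref, alt, none = 0) {
    data.frame(pair_id = pair, taxon_id = taxon,
               choice = rep(c("reference", "alternative", "none"),
                            c(ref, alt, none)),
               stringsAsFactors = FALSE)
  }
  rbind(mk("pA", "cr_h1", 15, 5), mk("pA", "cr_h2", 5, 20),
        mk("pB", "cr_h1", 20, 0), mk("pB", "po_h1", 0, 20),
        mk("pC", "po_h1", 10, 10, 2), mk("pC", "po_h2", 10, 10))
}

# mating trials for pA only: pooled homotypic 14/20, heterotypic 7/20
toy_mating_trials <- function() {
  mk <- function(male, female, mated, n) {
    data.frame(pair_id = "pA", male_taxon = male, female_taxon = female,
               mated = rep(c(1L, 0L), c(mated, n - mated)),
               stringsAsFactors = FALSE)
  }
  rbind(mk("cr_h1", "cr_h1", 7, 10), mk("cr_h2", "cr_h2", 7, 10),
        mk("cr_h1", "cr_h2", 4, 10), mk("cr_h2", "cr_h1", 3, 10))
}

toy_dataset <- function() {
  ri_dataset(toy_pairs(), toy_host_trials(), toy_mating_trials())
}

write_toy_csvs <- function(dir = tempfile("toy")) {
  dir.create(dir)
  paths <- list(pairs = file.path(dir, "pairs.csv"),
                host_trials = file.path(dir, "host.csv"),
                mating_trials = file.path(dir, "mating.csv"))
  write.csv(toy_pairs(), paths$pairs, row.names = FALSE, na = "")
  write.csv(toy_host_trials(), paths$host_trials, row.names = FALSE, na = "")
  write.csv(toy_mating_trials(), paths$mating_trials, row.names = FALSE, na = "")
  paths
}

# short-chain spec for tests whose point is not MCMC precision
quick_spec <- function(...) {
  mm_spec(n_iter = 2000, burnin = 500, thin = 3, ...)
}

# estimates frame for fitting models directly on constructed data
fake_estimates <- function(y, x, status = NULL, species1 = NULL,
                           species2 = NULL, sexual = NA_real_) {
  n <- length(y)
  if (is.null(status)) status <- rep("conspecific", n)
  if (is.null(species1)) species1 <- rep("s1", n)
  if (is.null(species2))
    species2 <- ifelse(status == "conspecific", species1, "s2")
  data.frame(pair_id = sprintf("p%03d", seq_len(n)), status = status,
             geography = "unknown", species1 = species1, species2 = species2,
             habitat_isolation = y, sexual_isolation = sexual,
             fst_observed = NA_real_, nuc_divergence = NA_real_,
             fst_final = x, stringsAsFactors = FALSE)
}
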