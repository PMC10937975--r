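test_that("generation is byte-identical under a fixed seed", {
  g1 <- generate_dataset(synth_config(seed = 5))
  g2 <- generate_dataset(synth_config(seed = 5))
  expect_identical(g1$dataset$pairs, g2$dataset$pairs)
  expect_identical(g1$dataset$host_trials, g2$dataset$host_trials)
  expect_identical(g1$dataset$mating_trials, g2$dataset$mating_trials)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_dataset(synth_config(seed = 6))
  expect_false(identical(g1$truth$true_fst, g3$truth$true_fst))
})

test_that("degenerate config (all betas and SDs zero) gives constant truth", {
  cfg <- synth_config(betas_habitat = c(0.3, 0, 0, 0),
                      betas_sexual = c(0.2, 0, 0, 0),
                      random_effect_sd = 0, residual_sd = 0, seed = 2)
  g <- generate_dataset(cfg)
  expect_true(all(g$truth$true_habitat_isolation == 0.3))
  expect_true(all(g$truth$true_sexual_isolation == 0.2))
})

test_that("F_ST honors the status-specific ranges and pairs honor the design counts", {
  cfg <- synth_config(seed = 9)
  g <- generate_dataset(cfg)
  con <- g$truth$status == "conspecific"
  expect_equal(sum(con), 9)
  expect_equal(sum(!con), 27)
  expect_true(all(g$truth$true_fst[con] >= cfg$fst_within_range[1] &
                    g$truth$true_fst[con] <= cfg$fst_within_range[2]))
  expect_true(all(g$truth$true_fst[!con] >= cfg$fst_between_range[1] &
                    g$truth$true_fst[!con] <= cfg$fst_between_range[2]))
  # pair status is consistent with the species of its taxa
  expect_identical(g$dataset$pairs$status, g$truth$status)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_species = 2, populations_per_species = 2,
                            n_pairs = 10, frac_heterospecific = 0),
               "infeasible")
  expect_error(synth_config(n_species = 2, populations_per_species = 1,
                            n_pairs = 2, frac_heterospecific = 0.5),
               "infeasible")
})

test_that("boundary isolation values produce deterministic trial outcomes", {
  tr <- simulate_host_trials(1, 200, seed = 3)
  expect_equal(habitat_isolation(tr), 1)  # p1 = 1, p2 = 0 exactly
  mt <- simulate_mating_trials(1, 0.5, 200, seed = 4)
  cnt <- mating_counts(mt)
  expect_equal(sum(cnt$n_mated[c("het12", "het21")]), 0)
  expect_error(simulate_host_trials(1.2, 10), "\\[0, 1\\]")
  expect_error(simulate_mating_trials(-1.5, 0.5, 10), "outside")
})

test_that("estimators are consistent for large trial counts", {
  tr <- simulate_host_trials(0.55, 10000, none_rate = 0.05, seed = 11)
  expect_lt(abs(habitat_isolation(tr) - 0.55), 0.02)
  mt <- simulate_mating_trials(0.5, 0.5, 5000, seed = 12)
  expect_lt(abs(sexual_isolation(mating_counts(mt)) - 0.5), 0.05)
  # SI = 0: all four combinations share one probability
  mt0 <- simulate_mating_trials(0, 0.5, 5000, seed = 13)
  cnt <- mating_counts(mt0)
  expect_true(all(abs(cnt$n_mated / cnt$n_trials - 0.5) < 0.03))
})

test_that("per-pair substreams allow regenerating one pair without touching others", {
  g <- generate_dataset(synth_config(seed = 14))
  i <- 5
  tr <- g$truth[i, ]
  pair <- g$dataset$pairs[g$dataset$pairs$pair_id == tr$pair_id, ]
  regen <- simulate_host_trials(
    tr$true_habitat_isolation, g$config$host_trials_per_taxon,
    taxa = c(pair$taxon1, pair$taxon2), pair_id = tr$pair_id,
    none_rate = g$config$none_rate, seed = tr$pair_seed)
  orig <- g$dataset$host_trials[g$dataset$host_trials$pair_id == tr$pair_id, ]
  rownames(orig) <- rownames(regen) <- NULL
  expect_identical(regen, orig)
})

test_that("generator plus estimator is calibrated across many pairs", {
  # bias of the plug-in estimators, measured over 200 pairs; restricted to
  # truths away from the HI fold point at 0 where |p1-p2| is upward biased
  cfg <- synth_config(n_species = 20, populations_per_species = 4,
                      n_pairs = 200, frac_heterospecific = 0.5,
                      frac_pairs_with_mating = 1, seed = 15)
  g <- generate_dataset(cfg)
  est <- estimate_all_pairs(g$dataset)
  stopifnot(identical(est$pair_id, g$truth$pair_id))
  hi_ok <- g$truth$true_habitat_isolation > 0.2
  dh <- est$habitat_isolation[hi_ok] - g$truth$true_habitat_isolation[hi_ok]
  expect_gt(sum(hi_ok), 100)
  expect_lt(abs(mean(dh)), 3 * sd(dh) / sqrt(length(dh)) + 0.005)
  ds <- est$sexual_isolation - g$truth$true_sexual_isolation
  ds <- ds[!is.na(ds)]
  expect_gt(length(ds), 150)
  # ratio estimator carries small-sample bias at 15 trials/combination
  expect_lt(abs(mean(ds)), 0.06)
})

test_that("host-choice estimator bias at HI = 0 shrinks as trials grow", {
  # E|p1_hat - p2_hat| > 0 at true HI = 0, vanishing as n -> infinity
  set.seed(16)
  bias_at <- function(n) {
    mean(replicate(200, {
      habitat_isolation(simulate_host_trials(0, n))
    }))
  }
  b <- vapply(c(10, 40, 160, 640), bias_at, numeric(1))
  expect_true(all(diff(b) < 0))
  expect_lt(b[4], 0.05)
  # matches the analytic half-normal scale at the largest n
  expect_equal(b[4], sqrt(2 / pi) * sqrt(2 * 0.25 / 640), tolerance = 0.3)
})
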