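mk_host <- function(taxon, ref, alt, none = 0) {
  data.frame(pair_id = "p", taxon_id = taxon,
             choice = rep(c("reference", "alternative", "none"),
                          c(ref, alt, none)), stringsAsFactors = FALSE)
}

test_that("habitat isolation matches hand-computed proportions", {
  cases <- list(
    list(a = c(10, 10), b = c(10, 10), want = 0),     # identical preference
    list(a = c(20, 0), b = c(0, 20), want = 1),       # complete divergence
    list(a = c(15, 5), b = c(5, 20), want = 0.55))    # 0.75 - 0.20
  for (cs in cases) {
    tr <- rbind(mk_host("t1", cs$a[1], cs$a[2]), mk_host("t2", cs$b[1], cs$b[2]))
    expect_equal(habitat_isolation(tr), cs$want)
  }
})

test_that("no-choice trials are excluded before computing proportions", {
  tr <- rbind(mk_host("t1", 15, 5, none = 10), mk_host("t2", 5, 20, none = 3))
  expect_equal(habitat_isolation(tr), 0.55)
  # a taxon with only no-choice trials gives a missing estimate with reason
  tr2 <- rbind(mk_host("t1", 10, 10), mk_host("t2", 0, 0, none = 5))
  v <- habitat_isolation(tr2)
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "no_usable_trials")
})

test_that("habitat isolation is symmetric in taxa and in reference labeling", {
  tr <- rbind(mk_host("t1", 13, 7), mk_host("t2", 2, 17))
  flipped <- tr
  flipped$choice <- c(reference = "alternative", alternative = "reference",
                      none = "none")[tr$choice]
  expect_identical(habitat_isolation(tr), habitat_isolation(flipped))
  expect_identical(habitat_isolation(tr, taxa = c("t1", "t2")),
                   habitat_isolation(tr, taxa = c("t2", "t1")))
})

test_that("sexual isolation matches hand-computed pooled frequencies", {
  # random mating at 50% in all four combinations
  even <- new_mating_counts(rep(20, 4), rep(10, 4))
  expect_equal(sexual_isolation(even), 0)
  # complete assortment: f_homo = 0.7, f_het = 0
  complete <- new_mating_counts(rep(10, 4), c(7, 7, 0, 0))
  expect_equal(sexual_isolation(complete), 1)
  # pooled homotypic 14/20, heterotypic 7/20 -> 1 - 0.35/0.70
  half <- new_mating_counts(rep(10, 4), c(7, 7, 4, 3))
  expect_equal(sexual_isolation(half), 0.5)
  # disassortative mating goes negative
  dis <- new_mating_counts(rep(10, 4), c(2, 2, 8, 8))
  expect_equal(sexual_isolation(dis), 1 - 0.8 / 0.2)
})

test_that("sexual isolation is undefined when f_homo is zero or a category is missing", {
  v <- sexual_isolation(new_mating_counts(rep(10, 4), c(0, 0, 3, 2)))
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "f_homo_zero")
  v2 <- sexual_isolation(new_mating_counts(c(10, 10, 0, 0), c(5, 5, 0, 0)))
  expect_equal(attr(v2, "reason"), "missing_combination")
})

test_that("sexual isolation decreases monotonically in the heterotypic mating count", {
  vals <- vapply(0:20, function(k)
    sexual_isolation(new_mating_counts(rep(10, 4), c(7, 7, min(k, 10),
                                                     max(k - 10, 0)))),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("pooled and directional-mean conventions differ only under unbalanced designs", {
  bal <- new_mating_counts(rep(10, 4), c(7, 7, 4, 3))
  expect_equal(sexual_isolation(bal, "pooled"),
               sexual_isolation(bal, "directional_mean"))
  unbal <- new_mating_counts(c(30, 10, 10, 30), c(24, 5, 4, 12))
  expect_equal(sexual_isolation(unbal, "pooled"),
               1 - (16 / 40) / (29 / 40))
  expect_equal(sexual_isolation(unbal, "directional_mean"),
               1 - mean(c(4 / 10, 12 / 30)) / mean(c(24 / 30, 5 / 10)))
})

test_that("the uncertainty posterior is seed-deterministic and consistent in the large-count limit", {
  cnt <- new_mating_counts(rep(20, 4), c(14, 14, 7, 7))
  d1 <- sexual_isolation_posterior(cnt, n_draws = 500, seed = 7)
  d2 <- sexual_isolation_posterior(cnt, n_draws = 500, seed = 7)
  expect_identical(d1, d2)
  expect_length(d1, 500)
  # scaling all counts by 100 concentrates the posterior on the plug-in index
  big <- new_mating_counts(rep(2000, 4), c(1400, 1400, 700, 700))
  med <- median(sexual_isolation_posterior(big, n_draws = 8000, seed = 1))
  expect_lt(abs(med - 0.5), 0.02)
  expect_error(sexual_isolation_posterior(cnt, n_draws = 0), "positive")
})

test_that("with no data the posterior is prior-wide and spans zero", {
  none <- new_mating_counts(rep(0, 4), rep(0, 4))
  d <- sexual_isolation_posterior(none, n_draws = 4000, seed = 2)
  q <- quantile(d, c(0.025, 0.975))
  expect_lt(q[1], 0)
  expect_gt(q[2], 0.5)
})

test_that("estimate_all_pairs records missing estimates instead of failing", {
  ds <- toy_dataset()
  est <- estimate_all_pairs(ds)
  expect_equal(nrow(est), 3)
  expect_equal(est$habitat_isolation, c(0.55, 1, 0))
  expect_equal(est$sexual_isolation[est$pair_id == "pA"], 0.5)
  expect_true(all(is.na(est$sexual_isolation[est$pair_id != "pA"])))
  expect_equal(est$si_reason[est$pair_id == "pB"], "no_trials")
  # no mating table at all
  ds2 <- ri_dataset(toy_pairs(), toy_host_trials(), NULL)
  est2 <- estimate_all_pairs(ds2)
  expect_true(all(is.na(est2$sexual_isolation)))
})

test_that("a study-shaped dataset yields 42 habitat and 30 sexual estimates", {
  cfg <- synth_config(n_species = 9, populations_per_species = 3,
                      n_pairs = 42, frac_heterospecific = 26 / 42,
                      frac_pairs_with_mating = 30 / 42, seed = 21)
  g <- generate_dataset(cfg)
  est <- estimate_all_pairs(g$dataset)
  expect_equal(nrow(est), 42)
  expect_equal(sum(!is.na(est$habitat_isolation)), 42)
  expect_equal(sum(!is.na(est$sexual_isolation)), 30)
  expect_equal(sum(is.na(est$sexual_isolation)), 12)
})
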