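test_that("model data retains the study subsets and builds the incidence matrix", {
  g <- generate_dataset(synth_config(seed = 42))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  dh <- build_model_data(est, "habitat")
  ds <- build_model_data(est, "sexual")
  expect_equal(dh$n, 36)
  expect_equal(ds$n, 27)
  # every pair loads exactly two population-slots onto species
  expect_true(all(rowSums(dh$Z) == 2))
  con <- dh$x_taxon == 0
  expect_true(all(apply(dh$Z[con, , drop = FALSE], 1, max) == 2))
  expect_true(all(apply(dh$Z[!con, , drop = FALSE], 1, max) == 1))
  # distances standardized over exactly the retained subset
  expect_lt(abs(mean(dh$x_gen)), 1e-12)
  expect_lt(abs(sd(dh$x_gen) - 1), 1e-12)
  # alternative conspecific encoding
  d1 <- build_model_data(est, "habitat", mm_spec(conspecific_coef = 1))
  expect_true(all(rowSums(d1$Z[d1$x_taxon == 0, , drop = FALSE]) == 1))
})

test_that("the interaction flag requires both main effects and burnin must precede n_iter", {
  expect_error(mm_spec(include_gen = FALSE, include_interaction = TRUE),
               "main effects")
  expect_error(mm_spec(burnin = 5000, n_iter = 5000), "burnin")
})

test_that("defaults give 2 chains of 800 retained draws with all parameters named", {
  g <- generate_dataset(synth_config(seed = 8))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  dat <- build_model_data(est, "habitat")
  ch <- gibbs_sample(dat, mm_spec(seed = 4))
  expect_length(ch, 2)
  expect_equal(nrow(ch[[1]]), 800)
  expect_true(all(c("intercept", "beta_gen", "beta_taxon", "beta_int",
                    "sigma2_resid", "sigma2_lambda") %in% colnames(ch[[1]])))
  expect_equal(sum(startsWith(colnames(ch[[1]]), "lambda_")), 9)
  # deterministic under the same master seed
  ch2 <- gibbs_sample(dat, mm_spec(seed = 4))
  expect_identical(ch, ch2)
})

test_that("the Gibbs posterior matches the closed-form conjugate posterior", {
  set.seed(3)
  n <- 60; x <- rnorm(n)
  y <- 0.5 + 0.8 * x + rnorm(n, 0, 0.5)
  est <- fake_estimates(y, x)
  tau <- 4; tau_b <- 0.001
  sp <- mm_spec(include_taxon = FALSE, include_interaction = FALSE,
                include_random = FALSE, fixed_resid_prec = tau,
                n_iter = 21000, burnin = 1000, thin = 4, seed = 5)
  dat <- build_model_data(est, "habitat", sp)
  pooled <- do.call(rbind, gibbs_sample(dat, sp))
  V <- solve(tau * crossprod(dat$X) + tau_b * diag(2))
  m <- drop(V %*% (tau * crossprod(dat$X, dat$y)))
  for (k in 1:2) {
    mcse <- sd(pooled[, k]) / sqrt(coda::effectiveSize(pooled[, k]))
    expect_lt(abs(mean(pooled[, k]) - m[k]), 3 * mcse)
    expect_lt(abs(sd(pooled[, k]) - sqrt(V[k, k])), 0.05 * sqrt(V[k, k]))
  }
})

test_that("with a constant response the genetic-distance effect is centered at zero", {
  set.seed(6)
  est <- fake_estimates(rep(0.4, 30), runif(30))
  sp <- quick_spec(include_taxon = FALSE, include_interaction = FALSE,
                   include_random = FALSE, seed = 2)
  fit <- fit_ri_model(build_model_data(est, "habitat", sp), sp)
  bg <- fit$summary[fit$summary$parameter == "beta_gen", ]
  expect_lt(bg$etpi95_lower, 0)
  expect_gt(bg$etpi95_upper, 0)
  expect_lt(abs(bg$median), 0.05)
})

test_that("posterior summaries use equal-tail type-7 quantiles and pooled P(>0)", {
  set.seed(12)
  draws <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "theta"))
  s <- summarize_posterior(list(draws[1:50000, , drop = FALSE],
                                draws[50001:1e5, , drop = FALSE]))
  expect_equal(s$etpi95_lower, -1.96, tolerance = 0.03)
  expect_equal(s$etpi95_upper, 1.96, tolerance = 0.03)
  expect_equal(s$p_gt0, 0.5, tolerance = 0.01)
  pos <- matrix(abs(rnorm(200)) + 0.01, ncol = 1,
                dimnames = list(NULL, "theta"))
  expect_equal(summarize_posterior(list(pos, pos))$p_gt0, 1.0)
  # pooling is invariant to permuting draws within chains
  perm <- draws[sample(nrow(draws)), , drop = FALSE]
  s1 <- summarize_posterior(list(draws))
  s2 <- summarize_posterior(list(perm))
  expect_equal(s1$median, s2$median)
  expect_equal(s1$etpi90_lower, s2$etpi90_lower)
  expect_equal(s1$p_gt0, s2$p_gt0)
})

test_that("relabeling species permutes random effects but not fixed-effect posteriors", {
  g <- generate_dataset(synth_config(seed = 19))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  sp <- quick_spec(seed = 9)
  f1 <- fit_ri_model(build_model_data(est, "habitat", sp), sp)
  # bijective relabeling of species ids
  relabel <- function(s) paste0("taxon_", toupper(s))
  est2 <- est
  est2$species1 <- relabel(est$species1)
  est2$species2 <- relabel(est$species2)
  f2 <- fit_ri_model(build_model_data(est2, "habitat", sp), sp)
  fx <- c("intercept", "beta_gen", "beta_taxon", "beta_int")
  s1 <- f1$summary[match(fx, f1$summary$parameter), c("median", "mean",
                                                      "etpi95_lower",
                                                      "etpi95_upper")]
  s2 <- f2$summary[match(fx, f2$summary$parameter), c("median", "mean",
                                                      "etpi95_lower",
                                                      "etpi95_upper")]
  expect_equal(s1, s2, tolerance = 1e-10)
  # lambda draws are identical up to the renaming
  l1 <- f1$chains[[1]][, paste0("lambda_", colnames(f1$data$Z))]
  l2 <- f2$chains[[1]][, paste0("lambda_", relabel(colnames(f1$data$Z)))]
  expect_equal(unname(l1), unname(l2), tolerance = 1e-12)
})

test_that("DIC is deterministic and its deviance decomposition is consistent", {
  g <- generate_dataset(synth_config(seed = 23))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  sp <- quick_spec(seed = 31)
  dat <- build_model_data(est, "habitat", sp)
  ch <- gibbs_sample(dat, sp)
  d1 <- compute_dic(ch, dat)
  d2 <- compute_dic(gibbs_sample(dat, sp), dat)
  expect_identical(d1, d2)
  expect_equal(d1$dic, d1$mean_deviance + d1$pD)
  expect_gt(d1$pD, 0)
})

test_that("PSRF distinguishes well-mixed from separated chains and grows with separation", {
  set.seed(14)
  mk <- function(mu) matrix(rnorm(2000, mu), ncol = 1,
                            dimnames = list(NULL, "theta"))
  same <- psrf(list(mk(0), mk(0)))
  expect_gt(same$per_parameter[["theta"]], 0.99)
  expect_lt(same$per_parameter[["theta"]], 1.05)
  apart <- psrf(list(mk(0), mk(10)))
  expect_gt(apart$per_parameter[["theta"]], 3)
  seps <- c(0, 0.5, 1, 2, 4)
  rhats <- vapply(seps, function(s) {
    set.seed(100)
    psrf(list(mk(0), mk(s)))$per_parameter[["theta"]]
  }, numeric(1))
  expect_true(all(diff(rhats) > 0))
  expect_error(psrf(list(mk(0))), "2 chains")
})

test_that("the sampler agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  g <- generate_dataset(synth_config(seed = 11))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  sp <- mm_spec(seed = 3, n_iter = 41000, burnin = 1000, thin = 5)
  dat <- build_model_data(est, "habitat", sp)
  mine <- colMeans(do.call(rbind, gibbs_sample(dat, sp))[, 1:4])

  model_str <- "model{
    for (p in 1:n) {
      mu[p] <- inprod(X[p,], beta) + inprod(Z[p,], lambda)
      y[p] ~ dnorm(mu[p], tau_e)
    }
    for (k in 1:4) { beta[k] ~ dnorm(0, 0.001) }
    for (s in 1:S) { lambda[s] ~ dnorm(0, tau_l) }
    tau_e ~ dgamma(1, 0.01)
    tau_l ~ dgamma(1, 0.01)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = dat$y, X = dat$X, Z = dat$Z,
                                      n = dat$n, S = ncol(dat$Z)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 4000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", n.iter = 40000, thin = 10,
                              progress.bar = "none")
  theirs <- summary(samp)$statistics[, "Mean"]
  ts_se <- summary(samp)$statistics[, "Time-series SE"]
  for (k in 1:4)
    expect_lt(abs(mine[k] - theirs[k]), 4 * ts_se[k] + 0.01)
})

test_that("the five-model suite shares data, ranks by DIC, and keeps full summaries", {
  g <- generate_dataset(synth_config(seed = 37))
  est <- add_final_fst(estimate_all_pairs(g$dataset))
  suite <- fit_model_suite(est, "habitat", quick_spec(seed = 5))
  expect_equal(nrow(suite$table), 5)
  expect_setequal(suite$table$model,
                  c("full", "no_interaction", "genetic_only", "taxon_only",
                    "null"))
  expect_true(!is.unsorted(suite$table$dic))
  expect_equal(suite$table$rank, 1:5)
  ids <- lapply(suite$fits, function(f) f$data$pair_id)
  expect_length(unique(ids), 1)
  expect_s3_class(suite$fits$null$summary, "mm_posterior_summary")
  expect_false("beta_gen" %in% suite$fits$null$summary$parameter)
})
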