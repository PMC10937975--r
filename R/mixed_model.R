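#' Specification of the Bayesian pairwise mixed model
#'
#' Defines which fixed effects enter the model for reproductive isolation
#' as a function of genetic distance, along with priors and MCMC settings.
#' The full model is
#' \deqn{RI_{ij} = \beta_0 + \beta_{gen} x^{gen}_{ij} + \beta_{taxon}
#'   x^{taxon}_{ij} + \beta_{int} x^{gen}_{ij} x^{taxon}_{ij} +
#'   \lambda_i + \lambda_j + \epsilon_{ij}}
#' where \eqn{x^{gen}} is standardized genetic distance, \eqn{x^{taxon}}
#' indicates a heterospecific pair (0 conspecific / 1 heterospecific),
#' and the \eqn{\lambda}s are crossed random effects of the species to
#' which the pair's two populations belong. Because each pair contributes
#' \eqn{\lambda_i + \lambda_j}, a conspecific pair loads twice on its
#' single species (coefficient 2); set `conspecific_coef = 1` for the
#' alternative encoding.
#'
#' Priors: normal(0, precision `beta_prec` = 0.001) on every regression
#' coefficient, gamma(shape 1, rate 0.01) on the residual precision and on
#' the random-effect precision. Defaults run 2 chains of 5000 iterations
#' with 1000 burn-in and thinning 5, giving 800 retained draws per chain.
#'
#' @param include_gen Include the genetic-distance slope.
#' @param include_taxon Include the taxonomic-status effect.
#' @param include_interaction Include the distance-by-status interaction
#'   (requires both main effects).
#' @param include_random Include the crossed species random effects.
#' @param conspecific_coef Incidence coefficient a conspecific pair puts
#'   on its single species: 2 (default, literal \eqn{\lambda_i+\lambda_j})
#'   or 1.
#' @param beta_prec Prior precision of regression coefficients.
#' @param resid_prior,re_prior Length-2 vectors `c(shape, rate)` of the
#'   gamma priors on the residual and random-effect precisions.
#' @param n_chains,n_iter,burnin,thin MCMC settings.
#' @param seed Master seed; per-chain seeds are derived by fixed offsets.
#' @param fixed_resid_prec If non-`NULL`, the residual precision is held
#'   fixed at this value instead of being sampled (used for analytic
#'   validation).
#' @return Object of class `mm_spec`.
#' @export
mm_spec <- function(include_gen = TRUE, include_taxon = TRUE,
                    include_interaction = TRUE, include_random = TRUE,
                    conspecific_coef = 2,
                    beta_prec = 0.001,
                    resid_prior = c(1, 0.01), re_prior = c(1, 0.01),
                    n_chains = 2, n_iter = 5000, burnin = 1000, thin = 5,
                    seed = 1, fixed_resid_prec = NULL) {
  if (include_interaction && !(include_gen && include_taxon))
    stop("the interaction requires both main effects", call. = FALSE)
  if (burnin >= n_iter) stop("burnin must be < n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  stopifnot(conspecific_coef %in% c(1, 2), n_chains >= 1)
  structure(list(include_gen = include_gen, include_taxon = include_taxon,
                 include_interaction = include_interaction,
                 include_random = include_random,
                 conspecific_coef = conspecific_coef,
                 beta_prec = beta_prec,
                 resid_prior = resid_prior, re_prior = re_prior,
                 n_chains = n_chains, n_iter = n_iter, burnin = burnin,
                 thin = thin, seed = seed,
                 fixed_resid_prec = fixed_resid_prec),
            class = "mm_spec")
}

#' Assemble model data for one response
#'
#' Drops pairs with a missing response or missing final genetic distance,
#' standardizes the genetic distances over exactly the retained subset,
#' and builds the fixed-effect design matrix and the species incidence
#' matrix (entries 0/1/2 counting how many of the pair's populations
#' belong to each species; rows sum to 2 under the default encoding).
#'
#' @param estimates Per-pair estimates with columns `fst_final`,
#'   `species1`, `species2`, `status` and the response column
#'   (`habitat_isolation` or `sexual_isolation`).
#' @param response `"habitat"` or `"sexual"`.
#' @param spec An [mm_spec()].
#' @return Object of class `mm_data`: list with `y`, `X`, `Z`, `terms`
#'   (column labels of `X`), `species` (column labels of `Z`), `pair_id`,
#'   `n`, `x_gen` (standardized distances), `x_taxon`, and the
#'   standardization parameters `std` (mean, sd).
#' @export
build_model_data <- function(estimates, response = c("habitat", "sexual"),
                             spec = mm_spec()) {
  response <- match.arg(response)
  ycol <- if (response == "habitat") "habitat_isolation" else "sexual_isolation"
  if (!"fst_final" %in% names(estimates))
    stop("estimates lack fst_final; run add_final_fst() first", call. = FALSE)
  keep <- !is.na(estimates[[ycol]]) & !is.na(estimates$fst_final)
  d <- estimates[keep, , drop = FALSE]
  if (nrow(d) < 5)
    stop("fewer than 5 pairs with both ", ycol, " and genetic distance",
         call. = FALSE)
  if (any(!is.finite(d[[ycol]])))
    stop("non-finite response values", call. = FALSE)
  std <- standardize_distances(d$fst_final)
  x_gen <- std$values
  x_taxon <- as.numeric(d$status == "heterospecific")

  X <- matrix(1, nrow(d), 1); terms <- "intercept"
  if (spec$include_gen) { X <- cbind(X, x_gen); terms <- c(terms, "beta_gen") }
  if (spec$include_taxon) { X <- cbind(X, x_taxon); terms <- c(terms, "beta_taxon") }
  if (spec$include_interaction) {
    X <- cbind(X, x_gen * x_taxon); terms <- c(terms, "beta_int")
  }
  colnames(X) <- terms

  # order of first appearance, not lexicographic: keeps the Gibbs update
  # sequence (and hence the exact draws) invariant to species relabeling
  species <- unique(as.vector(rbind(d$species1, d$species2)))
  Z <- matrix(0, nrow(d), length(species),
              dimnames = list(NULL, species))
  for (i in seq_len(nrow(d))) {
    if (d$species1[i] == d$species2[i]) {
      Z[i, d$species1[i]] <- spec$conspecific_coef
    } else {
      Z[i, d$species1[i]] <- 1
      Z[i, d$species2[i]] <- 1
    }
  }
  structure(list(y = d[[ycol]], X = X, Z = Z, terms = terms,
                 species = species, pair_id = d$pair_id, n = nrow(d),
                 x_gen = x_gen, x_taxon = x_taxon,
                 std = list(mean = std$mean, sd = std$sd),
                 response = response),
            class = "mm_data")
}

chain_seed <- function(master, chain) (master + 104729L * chain) %% 2147483647L

#' Draw posterior samples by blocked Gibbs sampling
#'
#' Runs the conjugate Gibbs sampler: a joint multivariate-normal update
#' for the fixed effects, scalar normal updates for each species random
#' effect, and gamma updates for the residual and random-effect
#' precisions. Fixed effects are initialized at the least-squares
#' solution, random effects at zero, precisions at 1. Chains are
#' deterministic given the spec's master seed (per-chain seeds are the
#' master seed plus fixed offsets).
#'
#' @param data An `mm_data` from [build_model_data()].
#' @param spec An [mm_spec()].
#' @return List of `n_chains` matrices (class `mm_chains`), each with one
#'   row per retained draw and named columns: the fixed effects, one
#'   `lambda_<species>` per species, `sigma2_resid`, `sigma2_lambda`.
#' @export
gibbs_sample <- function(data, spec = mm_spec()) {
  stopifnot(inherits(data, "mm_data") || is.list(data))
  y <- data$y; X <- data$X; Z <- data$Z
  if (any(!is.finite(y))) stop("non-finite response", call. = FALSE)
  p <- ncol(X)
  S <- if (spec$include_random) ncol(Z) else 0L
  # ridge-stabilized least-squares start (prior precision as ridge)
  beta_init <- drop(solve(crossprod(X) + spec$beta_prec * diag(p),
                          crossprod(X, y)))
  fixed <- if (is.null(spec$fixed_resid_prec)) -1 else spec$fixed_resid_prec
  cn <- c(data$terms,
          if (S > 0) paste0("lambda_", colnames(Z)),
          "sigma2_resid", if (S > 0) "sigma2_lambda")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  chains <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    set.seed(chain_seed(spec$seed, ch))
    draws <- gibbs_lmm_cpp(y, X, if (S > 0) Z else matrix(0, length(y), 0),
                           spec$beta_prec,
                           spec$resid_prior[1], spec$resid_prior[2],
                           spec$re_prior[1], spec$re_prior[2],
                           spec$n_iter, spec$burnin, spec$thin,
                           as.numeric(beta_init), fixed, S > 0)
    if (S == 0) draws <- draws[, seq_len(p + 1), drop = FALSE]
    colnames(draws) <- cn
    chains[[ch]] <- draws
  }
  structure(chains, class = "mm_chains")
}

#' Summarize posterior chains
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior median and mean, 95% and 90% equal-tail probability
#' intervals (type-7 quantiles), the posterior probability of exceeding
#' zero, the effective sample size, and the per-parameter Gelman-Rubin
#' PSRF (when at least two chains are available).
#'
#' @param chains An `mm_chains` object (or plain list of draw matrices).
#' @return Data frame with one row per parameter, class
#'   `mm_posterior_summary`.
#' @export
summarize_posterior <- function(chains) {
  chains <- as_chain_list(chains)
  if (any(vapply(chains, nrow, 1L) == 0))
    stop("empty chains", call. = FALSE)
  pooled <- do.call(rbind, chains)
  qs <- function(v, p) unname(quantile(v, p, type = 7, na.rm = TRUE))
  out <- data.frame(
    parameter = colnames(pooled),
    median = apply(pooled, 2, median, na.rm = TRUE),
    mean = colMeans(pooled),
    etpi95_lower = apply(pooled, 2, qs, 0.025),
    etpi95_upper = apply(pooled, 2, qs, 0.975),
    etpi90_lower = apply(pooled, 2, qs, 0.05),
    etpi90_upper = apply(pooled, 2, qs, 0.95),
    p_gt0 = colMeans(pooled > 0),
    ess = as.numeric(coda::effectiveSize(coda::as.mcmc(pooled))),
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(chains) >= 2 && nrow(chains[[1]]) >= 50) {
    rh <- psrf(chains)
    out$psrf <- rh$per_parameter[out$parameter]
  } else {
    out$psrf <- NA_real_
  }
  class(out) <- c("mm_posterior_summary", "data.frame")
  out
}

as_chain_list <- function(chains) {
  if (inherits(chains, "mm_chains")) chains <- unclass(chains)
  if (is.matrix(chains)) chains <- list(chains)
  stopifnot(is.list(chains), length(chains) >= 1)
  chains
}

#' Gelman-Rubin convergence diagnostics
#'
#' Classic per-parameter potential scale reduction factors and the
#' Brooks-Gelman multivariate PSRF, computed over all sampled parameters
#' with non-zero variance. Values near 1 indicate convergence; values
#' above ~1.1 indicate inadequate mixing.
#'
#' @param chains An `mm_chains` object or list of >= 2 equal-length draw
#'   matrices with >= 50 rows.
#' @return List with `multivariate` (scalar, `NA` if the between-chain
#'   covariance is singular) and `per_parameter` (named vector).
#' @export
psrf <- function(chains) {
  chains <- as_chain_list(chains)
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  len <- vapply(chains, nrow, 1L)
  if (length(unique(len)) != 1 || len[1] < 50)
    stop("chains must have equal lengths >= 50", call. = FALSE)
  # drop constant / all-NA columns (e.g. sigma2_lambda with no random effects)
  keep <- apply(do.call(rbind, chains), 2, function(v)
    all(is.finite(v)) && var(v) > 0)
  ml <- coda::mcmc.list(lapply(chains, function(m)
    coda::mcmc(m[, keep, drop = FALSE])))
  per <- tryCatch({
    g <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE,
                           transform = FALSE)
    setNames(g$psrf[, "Point est."], rownames(g$psrf))
  }, error = function(e) stop("PSRF computation failed: ",
                              conditionMessage(e), call. = FALSE))
  multi <- tryCatch({
    g <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = TRUE,
                           transform = FALSE)
    unname(g$mpsrf)
  }, error = function(e) NA_real_)
  list(multivariate = multi, per_parameter = per)
}

deviance_gauss <- function(y, mu, sigma2) {
  -2 * sum(dnorm(y, mu, sqrt(sigma2), log = TRUE))
}

#' Deviance information criterion of a fitted model
#'
#' DIC = mean deviance + pD, with the effective number of parameters
#' pD = mean deviance - deviance at the posterior means (the classic
#' Spiegelhalter definition; posterior means of the fixed effects, random
#' effects and residual variance are plugged in). The deviance is
#' -2 times the Gaussian log-likelihood of the response given the linear
#' predictor and residual variance. Lower DIC indicates better expected
#' predictive fit.
#'
#' @param chains An `mm_chains` object from [gibbs_sample()].
#' @param data The `mm_data` the chains were sampled for.
#' @return List with `dic`, `pD`, `mean_deviance`.
#' @export
compute_dic <- function(chains, data) {
  chains <- as_chain_list(chains)
  pooled <- do.call(rbind, chains)
  p <- ncol(data$X)
  has_re <- "sigma2_lambda" %in% colnames(pooled) &&
    any(startsWith(colnames(pooled), "lambda_"))
  lam_cols <- grep("^lambda_", colnames(pooled))
  sigma2 <- pooled[, "sigma2_resid"]
  if (any(sigma2 <= 0)) stop("non-positive variance draw", call. = FALSE)
  beta <- pooled[, seq_len(p), drop = FALSE]
  mu <- data$X %*% t(beta)
  if (has_re && length(lam_cols))
    mu <- mu + data$Z %*% t(pooled[, lam_cols, drop = FALSE])
  # deviance per retained draw
  dev <- vapply(seq_len(nrow(pooled)), function(i)
    deviance_gauss(data$y, mu[, i], sigma2[i]), numeric(1))
  mean_dev <- mean(dev)
  mu_bar <- drop(data$X %*% colMeans(beta))
  if (has_re && length(lam_cols))
    mu_bar <- mu_bar + drop(data$Z %*% colMeans(pooled[, lam_cols, drop = FALSE]))
  d_at_mean <- deviance_gauss(data$y, mu_bar, mean(sigma2))
  pD <- mean_dev - d_at_mean
  list(dic = mean_dev + pD, pD = pD, mean_deviance = mean_dev)
}

#' Fit one model: sample, summarize, diagnose
#'
#' @param data An `mm_data` from [build_model_data()].
#' @param spec An [mm_spec()].
#' @return Object of class `ri_fit`: list with `spec`, `data`, `chains`,
#'   `summary`, `dic` (list), `psrf` (list).
#' @export
fit_ri_model <- function(data, spec = mm_spec()) {
  chains <- gibbs_sample(data, spec)
  summ <- summarize_posterior(chains)
  dic <- compute_dic(chains, data)
  diag <- if (spec$n_chains >= 2) psrf(chains) else
    list(multivariate = NA_real_, per_parameter = NULL)
  structure(list(spec = spec, data = data, chains = chains,
                 summary = summ, dic = dic, psrf = diag),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Bayesian pairwise mixed model (%s isolation, n = %d pairs)\n",
              x$data$response, x$data$n))
  cat(sprintf("  DIC = %.2f (pD = %.2f), multivariate PSRF = %.3f\n",
              x$dic$dic, x$dic$pD, x$psrf$multivariate))
  fx <- x$summary[x$summary$parameter %in% x$data$terms, ]
  for (i in seq_len(nrow(fx)))
    cat(sprintf("  %-12s median %7.3f  95%% ETPI [%.3f, %.3f]  P(>0) = %.3f\n",
                fx$parameter[i], fx$median[i], fx$etpi95_lower[i],
                fx$etpi95_upper[i], fx$p_gt0[i]))
  invisible(x)
}

MODEL_SUITE <- list(
  full = c(gen = TRUE, taxon = TRUE, int = TRUE),
  no_interaction = c(gen = TRUE, taxon = TRUE, int = FALSE),
  genetic_only = c(gen = TRUE, taxon = FALSE, int = FALSE),
  taxon_only = c(gen = FALSE, taxon = TRUE, int = FALSE),
  null = c(gen = FALSE, taxon = FALSE, int = FALSE)
)

#' Fit the five-model suite and rank by DIC
#'
#' Fits the full model and its four submodels (no interaction; genetic
#' distance only; taxonomic status only; intercept plus random effects
#' only) on the identical data subset, with per-model seeds derived from
#' one master seed, and ranks them by ascending DIC.
#'
#' @param estimates Per-pair estimates with `fst_final` (see
#'   [add_final_fst()]).
#' @param response `"habitat"` or `"sexual"`.
#' @param spec Base [mm_spec()]; its inclusion flags are overridden per
#'   model, everything else (priors, MCMC settings, seed) is shared.
#' @return Object of class `ri_model_suite`: list with `table` (data
#'   frame: model, dic, pD, mean_deviance, mpsrf, rank; ordered by DIC)
#'   and `fits` (named list of `ri_fit`s).
#' @export
fit_model_suite <- function(estimates, response = c("habitat", "sexual"),
                            spec = mm_spec()) {
  response <- match.arg(response)
  data_full <- build_model_data(estimates, response, spec)
  fits <- list()
  for (i in seq_along(MODEL_SUITE)) {
    nm <- names(MODEL_SUITE)[i]
    fl <- MODEL_SUITE[[i]]
    sp <- spec
    sp$include_gen <- unname(fl["gen"])
    sp$include_taxon <- unname(fl["taxon"])
    sp$include_interaction <- unname(fl["int"])
    sp$seed <- (spec$seed + 7919L * i) %% 2147483647L
    dat <- build_model_data(estimates, response, sp)
    stopifnot(identical(dat$pair_id, data_full$pair_id))
    fits[[nm]] <- fit_ri_model(dat, sp)
  }
  tab <- data.frame(
    model = names(fits),
    dic = vapply(fits, function(f) f$dic$dic, numeric(1)),
    pD = vapply(fits, function(f) f$dic$pD, numeric(1)),
    mean_deviance = vapply(fits, function(f) f$dic$mean_deviance, numeric(1)),
    mpsrf = vapply(fits, function(f) f$psrf$multivariate, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$dic), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, response = response,
                 n = data_full$n),
            class = "ri_model_suite")
}

#' @export
print.ri_model_suite <- function(x, ...) {
  cat(sprintf("Model suite for %s isolation (n = %d pairs), ranked by DIC:\n",
              x$response, x$n))
  print(x$table, digits = 4)
  invisible(x)
}
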