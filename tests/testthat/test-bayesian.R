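# Two-state Bayesian arm: 2 examined x 2 concealed states, a uniform prior
# on the global sampling fraction, adaptive MCMC and stepping-stone marginal
# likelihoods. Chains and ladders here are kept short; the vignette
# documents the full-scale settings.

two_state_etd <- function() {
  generating_mode("ETD", c(0.1, 0.5), 0.001, 0.4)
}

sim_two_state <- function(n = 1, seed = 61, band = c(100, 250)) {
  sample_tree_set(two_state_etd(), 13.4, band, n, seed = seed,
                  n_examined = 2L, n_concealed = 2L)
}

test_that("sf_prior validates its support", {
  pr <- sf_prior(0.3, 0.9)
  expect_equal(pr$lower, 0.3)
  expect_error(sf_prior(0, 0.9))
  expect_error(sf_prior(0.5, 1.2))
  expect_error(sf_prior(0.7, 0.5))
})

test_that("log_posterior = loglik + log prior, -Inf outside support", {
  tr <- sim_two_state(band = c(20, 120))[[1]]
  model <- two_state_model("dependent")
  prior <- sf_prior(0.5, 0.7)
  free <- c(0.1, 0.5, 0.01, 0.4)
  rho <- 0.6
  settings <- likelihood_settings(rho = c(rho, rho))
  lp <- log_posterior(free, rho, tr, model, prior)
  ll <- loglik_model(tr, model, free, settings = settings)
  expect_equal(lp - ll, ssesim:::bayes_log_prior(free, rho, prior),
               tolerance = 1e-10)
  expect_identical(log_posterior(free, 0.45, tr, model, prior), -Inf)
  expect_identical(log_posterior(free, 0.75, tr, model, prior), -Inf)
  expect_identical(log_posterior(c(-0.1, 0.5, 0.01, 0.4), 0.6, tr, model,
                                 prior), -Inf)
})

test_that("prior-only MCMC recovers the uniform prior on rho (KS test)", {
  tr <- sim_two_state(band = c(10, 60))[[1]]
  model <- two_state_model("dependent")
  prior <- sf_prior(0.3, 0.9)
  post <- run_mcmc(tr, model, prior, n_iter = 16000, seed = 5, power = 0)
  rho <- post$chain$rho
  thinned <- rho[seq(1, length(rho), by = 25)]
  ks <- suppressWarnings(
    stats::ks.test(thinned, "punif", prior$lower, prior$upper))
  expect_gt(ks$p.value, 0.01)
  # rates marginally follow their exponential priors too
  lam <- post$chain[[1]][seq(1, nrow(post$chain), by = 25)]
  ks2 <- suppressWarnings(stats::ks.test(lam, "pexp", 1))
  expect_gt(ks2$p.value, 0.01)
})

test_that("same seed reproduces the chain; acceptance rates are sane", {
  tr <- sim_two_state(band = c(20, 100))[[1]]
  model <- two_state_model("dependent")
  prior <- sf_prior(0.5, 0.7)
  a <- run_mcmc(tr, model, prior, n_iter = 300, seed = 9)
  b <- run_mcmc(tr, model, prior, n_iter = 300, seed = 9)
  expect_identical(a$chain, b$chain)
  expect_true(all(a$accept_rate > 0 & a$accept_rate < 1))
  expect_true(all(a$ess > 1))
})

test_that("posterior on a trimmed two-state CR dataset brackets the truth", {
  cr2 <- generating_mode("CR", 0.3, 0.001, 0.4)
  tr <- sample_tree_set(cr2, 13.4, c(150, 250), 1, seed = 67,
                        n_examined = 2L, n_concealed = 2L)[[1]]
  trimmed <- random_trim(tr, 0.6, seed = 2)$tree
  model <- two_state_model("dependent")
  prior <- sf_prior(0.5, 0.7) # truth 0.6 inside
  post <- run_mcmc(trimmed, model, prior, n_iter = 1200, seed = 13,
                   settings_base = likelihood_settings(
                     rho = c(1, 1), ode_rel_tol = 1e-6, ode_abs_tol = 1e-8))
  m <- colMeans(post$chain[, 1:4])
  expect_lt(abs(m[["lambda1"]] - 0.3), 0.1)
  expect_lt(abs(m[["lambda2"]] - 0.3), 0.1)
})

test_that("stepping stone is exact for a constant likelihood", {
  const <- -3.7
  out <- stepping_stone_logml(function(theta) const,
                              function(theta) stats::dnorm(theta, log = TRUE),
                              init = 0, K = 5, n_iter = 200, burnin = 50,
                              seed = 1)
  expect_equal(out$logml, const, tolerance = 1e-12)
})

test_that("stepping stone matches the closed-form Gaussian evidence", {
  # prior N(0,1), likelihood N(y = 0 | theta, sigma):
  # evidence = N(0; 0, sqrt(1 + sigma^2))
  sigma <- 0.5
  log_lik <- function(theta) stats::dnorm(0, theta, sigma, log = TRUE)
  log_prior <- function(theta) stats::dnorm(theta, log = TRUE)
  exact <- stats::dnorm(0, 0, sqrt(1 + sigma^2), log = TRUE)
  out <- stepping_stone_logml(log_lik, log_prior, init = 0, K = 10,
                              n_iter = 1500, burnin = 300, seed = 3)
  expect_lt(abs(out$logml - exact), 3 * out$se)
  # ladder refinement changes the estimate by little
  out2 <- stepping_stone_logml(log_lik, log_prior, init = 0, K = 30,
                               n_iter = 1500, burnin = 300, seed = 4)
  expect_lt(abs(out$logml - out2$logml),
            2 * sqrt(out$se^2 + out2$se^2) + 0.02)
})

test_that("bayes_factor_select applies the conservative tie rule", {
  expect_equal(bayes_factor_select(-100, -100)$selected, "independent")
  sel <- bayes_factor_select(-97.5, -100)
  expect_equal(sel$selected, "dependent")
  expect_equal(sel$two_delta, 5)
  expect_error(bayes_factor_select(Inf, -100))
})

test_that("narrow-prior runs detect trait dependence on trimmed ETD data", {
  # scaled-down version of the study's Bayesian arm: 3 two-state ETD
  # datasets at 60% random sampling; dependent vs independent model by
  # stepping-stone Bayes factors under narrow and wide SF priors
  trees <- sim_two_state(3, seed = 71)
  narrow <- sf_prior(0.5, 0.7)
  wide <- sf_prior(0.3, 0.9)
  settings <- likelihood_settings(rho = c(1, 1), ode_rel_tol = 1e-6,
                                  ode_abs_tol = 1e-8)
  run_one <- function(tr, prior, seed) {
    dep <- stepping_stone_sse(tr, two_state_model("dependent"), prior,
                              K = 8, n_iter = 350, burnin = 100, seed = seed,
                              settings_base = settings)
    ind <- stepping_stone_sse(tr, two_state_model("independent"), prior,
                              K = 8, n_iter = 350, burnin = 100,
                              seed = seed + 1, settings_base = settings)
    bayes_factor_select(dep, ind)$selected
  }
  sel_narrow <- character(0)
  sel_wide <- character(0)
  for (i in seq_along(trees)) {
    trimmed <- random_trim(trees[[i]], 0.6, seed = derive_seed(83, i))$tree
    sel_narrow <- c(sel_narrow, run_one(trimmed, narrow, 100 + 10 * i))
    sel_wide <- c(sel_wide, run_one(trimmed, wide, 200 + 10 * i))
  }
  expect_gte(sum(sel_narrow == "dependent"), 2)
  # narrow priors never detect dependence less often than wide ones
  expect_gte(sum(sel_narrow == "dependent"), sum(sel_wide == "dependent"))
})
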