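test_that("tip initial conditions implement the per-state sampling fraction", {
  nm <- state_names()
  # complete sampling, tip in state 2
  ic <- tip_initial_conditions(2, likelihood_settings(rho = c(1, 1, 1)))
  expect_equal(ic$E, rep(0, 9))
  expect_equal(stats::setNames(ic$D, nm)[c("2A", "2B", "2C")], c(`2A` = 1, `2B` = 1, `2C` = 1))
  expect_equal(sum(ic$D), 3)
  # uniform rho = 0.6, tip in state 1
  ic <- tip_initial_conditions(1, likelihood_settings(rho = rep(0.6, 3)))
  expect_equal(unique(ic$E), 0.4)
  expect_equal(stats::setNames(ic$D, nm)[c("1A", "1B", "1C")], c(`1A` = 0.6, `1B` = 0.6, `1C` = 0.6))
  expect_equal(sum(ic$D > 0), 3)
  # per-state rho: E carries each state's own examined-trait rho
  ic <- tip_initial_conditions(3, likelihood_settings(rho = c(1, 1, 0.5)))
  E <- stats::setNames(ic$E, nm)
  expect_equal(unname(E[c("3A", "3B", "3C")]), rep(0.5, 3))
  expect_equal(unname(E[c("1A", "2B", "2C")]), rep(0, 3))
})

test_that("branch integration matches closed forms and the expm oracle", {
  # pure birth, q = 0: E stays 0 and D_i(t) = D_i(0) exp(-lambda_i t)
  lam <- c(0.1, 0.3, 0.5)[state_examined(1:9)]
  p <- sse_params(lam, 0, 0)
  init <- list(E = rep(0, 9), D = rep(1, 9))
  out <- integrate_branch(init, p, 2.0)
  expect_equal(out$E, rep(0, 9), tolerance = 1e-10)
  expect_equal(out$D, exp(-lam * 2.0), tolerance = 1e-7)
  # lambda = mu = 0: D follows the 9-state Markov backward equation
  p0 <- sse_params(rep(0, 9), 0, 0.4)
  skip_if_not_installed("Matrix")
  D0 <- c(1, 0, 0, 0, 0.5, 0, 0, 0, 0.25)
  out <- integrate_branch(list(E = rep(0, 9), D = D0), p0, 2.5)
  Qm <- p0$Q
  diag(Qm) <- -rowSums(Qm)
  Dex <- as.vector(Matrix::expm(Matrix::Matrix(t(Qm) * 2.5)) %*% D0)
  expect_lt(max(abs(out$D - Dex) / pmax(abs(Dex), 1e-12)), 1e-6)
  # zero length is the identity
  out <- integrate_branch(init, p, 0)
  expect_identical(out$E, init$E)
  expect_identical(out$D, init$D)
})

test_that("E is bounded in [0, 1], and non-decreasing from E(0) = 0", {
  # monotonicity holds under complete sampling (E starts at 0 and climbs to
  # its fixed point); with rho < 1 the initial value 1 - rho can sit above
  # the fixed point mu / lambda, and E then decreases toward it -- so only
  # boundedness is asserted there
  p <- expand_generating_mode(etd_mode(0.05))
  lens <- seq(0, 12, by = 0.5)
  s1 <- likelihood_settings(rho = rep(1, 3))
  init <- tip_initial_conditions(1, s1)
  Es <- t(vapply(lens, function(t) integrate_branch(init, p, t, s1)$E,
                 numeric(9)))
  expect_true(all(Es >= -1e-10 & Es <= 1 + 1e-10))
  expect_true(all(diff(Es) >= -1e-8))
  s6 <- likelihood_settings(rho = rep(0.6, 3))
  init <- tip_initial_conditions(1, s6)
  Es <- t(vapply(lens, function(t) integrate_branch(init, p, t, s6)$E,
                 numeric(9)))
  expect_true(all(Es >= -1e-10 & Es <= 1 + 1e-10))
})

test_that("combine_at_node multiplies partials and checks E agreement", {
  p <- sse_params(rep(1, 9), 0, 0.1)
  a <- list(E = rep(0.2, 9), D = (1:9) / 10)
  b <- list(E = rep(0.2, 9), D = rep(0.5, 9))
  out <- combine_at_node(a, b, p)
  expect_equal(out$D, unname(a$D * b$D)) # lambda_i = 1: elementwise product
  expect_equal(out$E, a$E)
  b$D <- rep(0, 9)
  expect_equal(combine_at_node(a, b, p)$D, rep(0, 9))
  b$E <- rep(0.9, 9)
  expect_error(combine_at_node(a, b, p), "disagree")
})

test_that("two-tip pure-birth tree matches the hand-derived closed form", {
  lam <- 0.3
  T <- 7
  p <- expand_generating_mode(generating_mode("CR", lam, 0, 0))
  phy <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);", T, T))
  s <- likelihood_settings(condition_on_survival = FALSE,
                           root_weighting = "equal")
  ll <- loglik_sse(phy, p, c(t1 = 1L, t2 = 1L), s)
  # D_root = lambda e^{-2 lambda T} in each compatible state; equal weights
  # over 9 states, 3 compatible
  expect_equal(ll, log(3 / 9 * lam * exp(-2 * lam * T)), tolerance = 1e-6)
})

test_that("CR likelihood factorizes into birth-death x Mk", {
  tr <- sample_tree_set(etd_mode(), 13.4, c(100, 250), 1, seed = 11)[[1]]
  lam <- 0.28
  mu <- 0.03
  q <- 0.35
  for (rho in c(1, 0.6)) {
    p <- expand_generating_mode(generating_mode("CR", lam, mu, q))
    s <- likelihood_settings(rho = rep(rho, 3), root_weighting = "equal")
    ll <- loglik_sse(tr, p, settings = s)
    oracle <- bd_loglik_oracle(tr$phy, lam, mu, rho) +
      mk_loglik_oracle(tr$phy, examined_states(tr), q)
    expect_lt(abs(ll - oracle), 1e-5)
  }
})

test_that("likelihood is continuous in rho near 1", {
  p <- expand_generating_mode(etd_mode())
  tr <- sample_tree_set(etd_mode(), 10, c(30, 120), 1, seed = 3)[[1]]
  l1 <- loglik_sse(tr, p, settings = likelihood_settings(rho = rep(1, 3)))
  l2 <- loglik_sse(tr, p,
                   settings = likelihood_settings(rho = rep(1 - 1e-6, 3)))
  expect_lt(abs(l1 - l2), 1e-3)
})

test_that("likelihood is invariant to concealed-label permutations", {
  tr <- sample_tree_set(etd_mode(), 10, c(30, 120), 1, seed = 19)[[1]]
  states <- examined_states(tr)
  perms <- list(c(2, 3, 1), c(3, 2, 1), c(2, 1, 3))
  for (mode in list(etd_mode(0.05), cr_mode(0.05))) {
    p <- expand_generating_mode(mode)
    base <- loglik_sse(tr, p, states,
                       settings = likelihood_settings(rho = rep(0.8, 3)))
    for (perm in perms) {
      i <- seq_len(9)
      newi <- state_index(state_examined(i), perm[state_concealed(i)])
      pp <- p
      pp$lambda[newi] <- p$lambda[i]
      pp$mu[newi] <- p$mu[i]
      ll <- loglik_sse(tr, pp, states,
                       settings = likelihood_settings(rho = rep(0.8, 3)))
      expect_equal(ll, base, tolerance = 1e-7)
    }
  }
})

test_that("ETD and CTD collapse to CR when the three rates coincide", {
  tr <- sample_tree_set(etd_mode(), 10, c(30, 120), 1, seed = 23)[[1]]
  s <- likelihood_settings(rho = rep(0.6, 3))
  free <- c(0.3, 0.3, 0.3, 0.02, 0.4)
  ll_etd <- loglik_model(tr, model_spec("ETD"), free, settings = s)
  ll_ctd <- loglik_model(tr, model_spec("CTD"), free, settings = s)
  ll_cr <- loglik_model(tr, model_spec("CR"), c(0.3, 0.02, 0.4), settings = s)
  expect_equal(ll_etd, ll_cr, tolerance = 1e-7)
  expect_equal(ll_ctd, ll_cr, tolerance = 1e-7)
})

test_that("full likelihood matches the dense plain-R oracle on tiny trees", {
  p <- expand_generating_mode(etd_mode(0.05))
  s <- likelihood_settings(rho = c(0.9, 0.7, 0.8))
  trees <- list(
    list(phy = balanced4(), states = c(t1 = 1L, t2 = 2L, t3 = 3L, t4 = 1L)),
    list(phy = caterpillar4(), states = c(t1 = 2L, t2 = 2L, t3 = 1L, t4 = 3L)),
    list(phy = ape::read.tree(text = "((t1:0.5,t2:0.5):1.5,t3:2);"),
         states = c(t1 = 1L, t2 = 3L, t3 = 2L)))
  for (tc in trees) {
    ll <- loglik_sse(tc$phy, p, tc$states, s)
    oracle <- sse_loglik_oracle_R(tc$phy, tc$states, p, s, h = 5e-4)
    expect_lt(abs(ll - oracle) / abs(oracle), 1e-6)
  }
})
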