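#' Uniform prior on the sampling fraction
#'
#' @param lower,upper bounds of a uniform prior on the global sampling
#'   fraction rho, 0 < lower < upper <= 1. The study's wide prior is
#'   U(0.3, 0.9) and its narrow prior U(0.5, 0.7).
#' @export
sf_prior <- function(lower, upper) {
  stopifnot(lower > 0, lower < upper, upper <= 1)
  structure(list(lower = lower, upper = upper), class = "sf_prior")
}

#' Two-state Bayesian arm model
#'
#' The reduced system has two examined and two concealed states. The
#' "dependent" model is the two-state examined-trait-dependent
#' parameterization (free: lambda_1, lambda_2, mu, q), the "independent"
#' model ties speciation to the concealed trait instead.
#'
#' @param name `"dependent"` or `"independent"`.
#' @return a [model_spec()] over the 2 x 2 state system.
#' @export
two_state_model <- function(name = c("dependent", "independent")) {
  name <- match.arg(name)
  model_spec(if (name == "dependent") "ETD" else "CTD",
             n_examined = 2L, n_concealed = 2L)
}

#' Log-posterior of the two-state model with a sampling-fraction prior
#'
#' Likelihood (with rho applied to both observed states) plus log-priors:
#' exponential(mean 1) on speciation and extinction rates, exponential(mean
#' 0.5) on the transition rate, uniform on rho. Outside the prior support the
#' value is `-Inf`.
#'
#' @param free rate vector `(lambda_a, lambda_b, mu, q)` of the model.
#' @param rho global sampling fraction.
#' @param tree,states data (2-state examined states).
#' @param model a [two_state_model()].
#' @param prior an [sf_prior()].
#' @param settings_base template [likelihood_settings()] (rho is overridden).
#' @export
log_posterior <- function(free, rho, tree, model, prior, states = NULL,
                          settings_base = likelihood_settings(rho = c(1, 1))) {
  if (rho < prior$lower || rho > prior$upper || any(free <= 0)) return(-Inf)
  settings <- settings_base
  settings$rho <- rep(rho, model$n_examined)
  ll <- loglik_model(tree, model, free, states, settings)
  ll + bayes_log_prior(free, rho, prior)
}

bayes_log_prior <- function(free, rho, prior) {
  if (rho < prior$lower || rho > prior$upper || any(free <= 0)) return(-Inf)
  n <- length(free)
  sum(stats::dexp(free[seq_len(n - 1)], rate = 1, log = TRUE)) +
    stats::dexp(free[n], rate = 2, log = TRUE) +
    stats::dunif(rho, prior$lower, prior$upper, log = TRUE)
}

# Internal: adaptive Metropolis-within-Gibbs on an unconstrained vector.
# log_target(theta, power) must return power * loglik + logprior (with
# Jacobians); returns list(chain, loglik, accept_rate, scales).
mwg_sampler <- function(log_target, log_lik, init, n_iter, burnin,
                        scales = NULL, adapt = TRUE) {
  d <- length(init)
  if (is.null(scales)) scales <- rep(0.3, d)
  theta <- init
  lt <- log_target(theta)
  ll <- log_lik(theta)
  chain <- matrix(NA_real_, n_iter, d)
  lls <- numeric(n_iter)
  acc <- integer(d)
  prop <- integer(d)
  batch_acc <- integer(d)
  batch <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      cand <- theta
      cand[j] <- cand[j] + stats::rnorm(1, 0, scales[j])
      ltc <- log_target(cand)
      prop[j] <- prop[j] + 1L
      if (is.finite(ltc) && log(stats::runif(1)) < ltc - lt) {
        theta <- cand
        lt <- ltc
        ll <- log_lik(theta)
        acc[j] <- acc[j] + 1L
        batch_acc[j] <- batch_acc[j] + 1L
      }
    }
    batch <- batch + 1L
    if (adapt && it <= burnin && batch == 50L) {
      rate <- batch_acc / 50
      scales <- scales * exp(0.5 * (rate - 0.44))
      batch_acc[] <- 0L
      batch <- 0L
    }
    chain[it, ] <- theta
    lls[it] <- ll
  }
  list(chain = chain, loglik = lls, accept_rate = acc / pmax(prop, 1L),
       scales = scales)
}

#' Posterior sampling for the two-state model
#'
#' Adaptive Metropolis-within-Gibbs on log-rates and logit-transformed rho
#' (rescaled to the prior support). `power` tempers the likelihood
#' (`power = 0` samples the prior, used by the stepping-stone ladder and by
#' the prior-recovery diagnostics).
#'
#' @param tree,model,prior,states,settings_base as in [log_posterior()].
#' @param n_iter chain length (post-burn-in draws are
#'   `n_iter - burnin`).
#' @param burnin adaptation window, default `n_iter %/% 4`.
#' @param seed integer seed; same seed gives an identical chain.
#' @param power likelihood tempering exponent in `[0, 1]`.
#' @param init optional starting rates `(lambda_a, lambda_b, mu, q, rho)`.
#' @return object of class `posterior_sample`: `chain` (data.frame of
#'   natural-scale parameters incl. rho and log-likelihood), `accept_rate`,
#'   `ess`, `scales`, `burnin`.
#' @export
run_mcmc <- function(tree, model, prior, states = NULL, n_iter = 2000L,
                     burnin = n_iter %/% 4L, seed = NULL, power = 1,
                     init = NULL,
                     settings_base = likelihood_settings(rho = c(1, 1))) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(states) && inherits(tree, "clade_tree")) {
    states <- examined_states(tree)
  }
  d <- model$n_lambda + 3L # rates + mu + q... (n_lambda lambdas, mu, q) + rho
  to_theta <- function(rates, rho) {
    z <- (rho - prior$lower) / (prior$upper - prior$lower)
    c(log(rates), stats::qlogis(z))
  }
  from_theta <- function(theta) {
    k <- length(theta)
    list(rates = exp(theta[-k]),
         rho = prior$lower +
           (prior$upper - prior$lower) * stats::plogis(theta[k]))
  }
  cache <- new.env()
  log_lik <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!is.null(cache$k) && identical(cache$k, key)) return(cache$v)
    p <- from_theta(theta)
    settings <- settings_base
    settings$rho <- rep(p$rho, model$n_examined)
    v <- if (power == 0) 0 else
      loglik_model(tree, model, p$rates, states, settings)
    cache$k <- key
    cache$v <- v
    v
  }
  log_target <- function(theta) {
    p <- from_theta(theta)
    lp <- bayes_log_prior(p$rates, p$rho, prior)
    if (!is.finite(lp)) return(-Inf)
    k <- length(theta)
    jac <- sum(theta[-k]) +
      log(prior$upper - prior$lower) + stats::dlogis(theta[k], log = TRUE)
    ll <- if (power == 0) 0 else power * log_lik(theta)
    ll + lp + jac
  }
  if (is.null(init)) {
    init <- c(rep(0.2, model$n_lambda), 0.05, 0.2,
              (prior$lower + prior$upper) / 2)
  }
  theta0 <- to_theta(init[-length(init)], init[length(init)])
  out <- mwg_sampler(log_target, log_lik, theta0, n_iter, burnin)
  nat <- t(apply(out$chain, 1, function(th) {
    p <- from_theta(th)
    c(p$rates, p$rho)
  }))
  colnames(nat) <- c(model$param_names, "rho")
  keep <- seq.int(burnin + 1L, n_iter)
  if (all(out$accept_rate == 0)) {
    warning("all proposals rejected after adaptation: tuning failure")
  }
  chain <- data.frame(nat, loglik = out$loglik, check.names = FALSE)
  structure(list(chain = chain[keep, ], full_chain = chain,
                 accept_rate = out$accept_rate,
                 ess = apply(nat[keep, , drop = FALSE], 2, ess_numeric),
                 scales = out$scales, burnin = burnin),
            class = "posterior_sample")
}

# initial-positive-sequence effective sample size estimate
ess_numeric <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  maxlag <- min(n - 1L, 200L)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' Stepping-stone marginal likelihood
#'
#' Importance-weighted estimate of the log marginal likelihood over a ladder
#' of power posteriors `0 = beta_0 < ... < beta_K = 1` (powers at quantiles
#' of Beta(alpha, 1), the usual stepping-stone placement). Each rung's chain
#' is warm-started from the previous rung. The standard error aggregates the
#' per-rung delta-method variances of the log importance weights.
#'
#' Generic interface: supply `log_lik(theta)` and `log_prior(theta)` over an
#' unconstrained parameterization (Jacobians inside `log_prior`), plus an
#' initial point. [stepping_stone_sse()] wraps this for the two-state model.
#'
#' @param log_lik,log_prior functions of the unconstrained parameter vector.
#' @param init starting parameter vector.
#' @param K number of stones (ladder has K + 1 powers).
#' @param alpha Beta shape for ladder placement.
#' @param n_iter,burnin per-rung chain length and adaptation window.
#' @param seed integer seed.
#' @param scales initial proposal scales.
#' @return object of class `stepping_stone`: `logml`, `se`, `powers`,
#'   `per_rung` data.frame.
#' @export
stepping_stone_logml <- function(log_lik, log_prior, init, K = 50L,
                                 alpha = 0.3, n_iter = 500L, burnin = 100L,
                                 seed = NULL, scales = NULL) {
  if (!is.null(seed)) set.seed(seed)
  powers <- (seq(0, K) / K)^(1 / alpha)
  theta <- init
  logml <- 0
  var_sum <- 0
  per_rung <- list()
  sc <- scales
  for (k in seq_len(K)) {
    beta_k <- powers[k]
    log_target <- function(th) {
      lp <- log_prior(th)
      if (!is.finite(lp)) return(-Inf)
      if (beta_k == 0) lp else lp + beta_k * log_lik(th)
    }
    out <- mwg_sampler(log_target, log_lik, theta, n_iter, burnin,
                       scales = sc)
    sc <- out$scales
    theta <- out$chain[nrow(out$chain), ]
    ll <- out$loglik[seq.int(burnin + 1L, n_iter)]
    dbeta_k <- powers[k + 1L] - beta_k
    m <- max(ll)
    w <- exp(dbeta_k * (ll - m))
    log_rk <- dbeta_k * m + log(mean(w))
    v <- stats::var(w) / (length(w) * mean(w)^2)
    logml <- logml + log_rk
    var_sum <- var_sum + v
    per_rung[[k]] <- data.frame(beta = beta_k, dbeta = dbeta_k,
                                log_ratio = log_rk, n = length(ll))
  }
  structure(list(logml = logml, se = sqrt(var_sum), powers = powers,
                 per_rung = do.call(rbind, per_rung)),
            class = "stepping_stone")
}

#' @rdname stepping_stone_logml
#' @param tree,model,prior,states,settings_base as in [run_mcmc()].
#' @param ... passed through to `stepping_stone_logml`.
#' @export
stepping_stone_sse <- function(tree, model, prior, states = NULL, ...,
                               settings_base = likelihood_settings(rho = c(1, 1))) {
  if (is.null(states) && inherits(tree, "clade_tree")) {
    states <- examined_states(tree)
  }
  from_theta <- function(theta) {
    k <- length(theta)
    list(rates = exp(theta[-k]),
         rho = prior$lower +
           (prior$upper - prior$lower) * stats::plogis(theta[k]))
  }
  log_lik <- local({
    last_key <- NULL
    last_val <- NULL
    function(theta) {
      key <- paste(theta, collapse = ",")
      if (identical(key, last_key)) return(last_val)
      p <- from_theta(theta)
      settings <- settings_base
      settings$rho <- rep(p$rho, model$n_examined)
      v <- loglik_model(tree, model, p$rates, states, settings)
      last_key <<- key
      last_val <<- v
      v
    }
  })
  log_prior <- function(theta) {
    p <- from_theta(theta)
    lp <- bayes_log_prior(p$rates, p$rho, prior)
    if (!is.finite(lp)) return(-Inf)
    k <- length(theta)
    lp + sum(theta[-k]) + log(prior$upper - prior$lower) +
      stats::dlogis(theta[k], log = TRUE)
  }
  init <- c(log(c(rep(0.2, model$n_lambda), 0.05, 0.2)), 0)
  stepping_stone_logml(log_lik, log_prior, init, ...)
}

#' Bayes-factor model choice
#'
#' The model with the larger log marginal likelihood wins; an exact tie
#' selects the independent model (conservative against false detection of
#' trait-dependent diversification). Reports `2 * (logML_dep - logML_ind)`.
#'
#' @param logml_dependent,logml_independent log marginal likelihoods (numbers
#'   or `stepping_stone` objects).
#' @return list with `selected` and `two_delta`.
#' @export
bayes_factor_select <- function(logml_dependent, logml_independent) {
  v <- function(x) if (inherits(x, "stepping_stone")) x$logml else x
  d <- v(logml_dependent)
  i <- v(logml_independent)
  stopifnot(is.finite(d), is.finite(i))
  list(selected = if (d > i) "dependent" else "independent",
       two_delta = 2 * (d - i))
}
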