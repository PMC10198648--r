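#' Maximum-likelihood fit of one model parameterization
#'
#' Derivative-free (Nelder-Mead) maximization of the hidden-state SSE
#' log-likelihood over log-transformed rates, box-bounded in
#' `[lower, upper]` (bounds enforced by a smooth penalty). The first cycle
#' starts at generating-magnitude heuristics (speciation at the Yule estimate
#' `log(N/2) / crown_age`, extinction at a tenth of that, q at 0.1); up to
#' `max_cycles - 1` restart cycles re-perturb the best point found so far and
#' the fit is declared converged once a cycle improves the log-likelihood by
#' less than `cycle_tol`. Non-finite likelihood evaluations are treated as
#' rejected points.
#'
#' @param tree a `clade_tree` or `phylo`.
#' @param model a [model_spec()].
#' @param states named examined-state vector (defaults to the tree's own).
#' @param settings a [likelihood_settings()].
#' @param seed integer seed controlling the restart jitter (same seed, same
#'   `fit_result`).
#' @param control list: `max_cycles` (default 10), `cycle_tol` (1e-6),
#'   `maxit` per Nelder-Mead run (500), `lower` / `upper` rate bounds
#'   (1e-6, 10), `jitter_sd` on the log scale (0.5).
#' @return object of class `fit_result`: `model`, `mle` (named rates), `lnL`,
#'   `k`, `aicc`, `n_used` (tip count), `converged`, `n_cycles_used`.
#' @export
fit_model <- function(tree, model, states = NULL,
                      settings = likelihood_settings(), seed = NULL,
                      control = list()) {
  ctl <- utils::modifyList(list(max_cycles = 10L, cycle_tol = 1e-6,
                                maxit = 500L, lower = 1e-6, upper = 10,
                                jitter_sd = 0.5), control)
  if (!is.null(seed)) set.seed(seed)
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  n <- ape::Ntip(phy)
  if (n <= model$k + 1L) {
    stop(sprintf("tree has %d tips; model %s needs more than k + 1 = %d",
                 n, model$name, model$k + 1L), call. = FALSE)
  }
  if (is.null(states)) states <- examined_states(tree)
  lb <- log(ctl$lower)
  ub <- log(ctl$upper)
  negll <- function(theta) {
    if (any(theta < lb) || any(theta > ub)) {
      return(1e8 + 1e4 * sum(pmax(lb - theta, 0)^2 + pmax(theta - ub, 0)^2))
    }
    ll <- loglik_model(tree, model, exp(theta), states, settings)
    if (!is.finite(ll)) return(1e8)
    -ll
  }
  depths <- ape::node.depth.edgelength(phy)
  age <- max(depths[seq_len(n)])
  lam0 <- max(log(n / 2) / age, 2 * ctl$lower)
  start <- log(pmin(pmax(c(rep(lam0, model$n_lambda), lam0 / 10, 0.1),
                         2 * ctl$lower), ub / 2))
  best <- NULL
  n_cycles <- 0L
  converged <- FALSE
  for (cycle in seq_len(ctl$max_cycles)) {
    n_cycles <- cycle
    init <- if (cycle == 1L) start else
      pmin(pmax(best$par + stats::rnorm(length(start), 0, ctl$jitter_sd), lb), ub)
    opt <- tryCatch(
      stats::optim(init, negll, method = "Nelder-Mead",
                   control = list(maxit = ctl$maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e8) {
      if (cycle == 1L) next else next
    }
    if (is.null(best) || opt$value < best$value) {
      improvement <- if (is.null(best)) Inf else best$value - opt$value
      best <- opt
      if (cycle > 1L && improvement < ctl$cycle_tol) {
        converged <- TRUE
        break
      }
    } else if (!is.null(best)) {
      converged <- TRUE # restart failed to improve beyond tolerance
      break
    }
  }
  if (is.null(best)) {
    return(structure(list(model = model$name, mle = NULL, lnL = -Inf,
                          k = model$k, aicc = Inf, n_used = n,
                          converged = FALSE, n_cycles_used = n_cycles),
                     class = "fit_result"))
  }
  mle <- stats::setNames(exp(best$par), model$param_names)
  lnL <- -best$value
  structure(list(model = model$name, mle = mle, lnL = lnL, k = model$k,
                 aicc = aicc(lnL, model$k, n), n_used = n,
                 converged = converged, n_cycles_used = n_cycles),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AICc = %.4f (n = %d, %s, %d cycles)\n",
              x$model, x$lnL, x$k, x$aicc, x$n_used,
              if (x$converged) "converged" else "NOT converged",
              x$n_cycles_used))
  if (!is.null(x$mle)) print(round(x$mle, 5))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 lnL + 2k + 2k(k + 1) / (n - k - 1)`; infinite when the
#' correction denominator is not positive.
#' @param lnL log-likelihood. @param k free-parameter count. @param n sample
#'   size (tip count of the fitted tree, by this package's convention).
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#' @param aiccs numeric vector of at least 2 AICc values, at least one of
#'   them finite; infinite entries (failed fits) get weight 0.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) < 2 || !any(is.finite(aiccs))) {
    stop("need at least 2 AICc values with a finite minimum")
  }
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w[!is.finite(aiccs)] <- 0
  w / sum(w)
}

#' Select the best model by AICc
#'
#' Lowest AICc wins; exact ties break toward the smaller parameter count and
#' then by the fixed order CR < CTD < ETD < ECTD (conservative against false
#' detection of trait-dependence). Non-converged fits are excluded with a
#' warning.
#'
#' @param fits list of `fit_result` objects (at least 2 converged).
#' @return list with `best` (model name) and `weights` (named Akaike
#'   weights over the converged fits).
#' @export
select_best <- function(fits) {
  names(fits) <- vapply(fits, `[[`, "", "model")
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aicc),
                 logical(1))
  if (any(!conv)) {
    warning("excluding non-converged fits: ",
            paste(names(fits)[!conv], collapse = ", "))
  }
  fits <- fits[conv]
  if (length(fits) < 2) stop("need at least 2 converged fits")
  a <- vapply(fits, `[[`, 0, "aicc")
  k <- vapply(fits, `[[`, 0, "k")
  name_order <- match(names(fits), c("CR", "CTD", "ETD", "ECTD"))
  best <- names(fits)[order(a, k, name_order)][1]
  list(best = best, weights = stats::setNames(akaike_weights(a), names(fits)))
}
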