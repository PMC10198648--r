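#' Likelihood settings
#'
#' Bundles the observation model and numerical knobs of the hidden-state SSE
#' likelihood: per-examined-state sampling fractions rho, whether to condition
#' on survival of both crown lineages, the root state weighting, and ODE
#' tolerances for the branch integration.
#'
#' @param rho per-examined-state sampling fractions in (0, 1].
#' @param condition_on_survival divide the root likelihood by
#'   `lambda_i (1 - E_i)^2` per state (crown conditioning). Default TRUE.
#' @param root_weighting `"fitzjohn"` (likelihood-proportional weights,
#'   computed before conditioning), `"equal"`, or `"fixed"` (supply
#'   `root_probs`).
#' @param root_probs fixed root state probabilities (length S) when
#'   `root_weighting = "fixed"`.
#' @param ode_rel_tol,ode_abs_tol tolerances of the adaptive branch
#'   integrator.
#' @return object of class `likelihood_settings`.
#' @export
likelihood_settings <- function(rho = c(1, 1, 1), condition_on_survival = TRUE,
                                root_weighting = c("fitzjohn", "equal",
                                                   "fixed"),
                                root_probs = NULL, ode_rel_tol = 1e-8,
                                ode_abs_tol = 1e-10) {
  root_weighting <- match.arg(root_weighting)
  stopifnot(all(rho > 0), all(rho <= 1), ode_rel_tol > 0, ode_abs_tol > 0)
  if (root_weighting == "fixed" && is.null(root_probs)) {
    stop("root_weighting = 'fixed' needs root_probs")
  }
  structure(list(rho = rho, condition_on_survival = condition_on_survival,
                 root_weighting = root_weighting, root_probs = root_probs,
                 ode_rel_tol = ode_rel_tol, ode_abs_tol = ode_abs_tol),
            class = "likelihood_settings")
}

#' Tip initial conditions
#'
#' Sampling fractions enter the likelihood only here: for combined state i,
#' `E_i(0) = 1 - rho[examined(i)]` and `D_i(0) = rho[observed]` when
#' `examined(i)` equals the observed state (0 otherwise).
#'
#' @param observed_state observed examined state of the tip.
#' @param settings a [likelihood_settings()] whose `rho` has one entry per
#'   examined state.
#' @param n_examined,n_concealed trait state counts.
#' @return list with numeric vectors `E` and `D` of length S.
#' @export
tip_initial_conditions <- function(observed_state, settings,
                                   n_examined = 3L, n_concealed = 3L) {
  rho <- settings$rho
  stopifnot(length(rho) == n_examined,
            observed_state %in% seq_len(n_examined))
  S <- n_examined * n_concealed
  ex <- state_examined(seq_len(S), n_examined)
  E <- 1 - rho[ex]
  D <- ifelse(ex == observed_state, rho[observed_state], 0)
  list(E = as.numeric(E), D = as.numeric(D))
}

#' Integrate the E/D system along a branch
#'
#' Propagates extinction probabilities and partial likelihoods rootward over
#' a branch of the given length using the adaptive Dormand-Prince integrator.
#' A zero-length branch returns the input unchanged.
#'
#' @param init list with `E` and `D` (e.g. from [tip_initial_conditions()]).
#' @param params an [sse_params()].
#' @param length branch length in MY (>= 0).
#' @param settings a [likelihood_settings()].
#' @return list with propagated `E` and `D`.
#' @export
integrate_branch <- function(init, params, length,
                             settings = likelihood_settings()) {
  stopifnot(length >= 0)
  if (length == 0) return(init[c("E", "D")])
  out <- sse_branch_cpp(init$E, init$D, params$lambda, params$mu, params$Q,
                        length, settings$ode_rel_tol, settings$ode_abs_tol)
  if (!isTRUE(out$ok)) {
    stop(errorCondition(
      sprintf("branch integration failed (length %.4g)", length),
      class = c("ssesim_numerical_failure", "error", "condition")))
  }
  list(E = out$E, D = out$D)
}

#' Merge the two child branches at a node
#'
#' Standard SSE node merge: `D_i = lambda_i * D_i(left) * D_i(right)`; the two
#' children's E vectors must agree (same time point) and pass through as
#' their average.
#'
#' @param left,right lists with `E` and `D` at the node-side end of each
#'   child branch.
#' @param params an [sse_params()].
#' @param e_tol tolerance for the E-agreement precondition.
#' @return list with merged `E` and `D`.
#' @export
combine_at_node <- function(left, right, params, e_tol = 1e-6) {
  if (max(abs(left$E - right$E)) > e_tol) {
    stop("E vectors of the two children disagree: not the same time point")
  }
  list(E = (left$E + right$E) / 2,
       D = unname(params$lambda * left$D * right$D))
}

#' Hidden-state SSE log-likelihood of a tree with examined-state tip data
#'
#' Post-order pruning over the tree, integrating the E/D system branch by
#' branch (underflow is controlled by per-branch rescaling, with the log
#' factors accumulated into the result). At the root, with per-state weights
#' w_i given by the root weighting, the likelihood is
#' `sum_i w_i D_i / (lambda_i (1 - E_i)^2)` under survival conditioning, or
#' `sum_i w_i D_i` without. The concealed trait is never observed; only the
#' examined states of the tips enter.
#'
#' @param tree a `clade_tree` or an `ape` `phylo`.
#' @param states named integer vector (tip label -> examined state); defaults
#'   to the tree's own examined states.
#' @param params an [sse_params()].
#' @param settings a [likelihood_settings()].
#' @return log-likelihood (natural log); `-Inf` on numerical failure.
#' @export
loglik_sse <- function(tree, params, states = NULL,
                       settings = likelihood_settings()) {
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  if (is.null(states)) {
    stopifnot(inherits(tree, "clade_tree"))
    states <- examined_states(tree)
  }
  ne <- params$n_examined
  nc <- params$n_concealed
  S <- ne * nc
  stopifnot(length(settings$rho) == ne)
  labs <- phy$tip.label
  if (!all(labs %in% names(states))) stop("every tip needs an observed state")
  obs <- as.integer(states[labs])
  if (anyNA(obs) || any(obs < 1 | obs > ne)) stop("invalid examined states")
  ex <- state_examined(seq_len(S), ne)
  ntip <- ape::Ntip(phy)
  tipD <- matrix(0, ntip, S)
  for (tp in seq_len(ntip)) {
    tipD[tp, ex == obs[tp]] <- settings$rho[obs[tp]]
  }
  tipE <- 1 - settings$rho[ex]
  po <- ape::reorder.phylo(phy, "postorder")
  root_mode <- match(settings$root_weighting, c("fitzjohn", "equal", "fixed")) - 1L
  root_probs <- if (is.null(settings$root_probs)) rep(1 / S, S) else
    settings$root_probs
  out <- sse_loglik_cpp(po$edge, po$edge.length, ntip, tipD, tipE,
                        params$lambda, params$mu, params$Q,
                        settings$ode_rel_tol, settings$ode_abs_tol,
                        settings$condition_on_survival, root_mode,
                        as.numeric(root_probs))
  if (!isTRUE(out$ok)) return(-Inf)
  out$loglik
}
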