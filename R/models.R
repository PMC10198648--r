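#' Model parameterizations for fitting
#'
#' Maps a free-parameter vector to a full [sse_params()] rate set:
#' \describe{
#'   \item{ETD}{speciation varies with the examined state:
#'     `(lambda_1..lambda_ne, mu, q)`, k = ne + 2 (5 in the 3x3 system).}
#'   \item{CTD}{speciation varies with the concealed state, k = nc + 2.}
#'   \item{CR}{one speciation rate: `(lambda, mu, q)`, k = 3.}
#'   \item{ECTD}{speciation free in every combined state:
#'     `(lambda_1..lambda_S, mu, q)`, k = S + 2 (11 in the 3x3 system).}
#' }
#' Extinction is shared across states and transitions are symmetric one-step
#' at a single rate in every parameterization.
#'
#' @param name one of "ETD", "CTD", "CR", "ECTD".
#' @param n_examined,n_concealed trait state counts.
#' @return object of class `model_spec` with `name`, `k`, `param_names`, and
#'   `map(free)` returning an `sse_params`.
#' @export
model_spec <- function(name = c("ETD", "CTD", "CR", "ECTD"),
                       n_examined = 3L, n_concealed = 3L) {
  name <- match.arg(name)
  S <- n_examined * n_concealed
  n_lambda <- switch(name, ETD = n_examined, CTD = n_concealed, CR = 1L,
                     ECTD = S)
  lambda_names <- switch(name,
    ETD = paste0("lambda", seq_len(n_examined)),
    CTD = paste0("lambda", LETTERS[seq_len(n_concealed)]),
    CR = "lambda",
    ECTD = paste0("lambda", state_names(n_examined, n_concealed)))
  i <- seq_len(S)
  idx <- switch(name,
    ETD = state_examined(i, n_examined),
    CTD = state_concealed(i, n_examined),
    CR = rep(1L, S),
    ECTD = i)
  map <- function(free) {
    stopifnot(length(free) == n_lambda + 2L)
    sse_params(free[idx], free[n_lambda + 1L], free[n_lambda + 2L],
               n_examined, n_concealed)
  }
  structure(list(name = name, k = n_lambda + 2L,
                 param_names = c(lambda_names, "mu", "q"),
                 n_lambda = n_lambda, map = map,
                 n_examined = n_examined, n_concealed = n_concealed),
            class = "model_spec")
}

#' Log-likelihood of a model at a free-parameter vector
#'
#' @param tree,states,settings as in [loglik_sse()].
#' @param model a [model_spec()].
#' @param free_params free-parameter vector in the model's order.
#' @return log-likelihood.
#' @export
loglik_model <- function(tree, model, free_params, states = NULL,
                         settings = likelihood_settings()) {
  loglik_sse(tree, model$map(free_params), states, settings)
}
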