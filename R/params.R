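#' Full per-state SSE rate set
#'
#' Container for the rates driving a combined examined x concealed state
#' system: per-state speciation rates, per-state extinction rates, and a
#' single symmetric one-step transition rate applied along the adjacency
#' mask. Units are events / lineage / MY.
#'
#' @param lambda numeric vector of S per-state speciation rates, in
#'   combined-state order (see [state_index()]).
#' @param mu numeric vector of S per-state extinction rates (a scalar is
#'   recycled).
#' @param q scalar transition rate; the full rate matrix is `q * mask`.
#' @param n_examined,n_concealed number of states per trait.
#' @return object of class `sse_params` with elements `lambda`, `mu`, `q`,
#'   `mask`, `Q`, `n_examined`, `n_concealed`.
#' @export
sse_params <- function(lambda, mu, q, n_examined = 3L, n_concealed = 3L) {
  S <- n_examined * n_concealed
  if (length(mu) == 1L) mu <- rep(mu, S)
  if (length(lambda) != S || length(mu) != S) {
    stop("lambda and mu must have length ", S, " (or mu scalar)")
  }
  if (any(lambda < 0) || any(mu < 0) || q < 0) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  mask <- one_step_mask(n_examined, n_concealed)
  nm <- state_names(n_examined, n_concealed)
  names(lambda) <- names(mu) <- nm
  structure(
    list(lambda = lambda, mu = mu, q = q, mask = mask, Q = q * mask,
         n_examined = as.integer(n_examined),
         n_concealed = as.integer(n_concealed)),
    class = "sse_params")
}

#' @export
print.sse_params <- function(x, ...) {
  cat("SSE rate set:", x$n_examined, "examined x", x$n_concealed,
      "concealed states\n")
  print(rbind(lambda = x$lambda, mu = x$mu))
  cat("q =", x$q, "(symmetric, one-step transitions only)\n")
  invisible(x)
}

#' Generating diversification mode
#'
#' Describes how a tree set was generated: speciation varies with the
#' examined trait (ETD), with the concealed trait (CTD), or not at all (CR).
#' Extinction and transition rates are shared across states.
#'
#' @param mode one of "ETD", "CTD", "CR".
#' @param lambda_values speciation rates: one per examined state (ETD), one
#'   per concealed state (CTD), or a single rate (CR).
#' @param mu_value scalar extinction rate.
#' @param q_value scalar transition rate.
#' @return object of class `generating_mode`.
#' @export
generating_mode <- function(mode = c("ETD", "CTD", "CR"), lambda_values,
                            mu_value, q_value) {
  mode <- match.arg(mode)
  if (any(lambda_values < 0) || mu_value < 0 || q_value < 0) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  structure(list(mode = mode, lambda_values = lambda_values,
                 mu_value = mu_value, q_value = q_value),
            class = "generating_mode")
}

#' Expand a generating mode to the full per-state rate set
#'
#' ETD assigns `lambda_values` by examined state (so e.g. the rates of 1A,
#' 1B, 1C coincide); CTD assigns them by concealed state (1A = 2A = 3A); CR
#' gives all combined states the same rate. Extinction is shared.
#'
#' @param mode a [generating_mode()].
#' @inheritParams sse_params
#' @return an [sse_params()] object.
#' @export
expand_generating_mode <- function(mode, n_examined = 3L, n_concealed = 3L) {
  stopifnot(inherits(mode, "generating_mode"))
  nl <- switch(mode$mode, ETD = n_examined, CTD = n_concealed, CR = 1L)
  if (length(mode$lambda_values) != nl) {
    stop("mode ", mode$mode, " needs ", nl, " lambda value(s)", call. = FALSE)
  }
  S <- n_examined * n_concealed
  i <- seq_len(S)
  lambda <- switch(mode$mode,
    ETD = mode$lambda_values[state_examined(i, n_examined)],
    CTD = mode$lambda_values[state_concealed(i, n_examined)],
    CR = rep(mode$lambda_values, S))
  sse_params(lambda, mode$mu_value, mode$q_value, n_examined, n_concealed)
}
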