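#' Combined-state indexing
#'
#' Combined states pair an examined trait state (coded 1, 2, ...) with a
#' concealed trait state (coded A, B, ...). The index is a fixed bijection
#' with the pair: examined varies fastest, so for the default 3x3 system the
#' order is 1A, 2A, 3A, 1B, 2B, 3B, 1C, 2C, 3C.
#'
#' @param examined,concealed integer trait states (1-based).
#' @param i combined state index.
#' @param n_examined,n_concealed number of states per trait.
#' @return `state_index()` the combined index; `state_examined()` /
#'   `state_concealed()` the marginal states; `state_names()` labels such as
#'   `"1A"`.
#' @export
state_index <- function(examined, concealed, n_examined = 3L) {
  as.integer((concealed - 1L) * n_examined + examined)
}

#' @rdname state_index
#' @export
state_examined <- function(i, n_examined = 3L) {
  as.integer((i - 1L) %% n_examined + 1L)
}

#' @rdname state_index
#' @export
state_concealed <- function(i, n_examined = 3L) {
  as.integer((i - 1L) %/% n_examined + 1L)
}

#' @rdname state_index
#' @export
state_names <- function(n_examined = 3L, n_concealed = 3L) {
  paste0(rep(seq_len(n_examined), n_concealed),
         rep(LETTERS[seq_len(n_concealed)], each = n_examined))
}

#' One-step adjacency mask between combined states
#'
#' `mask[i, j]` is TRUE iff states i and j differ in exactly one of the two
#' traits; double transitions (e.g. 1A -> 2C) are excluded. The mask is
#' symmetric with zero diagonal and, in the 3x3 system, every state has
#' exactly 4 one-step neighbours (2 per trait).
#'
#' @inheritParams state_index
#' @return logical matrix of dimension S x S with S = n_examined * n_concealed.
#' @export
one_step_mask <- function(n_examined = 3L, n_concealed = 3L) {
  S <- n_examined * n_concealed
  i <- seq_len(S)
  ex <- state_examined(i, n_examined)
  co <- state_concealed(i, n_examined)
  de <- outer(ex, ex, "!=")
  dc <- outer(co, co, "!=")
  mask <- xor(de, dc) # exactly one trait differs
  dimnames(mask) <- rep(list(state_names(n_examined, n_concealed)), 2)
  mask
}
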