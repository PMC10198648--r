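#' Simulate a clade under joint trait evolution and state-dependent
#' diversification
#'
#' Exact stochastic (Gillespie) simulation from the crown age: waiting times
#' are exponential with rate equal to the summed per-lineage event rates
#' (speciation + extinction + one-step trait transitions); the event and the
#' lineage undergoing it are then drawn proportionally to their rates.
#' Speciation duplicates the lineage's combined state, extinction removes the
#' lineage, a transition moves one trait one step and is recorded in the
#' event log. Extinct lineages are pruned before output, so the returned tree
#' is ultrametric with depth `crown_age`.
#'
#' The root state is assigned to both crown lineages. If every descendant of
#' either crown lineage dies out, a condition of class `ssesim_extinct_clade`
#' is signalled (the caller decides whether to resample).
#'
#' @param params an [sse_params()] rate set.
#' @param crown_age positive crown age in MY.
#' @param root_state combined-state index of the crown lineages; `NULL` draws
#'   uniformly from the combined states.
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @param max_lineages safety cap on total lineages ever created.
#' @return object of class `clade_tree`: a list with `phy` (extant `phylo`),
#'   `crown_age`, `tip_states` (data.frame: tip, examined, concealed),
#'   `event_log` (data.frame: time, lineage, trait, from, to), `root_state`,
#'   and `lineages` (the full simulation record, used to trace which
#'   transitions survive trimming).
#' @export
simulate_clade <- function(params, crown_age, root_state = NULL, seed = NULL,
                           max_lineages = 200000L) {
  stopifnot(inherits(params, "sse_params"), crown_age > 0)
  if (!is.null(seed)) set.seed(seed)
  S <- length(params$lambda)
  if (is.null(root_state)) root_state <- sample.int(S, 1L)
  sim <- gillespie_clade_cpp(params$lambda, params$mu, params$Q,
                             as.integer(root_state), crown_age,
                             as.integer(max_lineages))
  if (isTRUE(sim$overflow)) {
    stop("lineage cap exceeded during simulation", call. = FALSE)
  }
  lin <- data.frame(id = seq_along(sim$parent), parent = sim$parent,
                    t_birth = sim$t_birth, t_end = sim$t_end,
                    end_type = sim$end_type, state = sim$state)
  extant <- lin$id[lin$end_type == 0L]
  if (length(extant) < 2L || !all(c(1L, 2L) %in% crown_ancestors(lin, extant))) {
    stop(errorCondition("clade went extinct (or one crown lineage lost all descendants)",
                        class = c("ssesim_extinct_clade", "error", "condition")))
  }
  phy_full <- phylo_from_lineages(lin)
  phy <- ape::keep.tip(phy_full, paste0("t", extant))
  ne <- params$n_examined
  tip_states <- data.frame(
    tip = paste0("t", extant),
    examined = state_examined(lin$state[extant], ne),
    concealed = state_concealed(lin$state[extant], ne),
    stringsAsFactors = FALSE)
  event_log <- decode_events(sim, ne)
  structure(list(phy = phy, crown_age = crown_age, tip_states = tip_states,
                 event_log = event_log, root_state = as.integer(root_state),
                 lineages = lin, n_examined = ne,
                 n_concealed = params$n_concealed),
            class = "clade_tree")
}

# which crown lineages (ids 1, 2) have at least one extant descendant
crown_ancestors <- function(lin, extant) {
  found <- integer(0)
  for (tip in extant) {
    i <- tip
    while (lin$parent[i] != 0L) i <- lin$parent[i]
    found <- union(found, i)
    if (length(found) == 2L) break
  }
  found
}

# Build the complete (extinct lineages included) phylo from the lineage
# record. Every lineage is one edge; speciated lineages end at an internal
# vertex; the crown vertex is the root. Vertices are numbered in ape's
# canonical way (tips 1..n, root n + 1, internals in preorder) and edges
# emitted cladewise, so downstream ape operations are safe.
phylo_from_lineages <- function(lin) {
  nlin <- nrow(lin)
  is_tip <- lin$end_type != 2L
  ntip <- sum(is_tip)
  children <- split(lin$id, factor(lin$parent, levels = 0:nlin))
  parent_col <- integer(nlin)
  child_col <- integer(nlin)
  elen <- numeric(nlin)
  tip_ids <- integer(ntip)
  next_node <- ntip + 1L
  next_tip <- 0L
  vertex_no <- integer(nlin) # assigned when the lineage's edge is emitted
  row <- 0L
  # stack of (lineage id, parent vertex number); root vertex is ntip + 1
  stack <- list(c(2L, ntip + 1L), c(1L, ntip + 1L))
  next_node <- next_node + 1L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- top[1]
    pv <- top[2]
    row <- row + 1L
    if (is_tip[id]) {
      next_tip <- next_tip + 1L
      v <- next_tip
      tip_ids[next_tip] <- id
    } else {
      v <- next_node
      next_node <- next_node + 1L
      kids <- children[[as.character(id)]]
      for (k in rev(kids)) stack[[length(stack) + 1L]] <- c(k, v)
    }
    parent_col[row] <- pv
    child_col[row] <- v
    elen[row] <- lin$t_end[id] - lin$t_birth[id]
  }
  phy <- list(edge = cbind(parent_col, child_col), edge.length = elen,
              tip.label = paste0("t", tip_ids),
              Nnode = nlin - ntip + 1L)
  storage.mode(phy$edge) <- "integer"
  dimnames(phy$edge) <- NULL
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

decode_events <- function(sim, n_examined) {
  if (length(sim$ev_time) == 0L) {
    return(data.frame(time = numeric(0), lineage = integer(0),
                      trait = character(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  fe <- state_examined(sim$ev_from, n_examined)
  te <- state_examined(sim$ev_to, n_examined)
  fc <- state_concealed(sim$ev_from, n_examined)
  tc <- state_concealed(sim$ev_to, n_examined)
  examined_changed <- fe != te
  data.frame(
    time = sim$ev_time,
    lineage = sim$ev_lineage,
    trait = ifelse(examined_changed, "examined", "concealed"),
    from = ifelse(examined_changed, as.character(fe), LETTERS[fc]),
    to = ifelse(examined_changed, as.character(te), LETTERS[tc]),
    stringsAsFactors = FALSE)
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("clade_tree:", ape::Ntip(x$phy), "extant tips, crown age",
      format(x$crown_age), "MY,", nrow(x$event_log), "recorded transitions\n")
  invisible(x)
}

#' Rejection-sample a set of trees inside a tip-count band
#'
#' Repeatedly simulates clades under `mode`, discarding extinct clades and
#' trees whose extant tip count falls outside `size_band`, until `n_trees`
#' trees have been accepted. Each attempt uses its own seed derived from
#' `(seed, attempt)`, so downstream consumers (trimming, fitting) never
#' perturb the simulation stream and the same seed reproduces the same trees.
#'
#' @param mode a [generating_mode()].
#' @param crown_age crown age in MY.
#' @param size_band length-2 integer vector `(min_tips, max_tips)`.
#' @param n_trees number of trees to return.
#' @param seed integer seed for the whole set.
#' @param n_examined,n_concealed trait state counts.
#' @param max_attempts,acceptance_floor infeasibility guard: once
#'   `max_attempts` attempts have been made, an acceptance rate below
#'   `acceptance_floor` raises a condition of class `ssesim_infeasible_band`.
#' @return list of `clade_tree` objects with an `acceptance` attribute
#'   recording attempts, acceptances, extinctions and out-of-band rejections.
#' @export
sample_tree_set <- function(mode, crown_age, size_band, n_trees, seed,
                            n_examined = 3L, n_concealed = 3L,
                            max_attempts = 10000L, acceptance_floor = 1e-3) {
  stopifnot(n_trees >= 1, size_band[1] >= 2, size_band[2] >= size_band[1])
  params <- expand_generating_mode(mode, n_examined, n_concealed)
  trees <- vector("list", n_trees)
  got <- 0L
  attempts <- 0L
  extinct <- 0L
  out_of_band <- 0L
  while (got < n_trees) {
    attempts <- attempts + 1L
    if (attempts >= max_attempts && got / attempts < acceptance_floor) {
      stop(errorCondition(
        sprintf("size band [%d, %d] infeasible: %d accepted in %d attempts",
                size_band[1], size_band[2], got, attempts),
        class = c("ssesim_infeasible_band", "error", "condition")))
    }
    tr <- tryCatch(
      simulate_clade(params, crown_age, seed = derive_seed(seed, attempts)),
      ssesim_extinct_clade = function(e) NULL)
    if (is.null(tr)) {
      extinct <- extinct + 1L
      next
    }
    n <- ape::Ntip(tr$phy)
    if (n < size_band[1] || n > size_band[2]) {
      out_of_band <- out_of_band + 1L
      next
    }
    got <- got + 1L
    trees[[got]] <- tr
  }
  attr(trees, "acceptance") <- list(attempts = attempts, accepted = got,
                                    extinct = extinct,
                                    out_of_band = out_of_band)
  trees
}

#' Derive a reproducible sub-seed
#'
#' Deterministic map from a master seed and an index to a 32-bit seed, so
#' each tree / task gets an independent, reproducible stream.
#' @param seed,index integers.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483562 + 1)
}
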