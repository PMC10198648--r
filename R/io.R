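#' Read and write clade trees in the package's plain-text exchange formats
#'
#' A tree set is stored as a Newick file (branch lengths in MY, unquoted
#' labels), a tab-delimited tip-state table (`tip_label`, `examined_state`,
#' `concealed_state`), and the event log as CSV (`time`, `lineage`, `trait`,
#' `from`, `to`). The likelihood only ever consumes the 2-column examined
#' version of the state table.
#'
#' @param tree a `clade_tree`.
#' @param newick,states,events file paths; `events = NULL` skips the log.
#' @return `write_clade_tree()` invisibly returns the paths;
#'   `read_clade_tree()` a `clade_tree` (without a simulation lineage record);
#'   `read_tip_states()` a named integer vector of examined states.
#' @export
write_clade_tree <- function(tree, newick, states, events = NULL) {
  ape::write.tree(tree$phy, file = newick)
  st <- tree$tip_states
  out <- data.frame(tip_label = st$tip, examined_state = st$examined,
                    concealed_state = LETTERS[st$concealed])
  utils::write.table(out, states, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(events)) {
    utils::write.csv(tree$event_log, events, row.names = FALSE)
  }
  invisible(c(newick = newick, states = states, events = events))
}

#' @rdname write_clade_tree
#' @export
read_clade_tree <- function(newick, states) {
  phy <- ape::read.tree(newick)
  st <- utils::read.delim(states, stringsAsFactors = FALSE)
  concealed <- if ("concealed_state" %in% names(st)) {
    match(st$concealed_state, LETTERS)
  } else {
    NA_integer_
  }
  tip_states <- data.frame(tip = st$tip_label,
                           examined = as.integer(st$examined_state),
                           concealed = concealed, stringsAsFactors = FALSE)
  depths <- ape::node.depth.edgelength(phy)
  structure(list(phy = phy, crown_age = max(depths[seq_len(ape::Ntip(phy))]),
                 tip_states = tip_states,
                 event_log = NULL, root_state = NA_integer_, lineages = NULL,
                 n_examined = max(tip_states$examined),
                 n_concealed = if (all(is.na(concealed))) NA_integer_ else
                   max(concealed)),
            class = "clade_tree")
}

#' @rdname write_clade_tree
#' @param path a 2+ column tab-delimited state table.
#' @export
read_tip_states <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(st$examined_state), st$tip_label)
}

#' Examined-state vector of a clade tree
#'
#' @param tree a `clade_tree`.
#' @return named integer vector tip -> examined state, the only trait data a
#'   likelihood computation may see.
#' @export
examined_states <- function(tree) {
  stats::setNames(as.integer(tree$tip_states$examined), tree$tip_states$tip)
}
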