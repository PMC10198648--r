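#' Randomly trim a tree to a target sampling fraction
#'
#' Retains `round(target_sf * N)` tips drawn uniformly without replacement;
#' unary nodes are collapsed and branch lengths re-summed (via
#' [ape::keep.tip()]). Tip removal never consults trait states. A target that
#' would leave fewer than 4 tips is refused (condition class
#' `ssesim_trim_refusal`).
#'
#' @param tree a `clade_tree`.
#' @param target_sf target global sampling fraction in (0, 1].
#' @param seed optional integer seed.
#' @return list with `tree` (trimmed `clade_tree`) and `spec`, a sampling
#'   specification recording the regime, target and exactly achieved SF.
#' @export
random_trim <- function(tree, target_sf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree$phy)
  n_keep <- round(target_sf * n)
  if (n_keep < 4L) {
    stop(errorCondition(
      sprintf("target SF %.3g keeps %d < 4 tips", target_sf, n_keep),
      class = c("ssesim_trim_refusal", "error", "condition")))
  }
  if (n_keep == n) {
    spec <- sampling_spec(1, target_sf, "random")
    return(list(tree = tree, spec = spec))
  }
  keep <- sample(tree$phy$tip.label, n_keep)
  trimmed <- subset_clade(tree, keep)
  list(tree = trimmed, spec = sampling_spec(n_keep / n, target_sf, "random"))
}

sampling_spec <- function(achieved, target, regime, bias_config = NULL,
                          n_states = 3L) {
  structure(list(true_sf = achieved, target_sf = target,
                 specified_sf = rep(achieved, n_states), regime = regime,
                 bias_config = bias_config),
            class = "sampling_spec")
}

# keep a tip subset of a clade_tree, preserving simulation provenance
subset_clade <- function(tree, keep) {
  phy <- ape::keep.tip(tree$phy, keep)
  depths <- ape::node.depth.edgelength(phy)
  tree$phy <- phy
  tree$crown_age <- max(depths[seq_len(ape::Ntip(phy))])
  tree$tip_states <- tree$tip_states[tree$tip_states$tip %in% keep, ,
                                     drop = FALSE]
  tree
}

#' Taxonomically biased trimming
#'
#' Emulates under-sampling concentrated in sub-clades: (i) internal nodes
#' whose descendant-tip share of the full tree lies inside
#' `bias_config$subclade_frac` are enumerated and `n_subclades` non-nested
#' ones chosen at random; (ii) a fraction `removal_frac` (drawn uniformly
#' from its range, per sub-clade) of each chosen sub-clade's tips is removed;
#' (iii) tips are then removed at random from the remainder of the tree until
#' the global achieved SF is within +/- 0.02 of `target_sf`. If the heavy trim
#' alone overshoots below the tolerance band, `removal_frac` is redrawn once
#' before an `ssesim_infeasible_target` condition is raised. Trees with no
#' eligible sub-clade raise `ssesim_ineligible_tree`.
#'
#' @inheritParams random_trim
#' @param bias_config list with `n_subclades` (1 or 2), `subclade_frac`
#'   (range of eligible descendant-tip shares), `removal_frac` (range of the
#'   within-sub-clade removal fraction; a scalar fixes it).
#' @return list with `tree` and `spec` (including the chosen sub-clade sizes
#'   and achieved SF).
#' @export
biased_trim <- function(tree, target_sf,
                        bias_config = list(n_subclades = 1L,
                                           subclade_frac = c(0.20, 0.30),
                                           removal_frac = c(0.80, 0.90)),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phy
  n <- ape::Ntip(phy)
  fr <- range(bias_config$subclade_frac)
  clades <- clade_tip_sets(phy)
  share <- lengths(clades) / n
  eligible <- which(share >= fr[1] & share <= fr[2])
  if (length(eligible) < bias_config$n_subclades) {
    stop(errorCondition(
      sprintf("only %d eligible sub-clades (need %d) with tip share in [%.2f, %.2f]",
              length(eligible), bias_config$n_subclades, fr[1], fr[2]),
      class = c("ssesim_ineligible_tree", "error", "condition")))
  }
  pick_subclades <- function() {
    if (bias_config$n_subclades == 1L) {
      return(eligible[sample.int(length(eligible), 1L)])
    }
    # choose two non-nested eligible clades
    for (i in seq_len(200L)) {
      cand <- eligible[sample.int(length(eligible), 2L)]
      a <- clades[[cand[1]]]
      b <- clades[[cand[2]]]
      if (!any(a %in% b) && !any(b %in% a)) return(cand)
    }
    stop(errorCondition("no non-nested pair of eligible sub-clades",
                        class = c("ssesim_ineligible_tree", "error",
                                  "condition")))
  }
  chosen <- pick_subclades()
  n_target <- round(target_sf * n)
  rf_range <- range(bias_config$removal_frac)
  attempt <- function() {
    removed <- character(0)
    rfs <- numeric(0)
    for (cl in chosen) {
      tips <- clades[[cl]]
      rf <- stats::runif(1, rf_range[1], rf_range[2])
      rfs <- c(rfs, rf)
      removed <- c(removed, sample(tips, round(rf * length(tips))))
    }
    list(removed = removed, rfs = rfs)
  }
  res <- attempt()
  n_kept <- n - length(res$removed)
  if (n_kept < n_target && n_kept / n < target_sf - 0.02) {
    res <- attempt() # one redraw of removal_frac, per tolerance-band policy
    n_kept <- n - length(res$removed)
    if (n_kept / n < target_sf - 0.02) {
      stop(errorCondition(
        sprintf("heavy trim alone reaches SF %.3f, below target %.2f - 0.02",
                n_kept / n, target_sf),
        class = c("ssesim_infeasible_target", "error", "condition")))
    }
  }
  keep <- setdiff(phy$tip.label, res$removed)
  if (length(keep) > n_target) {
    background <- setdiff(keep, unlist(clades[chosen]))
    n_rm <- length(keep) - n_target
    if (length(background) < n_rm) {
      stop(errorCondition("not enough background tips to reach target SF",
                          class = c("ssesim_infeasible_target", "error",
                                    "condition")))
    }
    keep <- setdiff(keep, sample(background, n_rm))
  }
  if (length(keep) < 4L) {
    stop(errorCondition("biased trim leaves < 4 tips",
                        class = c("ssesim_trim_refusal", "error",
                                  "condition")))
  }
  achieved <- length(keep) / n
  stopifnot(abs(achieved - target_sf) <= 0.02 + 1e-12)
  trimmed <- subset_clade(tree, keep)
  spec <- sampling_spec(achieved, target_sf, "biased",
                        bias_config = c(bias_config,
                                        list(subclade_sizes = lengths(clades)[chosen],
                                             removal_drawn = res$rfs)))
  list(tree = trimmed, spec = spec)
}

# tip label sets of every internal node except the root
clade_tip_sets <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  nodes <- setdiff(unique(phy$edge[, 1]), root)
  prop <- ape::prop.part(phy)
  labs <- attr(prop, "labels")
  # prop.part indexes clades by node - n starting at the root
  sets <- lapply(nodes, function(nd) labs[prop[[nd - n]]])
  names(sets) <- nodes
  sets
}

#' Per-examined-state tip fractions
#'
#' @param tree a `clade_tree`.
#' @return numeric vector of length `n_examined` summing to 1; empty states
#'   are reported as 0, not dropped.
#' @export
state_proportions <- function(tree) {
  ne <- tree$n_examined
  if (is.na(ne)) ne <- max(tree$tip_states$examined)
  counts <- tabulate(tree$tip_states$examined, nbins = ne)
  stats::setNames(counts / sum(counts), as.character(seq_len(ne)))
}

#' Transitions lost to trimming
#'
#' A recorded transition counts as lost iff it occurred on a lineage with at
#' least one extant descendant in the full tree (i.e. it is visible on the
#' pruned complete tree) but no descendant among the trimmed tips. Counts are
#' returned for every ordered state pair of each trait.
#'
#' @param full a simulated `clade_tree` carrying `event_log` and `lineages`.
#' @param trimmed a tree whose tips are a subset of `full`'s.
#' @return data.frame with columns `trait`, `from`, `to`, `lost`.
#' @export
transition_loss_summary <- function(full, trimmed) {
  stopifnot(!is.null(full$event_log), !is.null(full$lineages))
  kept <- trimmed$phy$tip.label
  stopifnot(all(kept %in% full$phy$tip.label))
  lin <- full$lineages
  extant <- lin$id[lin$end_type == 0L]
  kept_ids <- as.integer(sub("^t", "", kept))
  # per lineage: does any extant / any kept tip descend from it?
  has_extant <- logical(nrow(lin))
  has_kept <- logical(nrow(lin))
  mark <- function(flags, tips) {
    for (tip in tips) {
      i <- tip
      while (i != 0L && !flags[i]) {
        flags[i] <- TRUE
        i <- lin$parent[i]
      }
    }
    flags
  }
  has_extant <- mark(has_extant, extant)
  has_kept <- mark(has_kept, kept_ids)
  ev <- full$event_log
  lost <- has_extant[ev$lineage] & !has_kept[ev$lineage]
  pairs <- transition_pairs(full$n_examined, full$n_concealed)
  pairs$lost <- mapply(function(tr, f, t) {
    sum(lost & ev$trait == tr & ev$from == f & ev$to == t)
  }, pairs$trait, pairs$from, pairs$to)
  pairs
}

transition_pairs <- function(n_examined, n_concealed) {
  ex <- as.character(seq_len(n_examined))
  co <- LETTERS[seq_len(n_concealed)]
  ord <- function(v) {
    g <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
    g[g$from != g$to, ]
  }
  e <- ord(ex)
  e$trait <- "examined"
  c_ <- ord(co)
  c_$trait <- "concealed"
  out <- rbind(e, c_)[, c("trait", "from", "to")]
  rownames(out) <- NULL
  out
}
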