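sim_tree <- function(seed = 11, mu = 0.05, age = 10, band = c(40, 200)) {
  sample_tree_set(etd_mode(mu), age, band, 1, seed = seed)[[1]]
}

test_that("random_trim keeps round(target * N) tips and records SF exactly", {
  tr <- sim_tree()
  n <- ape::Ntip(tr$phy)
  out <- random_trim(tr, 0.6, seed = 5)
  expect_equal(ape::Ntip(out$tree$phy), round(0.6 * n))
  expect_equal(out$spec$true_sf, round(0.6 * n) / n)
  expect_equal(out$spec$regime, "random")
  # trimmed trees stay ultrametric and binary
  phy <- out$tree$phy
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_lt(diff(range(depths)), 1e-8)
  expect_equal(phy$Nnode, ape::Ntip(phy) - 1L)
  # target 1.0 is the identity
  expect_identical(ape::write.tree(random_trim(tr, 1.0)$tree$phy),
                   ape::write.tree(tr$phy))
  # refusal below 4 tips
  expect_error(random_trim(tr, 3 / n), class = "ssesim_trim_refusal")
})

test_that("random_trim retains each examined state at the global fraction", {
  # hypergeometric oracle: over replicate trims the mean per-state retained
  # fraction matches the target within 3 binomial SEs
  tr <- sim_tree(seed = 13, band = c(80, 200))
  counts0 <- table(factor(examined_states(tr), levels = 1:3))
  fracs <- vapply(seq_len(400), function(i) {
    out <- random_trim(tr, 0.6, seed = derive_seed(1, i))
    as.numeric(table(factor(examined_states(out$tree), levels = 1:3)) /
                 counts0)
  }, numeric(3))
  m <- rowMeans(fracs)
  se <- apply(fracs, 1, stats::sd) / sqrt(ncol(fracs))
  expect_true(all(abs(m - 0.6) < pmax(3 * se, 1e-6)))
})

test_that("biased_trim arithmetic on a constructed fixture", {
  # 8-tip balanced tree: the only 2-tip "sub-clade" shares are 0.25 (cherries)
  phy <- ape::stree(8, "balanced")
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy$tip.label <- paste0("t", 1:8)
  tr <- structure(list(phy = phy, crown_age = 3,
                       tip_states = data.frame(tip = phy$tip.label,
                                               examined = rep(1:2, 4),
                                               concealed = 1L),
                       event_log = NULL, lineages = NULL, n_examined = 3L,
                       n_concealed = 3L), class = "clade_tree")
  cfg <- list(n_subclades = 1L, subclade_frac = c(0.20, 0.30),
              removal_frac = 0.5)
  out <- biased_trim(tr, 0.75, bias_config = cfg, seed = 3)
  # one cherry loses round(0.5 * 2) = 1 tip; 7/8 kept = 0.875 > 0.77, so one
  # background tip is removed to land on round(0.75 * 8) = 6
  expect_equal(ape::Ntip(out$tree$phy), 6L)
  expect_equal(out$spec$true_sf, 0.75)
  expect_equal(unname(out$spec$bias_config$subclade_sizes), 2L)
})

test_that("biased_trim achieves the target SF within the 2% band", {
  trees <- sample_tree_set(etd_mode(0.05), 10, c(80, 250), 6, seed = 31)
  for (target in c(0.8, 0.6, 0.2)) {
    for (tr in trees) {
      out <- tryCatch(biased_trim(tr, target, seed = 17),
                      ssesim_ineligible_tree = function(e) NULL,
                      ssesim_infeasible_target = function(e) NULL)
      if (is.null(out)) next
      expect_lte(abs(out$spec$true_sf - target), 0.02 + 1e-12)
      expect_gte(ape::Ntip(out$tree$phy), 4L)
    }
  }
})

test_that("biased_trim signals ineligible trees", {
  # a 4-tip balanced tree has only 2-tip clades: share 0.5, never in
  # [0.20, 0.30]
  phy <- balanced4()
  tr <- structure(list(phy = phy, crown_age = 2,
                       tip_states = data.frame(tip = phy$tip.label,
                                               examined = 1L, concealed = 1L),
                       event_log = NULL, lineages = NULL, n_examined = 3L,
                       n_concealed = 3L), class = "clade_tree")
  expect_error(biased_trim(tr, 0.8, seed = 1),
               class = "ssesim_ineligible_tree")
})

test_that("state_proportions reports zeros and sums to one", {
  tr <- list(tip_states = data.frame(tip = paste0("t", 1:4),
                                     examined = c(1L, 1L, 2L, 3L)),
             n_examined = 3L)
  class(tr) <- "clade_tree"
  expect_equal(unname(state_proportions(tr)), c(0.5, 0.25, 0.25))
  tr$tip_states$examined <- c(1L, 1L, 2L, 2L)
  expect_equal(unname(state_proportions(tr)), c(0.5, 0.5, 0))
})

test_that("transition_loss_summary: identity, hand-traced fixture, symmetry", {
  tr <- sim_tree(seed = 23, band = c(60, 200))
  # trimmed == full: nothing lost
  same <- transition_loss_summary(tr, tr)
  expect_true(all(same$lost == 0))
  expect_equal(nrow(same), 12L) # 6 examined + 6 concealed ordered pairs
  # drop one cherry entirely: transitions on its stem/descendants are lost
  out <- random_trim(tr, 0.5, seed = 9)
  loss <- transition_loss_summary(tr, out$tree)
  expect_true(all(loss$lost >= 0))
  expect_lte(sum(loss$lost), nrow(tr$event_log))
})

test_that("a transition on a fully pruned cherry stem is counted as lost", {
  # construct: simulate until an event sits on a lineage whose extant tips
  # we then remove completely
  tr <- sim_tree(seed = 37, band = c(30, 120))
  ev <- tr$event_log
  skip_if(nrow(ev) == 0)
  lin <- tr$lineages
  extant <- lin$id[lin$end_type == 0L]
  # find an event lineage with a small, proper extant descendant set
  desc_of <- function(id) {
    ids <- id
    repeat {
      kids <- lin$id[lin$parent %in% ids & !(lin$id %in% ids)]
      if (!length(kids)) break
      ids <- c(ids, kids)
    }
    intersect(ids, extant)
  }
  found <- FALSE
  for (r in seq_len(nrow(ev))) {
    d <- desc_of(ev$lineage[r])
    if (length(d) >= 1 && length(d) <= length(extant) - 4) {
      keep <- setdiff(paste0("t", extant), paste0("t", d))
      trimmed <- ssesim:::subset_clade(tr, keep)
      loss <- transition_loss_summary(tr, trimmed)
      hit <- loss[loss$trait == ev$trait[r] & loss$from == ev$from[r] &
                    loss$to == ev$to[r], "lost"]
      expect_gte(hit, 1)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("random trimming loses examined and concealed transitions alike", {
  # over replicate trees the per-tree examined vs concealed losses at SF 0.6
  # are statistically indistinguishable (paired test at alpha = 0.01)
  trees <- sample_tree_set(etd_mode(0.05), 10, c(50, 200), 25, seed = 53)
  diffs <- vapply(seq_along(trees), function(i) {
    out <- random_trim(trees[[i]], 0.6, seed = derive_seed(7, i))
    loss <- transition_loss_summary(trees[[i]], out$tree)
    sum(loss$lost[loss$trait == "examined"]) -
      sum(loss$lost[loss$trait == "concealed"])
  }, 0)
  expect_gt(stats::t.test(diffs)$p.value, 0.01)
})
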