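#' False-positive / false-negative model-selection rates
#'
#' A false positive is the selection of ETD on a CTD- or CR-generated
#' dataset; the rate is 100 times the number of such selections divided by
#' the total number of CTD- and CR-generated datasets. A false negative is
#' the selection of CTD or CR on an ETD-generated dataset, relative to the
#' number of ETD-generated datasets. The CTD-vs-CR origin of the false
#' positives is also reported.
#'
#' @param records data.frame with columns `generating` and `selected`
#'   (model names).
#' @return object of class `selection_summary`: `counts` (generating x
#'   selected table), `fp_rate`, `fn_rate` (percent, `NA` when the
#'   denominator class is absent), `fp_from_ctd`, `fp_from_cr`.
#' @export
fp_fn_rates <- function(records) {
  stopifnot(all(c("generating", "selected") %in% names(records)))
  gen <- records$generating
  sel <- records$selected
  non_etd <- gen %in% c("CTD", "CR")
  fp_rate <- if (any(non_etd)) {
    100 * sum(non_etd & sel == "ETD") / sum(non_etd)
  } else {
    NA_real_
  }
  fn_rate <- if (any(gen == "ETD")) {
    100 * sum(gen == "ETD" & sel != "ETD") / sum(gen == "ETD")
  } else {
    NA_real_
  }
  structure(list(
    counts = table(generating = gen, selected = sel),
    fp_rate = fp_rate, fn_rate = fn_rate,
    fp_from_ctd = sum(gen == "CTD" & sel == "ETD"),
    fp_from_cr = sum(gen == "CR" & sel == "ETD")),
    class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("false positives: %s%%  false negatives: %s%%\n",
              format(x$fp_rate), format(x$fn_rate)))
  cat(sprintf("FP origin: %d from CTD, %d from CR\n", x$fp_from_ctd,
              x$fp_from_cr))
  print(x$counts)
  invisible(x)
}

#' Sackin tree-imbalance index
#'
#' Average over tips of the number of internal nodes (root included) on the
#' root-to-tip path; invariant to branch lengths. The classical summed form
#' is also reported.
#'
#' @param tree a `clade_tree` or `phylo` with at least 2 tips.
#' @return list with `mean` (primary) and `total`.
#' @export
sackin_index <- function(tree) {
  phy <- if (inherits(tree, "clade_tree")) tree$phy else tree
  n <- ape::Ntip(phy)
  stopifnot(n >= 2)
  depth <- integer(n + phy$Nnode)
  cw <- ape::reorder.phylo(phy, "cladewise")
  depth[n + 1L] <- 0L
  for (k in seq_len(nrow(cw$edge))) {
    depth[cw$edge[k, 2]] <- depth[cw$edge[k, 1]] + 1L
  }
  tips <- depth[seq_len(n)]
  list(mean = mean(tips), total = sum(tips))
}

#' Parameter-recovery summaries
#'
#' Per-parameter bias, RMSE and median over a set of fits paired with the
#' generating truth. Computed over all supplied trees regardless of whether
#' the generating model won the model selection. Net diversification per
#' examined state (`lambda_s - mu`) is summarized from the ETD-parameter
#' columns when present.
#'
#' @param estimates data.frame with columns `param`, `estimate`, `truth`
#'   (one row per tree x parameter).
#' @return data.frame with columns `param`, `n`, `bias`, `rmse`,
#'   `median_estimate`, `truth`.
#' @export
estimate_summary <- function(estimates) {
  stopifnot(all(c("param", "estimate", "truth") %in% names(estimates)))
  out <- do.call(rbind, lapply(split(estimates, estimates$param), function(d) {
    err <- d$estimate - d$truth
    data.frame(param = d$param[1], n = nrow(d), bias = mean(err),
               rmse = sqrt(mean(err^2)),
               median_estimate = stats::median(d$estimate),
               truth = d$truth[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Net diversification per examined state from an ETD fit
#'
#' @param fit an ETD `fit_result`.
#' @return named vector `lambda_s - mu` over examined states.
#' @export
net_diversification <- function(fit) {
  stopifnot(fit$model == "ETD", !is.null(fit$mle))
  lam <- fit$mle[grep("^lambda[0-9]+$", names(fit$mle))]
  stats::setNames(lam - fit$mle[["mu"]], paste0("ND", seq_along(lam)))
}
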