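#' Experiment configuration
#'
#' Config-driven description of one arm of the simulation study: a tree size
#' class (crown age + tip-count band), an extinction level, the generating
#' modes, the sampling-fraction levels and trimming regime, and which
#' mis-specified SF settings to run. Only mis-specification pairs from the
#' study design are allowed: true SF 1.0 may be specified as 0.8; 0.8 as 1.0
#' or 0.6; 0.6 as 1.0, 0.8 or 0.4; 0.4 as 1.0 or 0.8; 0.2 admits none.
#'
#' @param size_class `"large"`, `"medium"`, `"small"`, or a list with `name`,
#'   `crown_age`, `band`.
#' @param extinction_level `"low"` (mu = 0.001) or `"regular"` (mu = 0.05).
#' @param modes generating modes to simulate.
#' @param n_replicates trees per generating mode.
#' @param sf_levels sampling-fraction levels (subset of 1, .8, .6, .4, .2).
#' @param regime `"random"` or `"biased"` trimming.
#' @param misspec `TRUE` runs every allowed mis-specified setting for each
#'   requested true SF, `FALSE` none, or a named list (true SF -> specified
#'   values) validated against the allowed pairs.
#' @param seed master seed.
#' @param models_to_fit models fitted to each trimmed dataset.
#' @param lambda_etd,lambda_cr,q_rate generating rates.
#' @param fit_control passed to [fit_model()].
#' @param ode_rel_tol,ode_abs_tol likelihood tolerances used in the fits.
#' @return validated config list of class `experiment_config`.
#' @export
experiment_config <- function(size_class = "small",
                              extinction_level = c("low", "regular"),
                              modes = c("ETD", "CTD", "CR"),
                              n_replicates = 20L,
                              sf_levels = c(1, 0.8, 0.6, 0.4, 0.2),
                              regime = c("random", "biased"),
                              misspec = FALSE, seed = 1L,
                              models_to_fit = c("CR", "CTD", "ETD"),
                              lambda_etd = c(0.1, 0.3, 0.5), lambda_cr = 0.3,
                              q_rate = 0.4, fit_control = list(),
                              ode_rel_tol = 1e-8, ode_abs_tol = 1e-10) {
  if (is.character(size_class)) size_class <- size_class_preset(size_class)
  extinction_level <- match.arg(extinction_level)
  regime <- match.arg(regime)
  stopifnot(all(modes %in% c("ETD", "CTD", "CR")),
            all(models_to_fit %in% c("CR", "CTD", "ETD", "ECTD")),
            n_replicates >= 1)
  sf_levels <- as.numeric(sf_levels)
  allowed <- misspec_allowed()
  if (!all(as.character(sf_levels) %in% names(allowed))) {
    stop("sf_levels must be a subset of ",
         paste(names(allowed), collapse = ", "))
  }
  if (isTRUE(misspec)) {
    misspec <- allowed[as.character(sf_levels)]
  } else if (identical(misspec, FALSE)) {
    misspec <- stats::setNames(vector("list", length(sf_levels)),
                               as.character(sf_levels))
  } else {
    for (true_sf in names(misspec)) {
      bad <- setdiff(misspec[[true_sf]], allowed[[true_sf]])
      if (length(bad)) {
        stop(sprintf(
          "mis-specification %s -> %s not in the study design (true SF %s admits: %s)",
          true_sf, paste(bad, collapse = ","), true_sf,
          if (length(allowed[[true_sf]]))
            paste(allowed[[true_sf]], collapse = ", ") else "none"))
      }
    }
  }
  structure(list(size_class = size_class,
                 extinction_level = extinction_level,
                 mu = c(low = 0.001, regular = 0.05)[[extinction_level]],
                 modes = modes, n_replicates = as.integer(n_replicates),
                 sf_levels = sf_levels, regime = regime, misspec = misspec,
                 seed = as.integer(seed), models_to_fit = models_to_fit,
                 lambda_etd = lambda_etd, lambda_cr = lambda_cr,
                 q_rate = q_rate, fit_control = fit_control,
                 ode_rel_tol = ode_rel_tol, ode_abs_tol = ode_abs_tol),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
size_class_preset <- function(name) {
  switch(name,
    large = list(name = "large", crown_age = 23, band = c(1000L, 5000L)),
    medium = list(name = "medium", crown_age = 19, band = c(450L, 650L)),
    small = list(name = "small", crown_age = 13.4, band = c(100L, 250L)),
    stop("unknown size class: ", name))
}

#' @rdname experiment_config
#' @export
misspec_allowed <- function() {
  list(`1` = 0.8, `0.8` = c(1, 0.6), `0.6` = c(1, 0.8, 0.4),
       `0.4` = c(1, 0.8), `0.2` = numeric(0))
}

#' Read an experiment configuration from JSON
#'
#' @param path JSON file whose fields mirror [experiment_config()] arguments.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")] # underscore keys are comments
  if (!is.null(raw$size_class) && is.list(raw$size_class)) {
    raw$size_class$band <- as.integer(raw$size_class$band)
  }
  do.call(experiment_config, raw)
}

generating_mode_for <- function(config, mode) {
  lam <- switch(mode, ETD = config$lambda_etd, CTD = config$lambda_etd,
                CR = config$lambda_cr)
  generating_mode(mode, lam, config$mu, config$q_rate)
}

#' Run a configured experiment
#'
#' For each generating mode: simulate `n_replicates` trees in the size band,
#' trim each to every SF level under the configured regime, fit all models
#' under the correctly specified SF and under each configured mis-specified
#' SF, select the best model by AICc, and summarize. Per-(mode, replicate)
#' task fragments under `outdir/tasks/` make a rerun resumable; outputs are
#' byte-identical for identical `(config, seed)`.
#'
#' @param config an [experiment_config()].
#' @param outdir writable output directory; receives `fits.csv`,
#'   `selection.csv`, `metrics.csv` and `run_log.jsonl`.
#' @return invisibly, a list with the three data.frames.
#' @export
run_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(file.path(outdir, "tasks"), recursive = TRUE,
             showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.jsonl")
  log_con <- file(log_path, open = "w")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(...) {
    writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE), log_con)
  }
  settings_for <- function(rho_scalar) {
    likelihood_settings(rho = rep(rho_scalar, 3),
                        ode_rel_tol = config$ode_rel_tol,
                        ode_abs_tol = config$ode_abs_tol)
  }
  all_fits <- list()
  for (mi in seq_along(config$modes)) {
    mode_name <- config$modes[mi]
    gm <- generating_mode_for(config, mode_name)
    set_seed <- derive_seed(config$seed, mi)
    trees <- sample_tree_set(gm, config$size_class$crown_age,
                             config$size_class$band, config$n_replicates,
                             seed = set_seed)
    acc <- attr(trees, "acceptance")
    log_line(event = "tree_set", mode = mode_name, attempts = acc$attempts,
             accepted = acc$accepted, extinct = acc$extinct,
             out_of_band = acc$out_of_band, seed = set_seed)
    for (r in seq_along(trees)) {
      frag <- file.path(outdir, "tasks",
                        sprintf("fits_%s_r%03d.csv", mode_name, r))
      if (file.exists(frag)) {
        all_fits[[length(all_fits) + 1L]] <-
          utils::read.csv(frag, stringsAsFactors = FALSE)
        log_line(event = "resumed", mode = mode_name, replicate = r)
        next
      }
      rows <- replicate_fits(trees[[r]], mode_name, r, config, settings_for,
                             log_line)
      utils::write.csv(rows, frag, row.names = FALSE)
      all_fits[[length(all_fits) + 1L]] <- rows
      log_line(event = "replicate_done", mode = mode_name, replicate = r)
    }
  }
  fits <- do.call(rbind, all_fits)
  selection <- derive_selection(fits)
  metrics <- derive_metrics(selection)
  utils::write.csv(fits, file.path(outdir, "fits.csv"), row.names = FALSE)
  utils::write.csv(selection, file.path(outdir, "selection.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  invisible(list(fits = fits, selection = selection, metrics = metrics))
}

# all fits for one simulated tree across SF levels and specified-SF settings
replicate_fits <- function(tree, mode_name, r, config, settings_for,
                           log_line) {
  rows <- list()
  tree_id <- sprintf("%s_%03d", mode_name, r)
  for (si in seq_along(config$sf_levels)) {
    sf <- config$sf_levels[si]
    trim_seed <- derive_seed(config$seed, 10000L + r * 100L + si)
    trimmed <- trim_for_regime(tree, sf, config$regime, trim_seed, log_line,
                               tree_id)
    if (is.null(trimmed)) next
    specified <- c(sf, config$misspec[[as.character(sf)]])
    for (spec_sf in specified) {
      for (model_name in config$models_to_fit) {
        model <- model_spec(model_name)
        fit_seed <- derive_seed(config$seed,
                                20000L + r * 400L + si * 40L +
                                  round(spec_sf * 10) +
                                  match(model_name, c("CR", "CTD", "ETD",
                                                      "ECTD")) * 4000L)
        fit <- fit_model(trimmed$tree, model,
                         settings = settings_for(spec_sf), seed = fit_seed,
                         control = config$fit_control)
        mle <- fit$mle
        rows[[length(rows) + 1L]] <- data.frame(
          tree_id = tree_id, generating = mode_name, replicate = r,
          regime = config$regime, sf_level = sf,
          achieved_sf = trimmed$spec$true_sf, specified_sf = spec_sf,
          model = model_name, lnL = fit$lnL, k = fit$k, aicc = fit$aicc,
          n_used = fit$n_used, converged = fit$converged,
          params = if (is.null(mle)) "" else
            paste(sprintf("%s=%.6g", names(mle), mle), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

trim_for_regime <- function(tree, sf, regime, trim_seed, log_line, tree_id) {
  if (regime == "random") {
    out <- tryCatch(random_trim(tree, sf, seed = trim_seed),
                    ssesim_trim_refusal = function(e) NULL)
    if (is.null(out)) log_line(event = "trim_refused", tree = tree_id,
                               sf = sf)
    return(out)
  }
  if (sf == 1) return(list(tree = tree, spec = sampling_spec(1, 1, "biased")))
  for (k in seq_len(10L)) {
    out <- tryCatch(
      biased_trim(tree, sf, seed = derive_seed(trim_seed, k)),
      ssesim_ineligible_tree = function(e) NULL,
      ssesim_infeasible_target = function(e) NULL,
      ssesim_trim_refusal = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  log_line(event = "biased_trim_failed", tree = tree_id, sf = sf)
  NULL
}

derive_selection <- function(fits) {
  keys <- c("tree_id", "generating", "regime", "sf_level", "specified_sf")
  groups <- split(fits, fits[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    conv <- g[g$converged & is.finite(g$aicc), ]
    if (nrow(conv) < 2) return(NULL)
    name_order <- match(conv$model, c("CR", "CTD", "ETD", "ECTD"))
    best <- conv$model[order(conv$aicc, conv$k, name_order)][1]
    out <- g[1, keys]
    out$selected <- best
    out$best_weight <- max(akaike_weights(conv$aicc))
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(tree_id = character(0), generating = character(0),
                      regime = character(0), sf_level = numeric(0),
                      specified_sf = numeric(0), selected = character(0),
                      best_weight = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$generating, out$tree_id, out$sf_level,
                   out$specified_sf), ]
  rownames(out) <- NULL
  out
}

derive_metrics <- function(selection) {
  keys <- c("regime", "sf_level", "specified_sf")
  if (!nrow(selection)) {
    return(data.frame(regime = character(0), sf_level = numeric(0),
                      specified_sf = numeric(0), n = integer(0),
                      fp_rate = numeric(0), fn_rate = numeric(0),
                      fp_from_ctd = integer(0), fp_from_cr = integer(0)))
  }
  groups <- split(selection, selection[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    s <- fp_fn_rates(data.frame(generating = g$generating,
                                selected = g$selected))
    data.frame(regime = g$regime[1], sf_level = g$sf_level[1],
               specified_sf = g$specified_sf[1], n = nrow(g),
               fp_rate = s$fp_rate, fn_rate = s$fn_rate,
               fp_from_ctd = s$fp_from_ctd, fp_from_cr = s$fp_from_cr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$regime, -out$sf_level, -out$specified_sf), ]
  rownames(out) <- NULL
  out
}
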