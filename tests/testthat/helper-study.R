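# Scaled-down replication study shared by the acceptance tests. Computed
# once per test run (memoised in this environment) with fixed seeds. The
# full design uses 100 trees per generating mode; replicate counts here are
# reduced so the whole suite stays inside a CI-scale compute budget, which
# makes the rate comparisons directional checks rather than precise
# re-estimates (see the methods vignette).

study_env <- new.env()

study_settings <- function(spec_sf, n_states = 3L) {
  likelihood_settings(rho = rep(spec_sf, n_states), ode_rel_tol = 1e-6,
                      ode_abs_tol = 1e-8)
}

study_fit_control <- list(maxit = 250)

fit_three <- function(tree, spec_sf, seed) {
  lapply(c(CR = "CR", CTD = "CTD", ETD = "ETD"), function(m) {
    fit_model(tree, model_spec(m), settings = study_settings(spec_sf),
              seed = seed + match(m, c("CR", "CTD", "ETD")),
              control = study_fit_control)
  })
}

select_quiet <- function(fits) {
  out <- tryCatch(suppressWarnings(select_best(fits)), error = function(e) NULL)
  if (is.null(out)) NA_character_ else out$best
}

acceptance_study <- function() {
  if (!is.null(study_env$study)) return(study_env$study)

  modes <- list(ETD = etd_mode(), CTD = ctd_mode(), CR = cr_mode())

  # --- small-tree arm: 100-250 tips, crown age 13.4, low extinction -------
  small_trees <- lapply(names(modes), function(mn) {
    sample_tree_set(modes[[mn]], 13.4, c(100, 250), 16,
                    seed = derive_seed(1234, match(mn, names(modes))))
  })
  names(small_trees) <- names(modes)

  small_sel <- list()
  for (mn in names(modes)) {
    for (i in seq_len(12)) {
      tr <- small_trees[[mn]][[i]]
      for (sf in c(1.0, 0.4)) {
        trimmed <- if (sf == 1) tr else
          random_trim(tr, sf, seed = derive_seed(100, i * 10 + sf * 10))$tree
        sel <- select_quiet(fit_three(trimmed, sf,
                                      seed = derive_seed(200, i * 100 + sf * 10)))
        small_sel[[length(small_sel) + 1L]] <- data.frame(
          generating = mn, replicate = i, sf = sf, selected = sel)
      }
    }
  }
  small_sel <- do.call(rbind, small_sel)

  # --- medium-tree arm (FP focus): CTD/CR only, SF 0.8 vs 0.4 vs 0.2 ------
  medium_sel <- list()
  for (mn in c("CTD", "CR")) {
    med <- sample_tree_set(modes[[mn]], 19, c(450, 650), 8,
                           seed = derive_seed(5678, match(mn, names(modes))))
    for (i in seq_along(med)) {
      for (sf in c(0.8, 0.4, 0.2)) {
        trimmed <- random_trim(med[[i]], sf,
                               seed = derive_seed(300, i * 10 + sf * 10))$tree
        sel <- select_quiet(fit_three(trimmed, sf,
                                      seed = derive_seed(400, i * 100 + sf * 10)))
        medium_sel[[length(medium_sel) + 1L]] <- data.frame(
          generating = mn, replicate = i, sf = sf, selected = sel)
      }
    }
  }
  medium_sel <- do.call(rbind, medium_sel)

  # --- mis-specification arm: small trees, true SF 0.6, random regime -----
  # CTD/CR: model selection under over- (1.0) vs under- (0.4) specified SF;
  # ETD: net-diversification estimates under specified 0.4 / 0.6 / 1.0
  over_under <- list()
  for (mn in c("CTD", "CR")) {
    for (i in seq_len(16)) {
      trimmed <- random_trim(small_trees[[mn]][[i]], 0.6,
                             seed = derive_seed(500, i))$tree
      for (spec in c(1.0, 0.4)) {
        sel <- select_quiet(fit_three(trimmed, spec,
                                      seed = derive_seed(600, i * 100 + spec * 10)))
        over_under[[length(over_under) + 1L]] <- data.frame(
          generating = mn, replicate = i, true_sf = 0.6, specified = spec,
          selected = sel)
      }
    }
  }
  over_under <- do.call(rbind, over_under)

  nd_truth <- c(0.1, 0.3, 0.5) - 0.001
  nd_rows <- list()
  random_err <- numeric(0)
  for (i in seq_len(12)) {
    trimmed <- random_trim(small_trees$ETD[[i]], 0.6,
                           seed = derive_seed(700, i))$tree
    for (spec in c(0.4, 0.6, 1.0)) {
      fit <- fit_model(trimmed, model_spec("ETD"),
                       settings = study_settings(spec),
                       seed = derive_seed(800, i * 100 + spec * 10),
                       control = study_fit_control)
      nd <- net_diversification(fit)
      nd_rows[[length(nd_rows) + 1L]] <- data.frame(
        replicate = i, specified = spec, nd_mean = mean(nd),
        abs_err = mean(abs(nd - nd_truth)))
      if (spec == 0.6) random_err <- c(random_err, mean(abs(nd - nd_truth)))
    }
  }
  nd_rows <- do.call(rbind, nd_rows)

  # --- biased-trimming arm: same ETD trees, biased trim to SF 0.6 ---------
  biased_err <- rep(NA_real_, 12)
  for (i in seq_len(12)) {
    trimmed <- NULL
    for (k in seq_len(10)) {
      trimmed <- tryCatch(
        biased_trim(small_trees$ETD[[i]], 0.6,
                    seed = derive_seed(900, i * 20 + k))$tree,
        ssesim_ineligible_tree = function(e) NULL,
        ssesim_infeasible_target = function(e) NULL)
      if (!is.null(trimmed)) break
    }
    if (is.null(trimmed)) next
    fit <- fit_model(trimmed, model_spec("ETD"),
                     settings = study_settings(0.6),
                     seed = derive_seed(1000, i), control = study_fit_control)
    biased_err[i] <- mean(abs(net_diversification(fit) - nd_truth))
  }

  study_env$study <- list(small_sel = small_sel, medium_sel = medium_sel,
                          over_under = over_under, nd = nd_rows,
                          random_err = random_err, biased_err = biased_err)
  study_env$study
}

study_fp <- function(df, subset_expr) {
  d <- df[subset_expr & df$generating %in% c("CTD", "CR") &
            !is.na(df$selected), ]
  fp_fn_rates(data.frame(generating = d$generating,
                         selected = d$selected))$fp_rate
}

study_fn <- function(df, subset_expr) {
  d <- df[subset_expr & df$generating == "ETD" & !is.na(df$selected), ]
  fp_fn_rates(data.frame(generating = d$generating,
                         selected = d$selected))$fn_rate
}
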