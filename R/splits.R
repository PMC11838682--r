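# Repeated stratified-split stability experiment: re-runs the entire
# pipeline (binning, path, AICc selection, L2 refit) on each split and
# summarizes discrimination and selection stability, with two companion
# arms (fixed support from run 0; sport-informative variables removed).

refit_on_support <- function(train, support, params, l2_strength) {
  woe <- fit_all_binnings(train, params)
  support <- intersect(support, names(woe$schemes))
  X <- woe_encode(woe, train, support)
  w <- ridge_logistic(X, train$y, l2 = l2_strength)
  structure(
    list(selected = support, weights = w, l2_strength = l2_strength,
         path = NULL, schemes = woe$schemes[support],
         train_n = length(train$y), train_events = sum(train$y == 1L)),
    class = "risk_model")
}

test_auc <- function(model, test) {
  pred <- stats::predict(model, test)
  roc_auc(pred$log_odds, test$y)$auc
}

#' Repeated stratified-split stability experiment
#'
#' For run `r` (seed `r`, `r = 0 ... n_runs - 1`): stratified split with
#' the category-coverage rejection rule, full pipeline on the training
#' half, AUC on the held-out half.  Aggregates mean and SD of AUC,
#' support sizes, and per-variable selection frequency.  Two companion
#' arms re-use the same splits: (a) L2 refits restricted to the first
#' run's selected set, and (b) the full pipeline with sport-informative
#' variables removed.  Rejected split draws advance an inner counter
#' only, so runs stay independent and reproducible.
#'
#' @param cohort A `cohort_table`.
#' @param n_runs Number of random splits.
#' @param test_fraction Test-set proportion per split.
#' @param params Binning parameters.
#' @param l2_strength Ridge penalty of the refits.
#' @param sport_pattern Regular expression identifying sport-informative
#'   variables for the ablation arm (case-insensitive).
#' @param per_group Also compute held-out AUC per group label (only for
#'   groups with both classes present)?
#' @param ... Passed to [l1_path()].
#' @return Object of class `split_experiment`: per-run tibble, AUC
#'   mean/SD for the three arms, support sizes, selection frequencies,
#'   failures, and optionally per-group AUCs.
#' @export
run_split_experiment <- function(cohort, n_runs = 20L,
                                 test_fraction = 0.2,
                                 params = binning_params(),
                                 l2_strength = 1.0,
                                 sport_pattern = "sport",
                                 per_group = FALSE, ...) {
  seeds <- seq_len(n_runs) - 1L
  all_vars <- cohort$specs$name
  sport_vars <- grep(sport_pattern, all_vars, ignore.case = TRUE,
                     value = TRUE)
  nosport_cohort <- if (length(sport_vars) > 0L) {
    drop_variables(cohort, sport_vars)
  } else {
    cohort
  }
  sel_count <- stats::setNames(rep(0L, length(all_vars)), all_vars)
  runs <- list()
  supports <- list()
  failures <- character(0)
  per_group_auc <- list()
  for (r in seeds) {
    res <- tryCatch({
      sp <- stratified_split(cohort, test_fraction, seed = r)
      model <- fit_woe_risk_model(sp$train, params,
                                  l2_strength = l2_strength, ...)
      auc <- test_auc(model, sp$test)
      nos <- stratified_split(nosport_cohort, test_fraction, seed = r)
      nosport_model <- fit_woe_risk_model(nos$train, params,
                                          l2_strength = l2_strength, ...)
      nosport_auc <- test_auc(nosport_model, nos$test)
      if (per_group && !is.null(sp$test$group)) {
        pred <- stats::predict(model, sp$test)
        g <- split(seq_along(sp$test$y), sp$test$group)
        per_group_auc[[as.character(r)]] <<- vapply(g, function(idx) {
          if (length(unique(sp$test$y[idx])) == 2L) {
            concordance_auc(pred$log_odds[idx], sp$test$y[idx])
          } else {
            NA_real_  # group lacks one class; undefined
          }
        }, numeric(1))
      }
      list(split = sp, model = model, auc = auc,
           nosport_auc = nosport_auc)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("run %d: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    supports[[as.character(r)]] <- res$model$selected
    sel_count[res$model$selected] <- sel_count[res$model$selected] + 1L
    runs[[as.character(r)]] <- tibble::tibble(
      seed = r, auc = res$auc,
      support_size = length(res$model$selected),
      rejected_attempts = res$split$rejected_attempts,
      nosport_auc = res$nosport_auc)
  }
  if (length(runs) == 0L) {
    stop("every split run failed: ", paste(failures, collapse = "; "),
         call. = FALSE)
  }
  runs <- do.call(rbind, runs)

  # Companion arm (a): fixed support from the first successful run.
  support0 <- supports[[1L]]
  fixed_auc <- vapply(runs$seed, function(r) {
    sp <- stratified_split(cohort, test_fraction, seed = r)
    m <- refit_on_support(sp$train, support0, params, l2_strength)
    test_auc(m, sp$test)
  }, numeric(1))
  runs$fixed_support_auc <- fixed_auc

  structure(
    list(n_runs = n_runs, runs = runs,
         auc_mean = mean(runs$auc), auc_sd = stats::sd(runs$auc),
         support_sizes = runs$support_size,
         selection_frequency = sel_count / nrow(runs),
         fixed_support = support0,
         fixed_auc_mean = mean(fixed_auc),
         fixed_auc_sd = stats::sd(fixed_auc),
         nosport_auc_mean = mean(runs$nosport_auc),
         nosport_auc_sd = stats::sd(runs$nosport_auc),
         sport_vars = sport_vars,
         per_group_auc = if (per_group) per_group_auc else NULL,
         failures = failures),
    class = "split_experiment")
}

#' @export
print.split_experiment <- function(x, ...) {
  cat("<split_experiment> ", nrow(x$runs), "/", x$n_runs,
      " runs; AUC ", sprintf("%.3f +/- %.3f", x$auc_mean, x$auc_sd),
      "; support ", min(x$support_sizes), "-", max(x$support_sizes),
      "\n  fixed-support AUC ",
      sprintf("%.3f +/- %.3f", x$fixed_auc_mean, x$fixed_auc_sd),
      "; no-sport AUC ",
      sprintf("%.3f +/- %.3f", x$nosport_auc_mean, x$nosport_auc_sd),
      "\n", sep = "")
  if (length(x$failures) > 0L) {
    cat("  failed runs: ", paste(x$failures, collapse = "; "), "\n")
  }
  invisible(x)
}
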