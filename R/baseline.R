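# Raw-variable benchmark: mean imputation, one-hot encoding,
# standardization, and a lightly ridge-stabilized logistic fit.

encode_baseline <- function(enc, cohort) {
  n <- length(cohort$subjects)
  cols <- list()
  for (nm in enc$continuous$name) {
    i <- match(nm, enc$continuous$name)
    v <- as.numeric(cohort$x[[nm]])
    v[is.na(v)] <- enc$continuous$mean[i]
    cols[[nm]] <- (v - enc$continuous$mean[i]) / enc$continuous$sd[i]
  }
  for (nm in names(enc$levels)) {
    v <- as.character(cohort$x[[nm]])
    for (lev in enc$levels[[nm]]) {
      cols[[paste0(nm, "=", lev)]] <- as.numeric(!is.na(v) & v == lev)
    }
  }
  do.call(cbind, cols)
}

#' Fit the raw-variable benchmark logistic model
#'
#' The comparison model the WoE pipeline is benchmarked against:
#' continuous variables are mean-imputed and standardized to zero mean
#' and unit variance using training statistics only; categorical and
#' binary variables are one-hot encoded over their training levels
#' (missing or unseen levels give an all-zero indicator row); a plain
#' logistic regression is fit with a small ridge penalty for numerical
#' stability.  Zero-variance columns are dropped with a warning.
#'
#' @param cohort Training `cohort_table` with both classes present.
#' @param ridge Small L2 penalty (absolute units).
#' @return Object of class `baseline_risk_model`.
#' @export
fit_baseline_benchmark <- function(cohort, ridge = 1e-2) {
  assert_both_classes(cohort$y)
  cont <- cohort$specs$name[cohort$specs$kind == "continuous"]
  cat_vars <- cohort$specs$name[cohort$specs$kind %in%
                                  c("categorical", "binary")]
  means <- numeric(0)
  sds <- numeric(0)
  keep <- character(0)
  for (nm in cont) {
    v <- cohort$x[[nm]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) {
      warning("dropping all-missing column '", nm, "'")
      next
    }
    mu <- mean(obs)
    v[is.na(v)] <- mu
    sdv <- stats::sd(v)
    if (!is.finite(sdv) || sdv == 0) {
      warning("dropping zero-variance column '", nm, "'")
      next
    }
    keep <- c(keep, nm)
    means <- c(means, mu)
    sds <- c(sds, sdv)
  }
  levels_map <- list()
  for (nm in cat_vars) {
    lev <- sort(unique(cohort$x[[nm]][!is.na(cohort$x[[nm]])]))
    if (length(lev) == 0L) {
      warning("dropping all-missing column '", nm, "'")
      next
    }
    levels_map[[nm]] <- lev
  }
  enc <- list(continuous = data.frame(name = keep, mean = means, sd = sds,
                                      stringsAsFactors = FALSE),
              levels = levels_map)
  X <- encode_baseline(enc, cohort)
  w <- ridge_logistic(X, cohort$y, l2 = ridge)
  structure(list(encoding = enc, weights = w, ridge = ridge,
                 train_n = length(cohort$y)),
            class = "baseline_risk_model")
}

#' @export
predict.baseline_risk_model <- function(object, cohort, ...) {
  X <- encode_baseline(object$encoding, cohort)
  eta <- unname(drop(cbind(1, X) %*% object$weights))
  tibble::tibble(subject_id = cohort$subjects, log_odds = eta,
                 probability = stats::plogis(eta))
}
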