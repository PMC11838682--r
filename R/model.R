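# L1-path variable selection on WoE-coded predictors, AICc model
# choice, and L2-regularized refit.

# Exact penalized logistic fit: minimizes the total (unscaled) negative
# log-likelihood plus 0.5 * l2 * ||w||^2 (intercept unpenalized) by BFGS
# with analytic gradient.  Used for the L2 refit and the raw-variable
# benchmark, where the penalty is meant in absolute units.
ridge_logistic <- function(X, y, l2 = 1, start = NULL) {
  X1 <- cbind(`(bias)` = 1, X)
  p <- ncol(X1)
  pen_mask <- c(0, rep(1, p - 1L))
  nll_fn <- function(w) {
    eta <- drop(X1 %*% w)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta)))) - sum(y * eta) +
      0.5 * l2 * sum(pen_mask * w^2)
  }
  grad_fn <- function(w) {
    eta <- drop(X1 %*% w)
    drop(crossprod(X1, stats::plogis(eta) - y)) + l2 * pen_mask * w
  }
  w0 <- start %||% c(stats::qlogis(mean(y)), rep(0, p - 1L))
  opt <- stats::optim(w0, nll_fn, grad_fn, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  stats::setNames(opt$par, colnames(X1))
}

total_nll <- function(eta, y) {
  sum(pmax(eta, 0) + log1p(exp(-abs(eta)))) - sum(y * eta)
}

#' Corrected Akaike Information Criterion
#'
#' `AICc = 2 nll + 2k + 2k(k+1) / (n - k - 1)`; the small-sample
#' correction term requires `n > k + 1` and the criterion approaches the
#' plain AIC as `n` grows.
#'
#' @param nll Negative log-likelihood of the fit (total, natural log).
#' @param k Number of parameters (nonzero coefficients plus intercept).
#' @param n Training sample size.
#' @return Scalar AICc.
#' @export
aicc <- function(nll, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  2 * nll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' L1-penalized logistic regression path
#'
#' Fits the lasso-penalized logistic model over a descending penalty
#' grid (default: 100 log-spaced values from the analytic all-zero
#' threshold `lambda_max = max_j |x_j'(y - ybar)| / n` down to
#' `1e-4 * lambda_max`), on the WoE-coded design without further
#' standardization.  Coefficients below the zero-snap threshold are set
#' to exactly 0.  Each path point records the penalty, the number of
#' parameters `k` (nonzero + intercept), the training negative
#' log-likelihood of the penalized coefficients, and AICc (infinite
#' where the correction is undefined).
#'
#' @param X Numeric matrix of WoE-coded predictors (no missing values).
#' @param y 0/1 labels.
#' @param grid Optional descending penalty grid; built from the data
#'   when `NULL`.
#' @param n_lambda,lambda_min_ratio Grid size and lower endpoint ratio.
#' @param zero_threshold Magnitude under which coefficients snap to 0.
#' @return Object of class `l1_path`: `lambda`, `intercept`, `beta`
#'   (variables x path points), `k`, `nll`, `aicc`, `n`.
#' @export
l1_path <- function(X, y, grid = NULL, n_lambda = 100L,
                    lambda_min_ratio = 1e-4, zero_threshold = 1e-8) {
  y <- assert_binary_outcome(y)
  assert_both_classes(y)
  X <- as.matrix(X)
  stopifnot(!anyNA(X))
  n <- nrow(X)
  if (is.null(grid)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
    grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = n_lambda))
  }
  grid <- sort(unique(grid), decreasing = TRUE)
  X_fit <- X
  padded <- FALSE
  if (ncol(X_fit) < 2L) {  # glmnet needs >= 2 columns
    X_fit <- cbind(X_fit, `..pad..` = 0)
    padded <- TRUE
  }
  fit <- glmnet::glmnet(X_fit, y, family = "binomial", alpha = 1,
                        lambda = grid, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  lambda <- fit$lambda
  beta <- as.matrix(fit$beta)
  if (padded) beta <- beta[setdiff(rownames(beta), "..pad.."), , drop = FALSE]
  intercept <- as.numeric(fit$a0)
  beta[abs(beta) < zero_threshold] <- 0
  k <- colSums(beta != 0) + 1L
  nll <- vapply(seq_along(lambda), function(j) {
    total_nll(drop(X %*% beta[, j]) + intercept[j], y)
  }, numeric(1))
  aicc_vals <- vapply(seq_along(lambda), function(j) {
    if (n > k[j] + 1L) aicc(nll[j], k[j], n) else Inf
  }, numeric(1))
  structure(
    list(lambda = lambda, intercept = intercept, beta = beta,
         k = as.integer(k), nll = nll, aicc = aicc_vals, n = n),
    class = "l1_path")
}

#' @export
print.l1_path <- function(x, ...) {
  cat("<l1_path> ", length(x$lambda), " penalty values, support 0-",
      max(x$k) - 1L, "; min AICc = ",
      sprintf("%.2f", min(x$aicc[is.finite(x$aicc)])), "\n", sep = "")
  invisible(x)
}

#' Select the AICc-best path point and refit with an L2 penalty
#'
#' The path point with minimal AICc is chosen (ties broken toward fewer
#' variables, then toward the larger penalty); its nonzero support
#' defines the selected variable set, which is refit by L2-penalized
#' logistic regression to temper collinearity among the selected
#' WoE-coded variables.  An empty support yields an intercept-only model
#' with a warning.
#'
#' @param path An [l1_path()] result.
#' @param X,y The training design and labels the path was fit on.
#' @param l2_strength Ridge penalty (absolute units; WoE features are
#'   already on the log-odds scale, so unit ridge is mild).
#' @return Object of class `risk_model` with `selected`, `weights`
#'   (bias first), `l2_strength` and the retained `path`.
#' @export
select_and_refit <- function(path, X, y, l2_strength = 1.0) {
  cand <- which(is.finite(path$aicc))
  if (length(cand) == 0L) {
    stop("no path point admits a finite AICc", call. = FALSE)
  }
  best <- cand[order(path$aicc[cand], path$k[cand],
                     -path$lambda[cand])][1L]
  support <- rownames(path$beta)[path$beta[, best] != 0]
  if (length(support) == 0L) {
    warning("selected support is empty; returning intercept-only model")
  }
  start <- c(path$intercept[best], path$beta[support, best])
  w <- ridge_logistic(X[, support, drop = FALSE], y, l2 = l2_strength,
                      start = start)
  structure(
    list(selected = support, weights = w, l2_strength = l2_strength,
         path = path, schemes = NULL,
         selected_lambda = path$lambda[best],
         train_n = length(y), train_events = sum(y == 1L)),
    class = "risk_model")
}

#' Fit the full WoE risk pipeline on a training cohort
#'
#' Runs supervised binning ([fit_all_binnings()]), WoE-encodes the
#' training table, fits the L1 path, selects by AICc and refits with an
#' L2 penalty.  All supervised steps see the training cohort only.
#'
#' @param train Training `cohort_table` (both classes present).
#' @param params Binning parameters.
#' @param l2_strength Ridge penalty of the refit.
#' @param ... Passed to [l1_path()].
#' @return A `risk_model` with attached binning schemes and the
#'   per-variable IV manifest.
#' @export
fit_woe_risk_model <- function(train, params = binning_params(),
                               l2_strength = 1.0, ...) {
  woe <- fit_all_binnings(train, params)
  X <- woe_encode(woe, train)
  path <- l1_path(X, train$y, ...)
  model <- select_and_refit(path, X, train$y, l2_strength)
  model$schemes <- woe$schemes[model$selected]
  model$iv_manifest <- woe$manifest
  model$binning_params <- params
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", length(x$selected), " selected variables; ",
      "trained on n = ", x$train_n, " (", x$train_events, " events)\n",
      sep = "")
  invisible(x)
}

#' Predict injury risk for a cohort
#'
#' `log_odds = w0 + sum_i w_i WoE_i(x_i)`;
#' `probability = 1 / (1 + exp(-log_odds))`.  Missing inputs flow
#' through each variable's missing bin, so predictions are never
#' missing.
#'
#' @param object A fitted `risk_model`.
#' @param cohort A `cohort_table` containing every selected variable.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `log_odds`, `probability`.
#' @export
predict.risk_model <- function(object, cohort, ...) {
  w <- object$weights
  if (length(object$selected) > 0L) {
    X <- woe_encode(object$schemes, cohort, object$selected)
    eta <- unname(drop(X %*% w[object$selected])) + w[["(bias)"]]
  } else {
    eta <- rep(w[["(bias)"]], length(cohort$subjects))
  }
  tibble::tibble(subject_id = cohort$subjects, log_odds = eta,
                 probability = stats::plogis(eta))
}

#' Serialize a fitted risk model to a structured text bundle
#'
#' JSON holding the weights, selected names, binning schemes and the
#' path trace (penalty, support size, negative log-likelihood, AICc per
#' point); [read_risk_model()] restores a model whose predictions are
#' bit-identical.
#'
#' @param model A `risk_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_risk_model <- function(model, path) {
  bundle <- list(
    selected = model$selected,
    weights = as.list(model$weights),
    l2_strength = model$l2_strength,
    selected_lambda = model$selected_lambda,
    train_n = model$train_n,
    train_events = model$train_events,
    path_trace = list(lambda = model$path$lambda,
                      k = model$path$k,
                      nll = model$path$nll,
                      aicc = ifelse(is.finite(model$path$aicc),
                                    model$path$aicc, NA_real_)),
    schemes = lapply(model$schemes, scheme_to_list)
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Reload a risk model written by [write_risk_model()]
#'
#' @param path File path.
#' @return A `risk_model` (path trace retained without per-point
#'   coefficient vectors).
#' @export
read_risk_model <- function(path) {
  b <- jsonlite::read_json(path)
  pt <- b$path_trace
  num <- function(x) vapply(x, function(v) {
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  aicc_vals <- num(pt$aicc)
  aicc_vals[is.na(aicc_vals)] <- Inf
  structure(
    list(selected = as.character(unlist(b$selected)),
         weights = stats::setNames(num(b$weights), names(b$weights)),
         l2_strength = as.numeric(b$l2_strength),
         path = list(lambda = num(pt$lambda),
                     k = as.integer(num(pt$k)),
                     nll = num(pt$nll), aicc = aicc_vals),
         schemes = lapply(b$schemes, list_to_scheme),
         selected_lambda = as.numeric(b$selected_lambda),
         train_n = as.integer(b$train_n),
         train_events = as.integer(b$train_events)),
    class = "risk_model")
}
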