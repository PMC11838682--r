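# Closed-form SHAP attributions for the linear WoE model.
#
# For a linear model on WoE-coded variables the Shapley contribution of
# variable i to a subject's log-odds is exactly
# phi_i = w_i * (WoE_i(x_i) - mean WoE_i over the reference sample),
# and the contributions sum to the subject's log-odds minus the mean
# reference log-odds (local accuracy).

#' Per-subject SHAP contributions on the log-odds scale
#'
#' @param model A fitted `risk_model`.
#' @param reference Reference `cohort_table` whose per-variable mean WoE
#'   anchors the attributions; by convention the training set.
#' @param subjects Cohort to explain; defaults to the reference.
#' @return Object of class `contribution_set`: `phi` (subjects by
#'   selected variables), `reference_means`, `reference_n`,
#'   `log_odds`, and `base_log_odds` (the mean reference log-odds).
#' @export
shap_values <- function(model, reference, subjects = reference) {
  if (length(reference$subjects) == 0L) {
    stop("reference cohort is empty", call. = FALSE)
  }
  sel <- model$selected
  w <- model$weights[sel]
  R <- woe_encode(model$schemes, reference, sel)
  S <- woe_encode(model$schemes, subjects, sel)
  ref_means <- colMeans(R)
  phi <- sweep(S, 2L, ref_means) * rep(w, each = nrow(S))
  eta <- drop(S %*% w) + model$weights[["(bias)"]]
  structure(
    list(phi = phi,
         reference_means = ref_means,
         reference_n = nrow(R),
         log_odds = eta,
         base_log_odds = model$weights[["(bias)"]] +
           sum(w * ref_means)),
    class = "contribution_set")
}

#' Rank variables by mean absolute SHAP contribution
#'
#' Variables sorted descending by `(1/N) sum |phi_i|`, ties broken
#' alphabetically — the standard global-importance summary for a linear
#' model's attributions.
#'
#' @param contributions A `contribution_set` from [shap_values()].
#' @param top_k Number of rows to report.
#' @return Tibble with `rank`, `variable`, `mean_abs_shap`.
#' @export
rank_variables <- function(contributions, top_k = 10L) {
  phi <- contributions$phi
  if (is.null(phi) || ncol(phi) == 0L) {
    stop("contribution set is empty", call. = FALSE)
  }
  score <- colMeans(abs(phi))
  if (top_k > length(score)) {
    warning("top_k exceeds the number of variables; truncating to ",
            length(score))
    top_k <- length(score)
  }
  ord <- order(-score, names(score))
  tibble::tibble(rank = seq_len(top_k),
                 variable = names(score)[ord][seq_len(top_k)],
                 mean_abs_shap = unname(score[ord][seq_len(top_k)]))
}
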