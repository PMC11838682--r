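# Synthetic cohort generator with known ground truth.
#
# Emulates the statistical structure the risk pipeline assumes: mixed
# variable types across four assessment timepoints, piecewise-constant
# (threshold) effects on the log-odds of injury, correlated variable
# blocks, heavy missingness, and sport-varying base rates.

#' Default sport event-rate profile
#'
#' Per-sport event rates aggregated from the collegiate cohort
#' composition in [study_injury_counts()], with sampling weights
#' proportional to each sport's size in that cohort.  Rates are clamped
#' to \[0.02, 0.98\] before conversion to log-odds shifts so empty cells
#' stay finite.
#'
#' @return Named numeric vector of event rates with a `weights`
#'   attribute.
#' @export
default_sport_rates <- function() {
  counts <- study_injury_counts()
  agg <- stats::aggregate(cbind(non_event, event) ~ sport, data = counts,
                          FUN = sum)
  rates <- agg$event / (agg$event + agg$non_event)
  names(rates) <- agg$sport
  attr(rates, "weights") <- agg$event + agg$non_event
  rates
}

#' Default threshold-effect configuration
#'
#' Each informative continuous variable shifts the log-odds of injury by
#' a piecewise-constant amount with cutpoints at 9 and 12 on a
#' days-scale N(10, 3) score.  Odd-numbered variables carry a monotone
#' step profile (-0.45, 0, +0.45); even-numbered ones a U-shaped profile
#' (+0.4, -0.4, +0.4), emulating the clinically observed elevated risk
#' at short recovery times.
#'
#' @param n_informative Number of informative variables.
#' @return List of `list(variable, cutpoints, shifts)` entries.
#' @export
default_threshold_effects <- function(n_informative = 5L) {
  lapply(seq_len(n_informative), function(i) {
    list(
      variable = sprintf("Marker%02d Acute", i),
      cutpoints = c(9, 12),
      shifts = if (i %% 2L == 1L) c(-0.45, 0, 0.45) else c(0.4, -0.4, 0.4)
    )
  })
}

#' Specify a synthetic cohort
#'
#' Collects the generator's parameters.  Defaults describe the package's
#' desk-scale preset: 50 predictors (5 informative threshold-effect
#' variables, 40 correlated noise variables spread over four timepoints,
#' 4 noise categoricals, and Sport), 35% missingness completely at
#' random, and sport base rates from the collegiate cohort profile.
#'
#' @param n_subjects Number of subjects.
#' @param n_informative Continuous variables with true threshold effects.
#' @param n_noise Continuous noise variables (grouped into measures
#'   observed at up to four timepoints, correlated within measure).
#' @param n_categorical Noise categorical variables (4 levels, no
#'   effect).
#' @param block_correlation Within-measure correlation of noise
#'   variables, in \[0, 1).
#' @param missing_rate Proportion of entries masked as missing (Sport is
#'   never masked).
#' @param threshold_effects List of `list(variable, cutpoints, shifts)`;
#'   see [default_threshold_effects()].
#' @param sport_rates Named event-rate vector (or `NULL` to omit the
#'   Sport variable); see [default_sport_rates()].
#' @param base_log_odds Intercept of the latent log-odds.
#' @param missing_mode `"mcar"` (default) or `"outcome"`; the latter
#'   makes missingness probability depend on the outcome so the missing
#'   bin carries evidence.
#' @param missing_outcome_shift Log-odds shift of the missingness
#'   probability for events under `missing_mode = "outcome"`.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 500L, n_informative = 5L,
                           n_noise = 40L, n_categorical = 4L,
                           block_correlation = 0.5, missing_rate = 0.35,
                           threshold_effects =
                             default_threshold_effects(n_informative),
                           sport_rates = default_sport_rates(),
                           base_log_odds = 0.5,
                           missing_mode = c("mcar", "outcome"),
                           missing_outcome_shift = 0.7,
                           seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_informative + n_noise + n_categorical >= 1L,
            missing_rate >= 0, missing_rate < 1,
            block_correlation >= 0, block_correlation < 1)
  if (!is.null(sport_rates)) {
    stopifnot(all(sport_rates >= 0), all(sport_rates <= 1))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         n_categorical = as.integer(n_categorical),
         block_correlation = block_correlation,
         missing_rate = missing_rate,
         threshold_effects = threshold_effects,
         sport_rates = sport_rates,
         base_log_odds = base_log_odds,
         missing_mode = missing_mode,
         missing_outcome_shift = missing_outcome_shift,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Preset mirroring the shape of the motivating study
#'
#' 194 subjects and 135 variables (5 informative, 125 noise, 4
#' categorical, Sport).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
generator_spec_paper_scale <- function(seed = 1L, ...) {
  generator_spec(n_subjects = 194L, n_informative = 5L, n_noise = 125L,
                 n_categorical = 4L, seed = seed, ...)
}

piecewise_shift <- function(x, cutpoints, shifts) {
  stopifnot(length(shifts) == length(cutpoints) + 1L)
  out <- shifts[1L + findInterval(x, cutpoints)]
  out[is.na(x)] <- 0
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Continuous noise variables are drawn from correlated measure blocks
#' (a shared latent factor per measure across timepoints); informative
#' variables contribute piecewise-constant log-odds shifts at their
#' stated cutpoints, so optimal binning has true edges to recover; Sport
#' contributes a level shift reproducing its configured event rate; the
#' outcome is Bernoulli in the logistic of the latent score; missingness
#' is applied at `missing_rate` to every variable except Sport.
#'
#' Under the default MCAR mode the mask is drawn before scoring and a
#' masked entry contributes no log-odds shift, so `latent_score` is the
#' generating log-odds of the observable process and `bayes_auc` is an
#' attainable ceiling for models fit to the released table — the basis
#' of the package's parameter-recovery tests.  Under
#' `missing_mode = "outcome"` the score uses the complete values and
#' the mask is drawn given the outcome, so missingness itself carries
#' evidence (exercising the predictive missing bin).
#'
#' @param spec A [generator_spec()].
#' @return A list with `cohort` (a `cohort_table`) and `truth`
#'   (`informative_set`, `latent_score`, `bayes_auc`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  local_seed(spec$seed, {
    n <- spec$n_subjects
    cols <- list()
    specs_rows <- list()
    add_var <- function(name, kind, timepoint, values) {
      cols[[name]] <<- values
      specs_rows[[name]] <<- tibble::tibble(
        name = name, kind = kind, timepoint = timepoint,
        higher_is_worse = NA)
    }

    # Informative continuous variables: independent N(10, 3)
    inf_names <- vapply(spec$threshold_effects, function(e) e$variable,
                        character(1))
    if (spec$n_informative > 0L) {
      stopifnot(length(inf_names) == spec$n_informative)
      for (nm in inf_names) {
        add_var(nm, "continuous", "acute", stats::rnorm(n, 10, 3))
      }
    }

    # Noise continuous variables: measures x timepoints, correlated
    # within measure through a shared latent factor.
    if (spec$n_noise > 0L) {
      tps <- names(TIMEPOINT_LABELS)
      n_measures <- ceiling(spec$n_noise / 4L)
      made <- 0L
      rho <- spec$block_correlation
      for (m in seq_len(n_measures)) {
        f <- stats::rnorm(n)
        for (t in seq_along(tps)) {
          if (made >= spec$n_noise) break
          made <- made + 1L
          vals <- 10 + 3 * (sqrt(rho) * f +
                              sqrt(1 - rho) * stats::rnorm(n))
          add_var(sprintf("Measure%02d %s", m, TIMEPOINT_LABELS[[tps[t]]]),
                  "continuous", tps[t], vals)
        }
      }
    }

    # Noise categoricals: four uniform levels, no effect.
    for (k in seq_len(spec$n_categorical)) {
      add_var(sprintf("Category%02d", k), "categorical", "static",
              sample(LETTERS[1:4], n, replace = TRUE))
    }

    # Sport: level shift reproducing the configured event rate.
    sport_shift <- rep(0, n)
    if (!is.null(spec$sport_rates)) {
      w <- attr(spec$sport_rates, "weights") %||%
        rep(1, length(spec$sport_rates))
      sport <- sample(names(spec$sport_rates), n, replace = TRUE,
                      prob = w / sum(w))
      clamped <- pmin(pmax(spec$sport_rates, 0.02), 0.98)
      sport_shift <- stats::qlogis(clamped)[sport] - spec$base_log_odds
      add_var("Sport", "categorical", "static", sport)
    }

    # Missingness mask (every variable except Sport) and latent score.
    #
    # Under MCAR the mask is drawn first, independently of everything,
    # and masked entries contribute nothing to the latent score: the
    # ground truth is the generating log-odds of the observable
    # process, so its concordance is an attainable ceiling for models
    # fit to the released data.  Under outcome-dependent missingness
    # the score uses the complete values and the mask is drawn given
    # the outcome, so the missingness pattern itself carries evidence.
    maskable <- setdiff(names(cols), "Sport")
    if (spec$missing_mode == "mcar" && spec$missing_rate > 0) {
      for (nm in maskable) {
        cols[[nm]][stats::runif(n) < spec$missing_rate] <- NA
      }
    }
    contrib <- rep(0, n)
    for (e in spec$threshold_effects) {
      contrib <- contrib +
        piecewise_shift(cols[[e$variable]], e$cutpoints, e$shifts)
    }
    base <- spec$base_log_odds
    for (attempt in 1:10) {
      latent <- base + contrib + sport_shift
      y <- stats::rbinom(n, 1L, stats::plogis(latent))
      if (length(unique(y)) == 2L) break
      base <- base + if (all(y == 0L)) 1 else -1
      if (attempt == 10L) {
        stop("generate_cohort: could not obtain both outcome classes",
             call. = FALSE)
      }
    }
    if (spec$missing_mode == "outcome" && spec$missing_rate > 0) {
      p_miss <- stats::plogis(stats::qlogis(spec$missing_rate) +
                                spec$missing_outcome_shift * (2 * y - 1))
      for (nm in maskable) {
        cols[[nm]][stats::runif(n) < p_miss] <- NA
      }
    }

    tab <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    tab$outcome <- y
    cohort <- cohort_table(
      tab, do.call(rbind, unname(specs_rows)), outcome = "outcome",
      group = if (!is.null(spec$sport_rates)) "Sport" else NULL)

    informative <- inf_names[vapply(spec$threshold_effects, function(e) {
      any(e$shifts != 0)
    }, logical(1))]
    truth <- list(informative_set = informative,
                  latent_score = latent,
                  bayes_auc = if (length(unique(y)) == 2L) {
                    concordance_auc(latent, y)
                  } else {
                    NA_real_
                  })
    list(cohort = cohort, truth = truth)
  })
}

#' Concordance of the generator's latent score against the outcome
#'
#' Same pairwise-concordance estimator as [roc_auc()]; the result bounds
#' what any model fit to the generated data can achieve.
#'
#' @param truth Ground-truth list from [generate_cohort()].
#' @param outcome 0/1 labels aligned with `truth$latent_score`.
#' @return Scalar AUC.
#' @export
estimate_bayes_auc <- function(truth, outcome) {
  outcome <- assert_binary_outcome(outcome)
  assert_both_classes(outcome)
  stopifnot(length(truth$latent_score) == length(outcome))
  concordance_auc(truth$latent_score, outcome)
}
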