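# Supervised optimal binning and Weight-of-Evidence transformation.
#
# Continuous variables are quantile pre-binned, then contiguous cells
# are merged by exact dynamic programming to maximize Information Value
# under a minimum-bin-size and maximum-bin-count constraint; categorical
# levels are ordered by event rate and merged with the same machinery.
# Missing values always form their own bin, so the transform imputes
# them with data-driven evidence rather than a fill-in value.  Fitting
# uses training data only.

#' Binning parameters
#'
#' @param min_bin_fraction Minimum fraction of the non-missing training
#'   values a bin must hold.
#' @param max_bins Maximum number of non-missing bins.
#' @param pre_bins Number of quantile pre-bins for continuous variables.
#' @param smoothing Pseudo-count added per class per bin so Weights of
#'   Evidence stay finite when a bin holds a single class.
#' @param complexity_penalty Chi-square-scale charge per bin beyond the
#'   first when choosing how many bins to keep; it enters the bin-count
#'   score as `complexity_penalty * (1/E + 1/NE)` per extra bin, the
#'   IV contribution of a one-degree chi-square fluctuation (`E`, `NE`
#'   the training event/non-event totals).  Raw IV never decreases
#'   under further splitting, so some such charge is needed for an
#'   uninformative variable to collapse to a single bin.  The default
#'   (`NULL`) uses a one-degree chi-square quantile Bonferroni-corrected
#'   for the number of candidate boundaries of the variable at hand,
#'   `qchisq(1 - 0.05 / (m - 1), 1)` for `m` cells: each extra bin is
#'   the best of `~m` chance splits, so an uncorrected 95% point
#'   under-charges and null variables retain spurious bins.  Set to 0 to
#'   recover the unpenalized IV maximum.
#' @return An object of class `binning_params`.
#' @export
binning_params <- function(min_bin_fraction = 0.05, max_bins = 10L,
                           pre_bins = 20L, smoothing = 0.5,
                           complexity_penalty = NULL) {
  stopifnot(min_bin_fraction >= 0, min_bin_fraction < 1,
            max_bins >= 1L, pre_bins >= 2L, smoothing >= 0,
            is.null(complexity_penalty) || complexity_penalty >= 0)
  structure(list(min_bin_fraction = min_bin_fraction,
                 max_bins = as.integer(max_bins),
                 pre_bins = as.integer(pre_bins),
                 smoothing = smoothing,
                 complexity_penalty = complexity_penalty),
            class = "binning_params")
}

#' Weight of Evidence of one bin
#'
#' `ln[((e + s) / (E + s B)) / ((ne + s) / (NE + s B))]` where `e`/`ne`
#' are the bin's event and non-event counts, `E`/`NE` the training
#' totals, `s` the pseudo-count and `B` the number of bins in the
#' scheme.  Positive values are evidence for the event (injury).
#'
#' @param n_event_bin,n_nonevent_bin Bin counts.
#' @param n_event_total,n_nonevent_total Training totals (over all
#'   bins, including the missing bin).
#' @param smoothing Pseudo-count per class per bin.
#' @param n_bins Number of bins `B` in the scheme.
#' @return Scalar WoE (natural log).
#' @export
woe_value <- function(n_event_bin, n_nonevent_bin, n_event_total,
                      n_nonevent_total, smoothing = 0.5, n_bins = 1L) {
  stopifnot(n_event_total > 0, n_nonevent_total > 0,
            n_event_bin <= n_event_total,
            n_nonevent_bin <= n_nonevent_total, smoothing >= 0)
  if (smoothing == 0 && (n_event_bin == 0 || n_nonevent_bin == 0)) {
    stop("zero bin count: a positive smoothing pseudo-count is required",
         call. = FALSE)
  }
  pe <- (n_event_bin + smoothing) / (n_event_total + smoothing * n_bins)
  pn <- (n_nonevent_bin + smoothing) /
    (n_nonevent_total + smoothing * n_bins)
  log(pe / pn)
}

# Smoothed (p_event - p_nonevent) * woe contribution of one bin.
iv_term <- function(e, ne, E, NE, s, B) {
  pe <- (e + s) / (E + s * B)
  pn <- (ne + s) / (NE + s * B)
  (pe - pn) * log(pe / pn)
}

#' Information Value of a fitted scheme
#'
#' `IV = sum over bins of (p_event_bin - p_nonevent_bin) * WoE_bin`,
#' with class proportions smoothed exactly as in [woe_value()].  IV is
#' non-negative and measures the binned variable's discriminatory
#' power.
#'
#' @param scheme A `binning_scheme` from [fit_binning()].
#' @return Scalar IV.
#' @export
information_value <- function(scheme) {
  b <- scheme$bins
  sum(iv_term(b$n_event, b$n_nonevent, scheme$n_event_total,
              scheme$n_nonevent_total, scheme$smoothing, nrow(b)))
}

# Exact DP over contiguous partitions of ordered cells.
# Returns, for each bin count b, the IV-maximal partition (boundaries as
# last-cell indices) and its total IV including the missing-bin term.
dp_partition <- function(e, ne, E, NE, s, min_count, max_bins,
                         has_missing, miss_e = 0L, miss_ne = 0L) {
  m <- length(e)
  ce <- c(0, cumsum(e))
  cn <- c(0, cumsum(ne))
  bmax <- min(max_bins, m)
  out <- vector("list", bmax)
  for (b in seq_len(bmax)) {
    B <- b + has_missing
    term <- function(i, j) { # cells i..j as one bin
      cnt_e <- ce[j + 1L] - ce[i]
      cnt_n <- cn[j + 1L] - cn[i]
      if (cnt_e + cnt_n < min_count) return(-Inf)
      v <- iv_term(cnt_e, cnt_n, E, NE, s, B)
      if (!is.finite(v)) return(-Inf)
      v
    }
    f <- matrix(-Inf, b, m)
    ptr <- matrix(0L, b, m)
    for (i in seq_len(m)) f[1L, i] <- term(1L, i)
    if (b > 1L) {
      for (bb in 2:b) {
        for (i in bb:m) {
          best <- -Inf
          arg <- 0L
          for (j in (bb - 1L):(i - 1L)) {
            if (f[bb - 1L, j] == -Inf) next
            v <- f[bb - 1L, j] + term(j + 1L, i)
            if (v > best) {
              best <- v
              arg <- j
            }
          }
          f[bb, i] <- best
          ptr[bb, i] <- arg
        }
      }
    }
    if (f[b, m] == -Inf) {
      out[[b]] <- NULL
      next
    }
    bounds <- integer(b)
    i <- m
    for (bb in b:1L) {
      bounds[bb] <- i
      i <- if (bb > 1L) ptr[bb, i] else 0L
    }
    total <- f[b, m]
    if (has_missing) {
      total <- total + iv_term(miss_e, miss_ne, E, NE, s, B)
    }
    out[[b]] <- list(bounds = bounds, iv = total)
  }
  out
}

#' Fit an optimal binning scheme for one variable
#'
#' Continuous variables are pre-binned at training-quantile edges (at
#' most `pre_bins` cells), then cells are merged by exact dynamic
#' programming to the contiguous partition maximizing total IV subject
#' to the minimum bin fraction, for each candidate bin count up to
#' `max_bins`; the kept bin count maximizes IV minus the per-bin
#' complexity charge.  Categorical levels are ordered by event rate
#' (ties alphabetically) and merged with the same optimizer.  Missing
#' values always form their own bin when present.  Outer continuous
#' bins extend to +/-Inf, and bins are half-open `[lo, hi)`.
#'
#' Degenerate inputs: an all-missing column yields a scheme with only
#' the missing bin; a constant column yields a single bin (plus the
#' missing bin if applicable).
#'
#' @param values One variable's training column (numeric, or character
#'   for categorical variables), with `NA` for missing.
#' @param outcome 0/1 training labels (both classes required).
#' @param params A [binning_params()].
#' @param variable Variable name recorded in the scheme.
#' @return An object of class `binning_scheme`: `variable`, `type`,
#'   `bins` (data frame with `lo`, `hi`, `levels`, `is_missing`,
#'   `n_event`, `n_nonevent`, `woe`), `iv`, `smoothing`, training
#'   totals, and a training fingerprint.
#' @export
fit_binning <- function(values, outcome, params = binning_params(),
                        variable = "x") {
  y <- assert_binary_outcome(outcome)
  assert_both_classes(y)
  stopifnot(length(values) == length(y))
  s <- params$smoothing
  E <- sum(y == 1L)
  NE <- sum(y == 0L)
  miss <- is.na(values)
  has_missing <- any(miss)
  miss_e <- sum(y[miss] == 1L)
  miss_ne <- sum(y[miss] == 0L)
  v <- values[!miss]
  yv <- y[!miss]
  type <- if (is.numeric(values)) "continuous" else "categorical"

  finish <- function(bins_df) {
    B <- nrow(bins_df)
    bins_df$woe <- vapply(seq_len(B), function(i) {
      woe_value(bins_df$n_event[i], bins_df$n_nonevent[i], E, NE, s, B)
    }, numeric(1))
    scheme <- structure(
      list(variable = variable, type = type, bins = bins_df,
           iv = NA_real_, smoothing = s,
           n_event_total = E, n_nonevent_total = NE,
           fitted_on = sprintf("n=%d;events=%d", E + NE, E)),
      class = "binning_scheme")
    scheme$iv <- information_value(scheme)
    scheme
  }
  missing_bin_row <- function() {
    data.frame(lo = NA_real_, hi = NA_real_,
               levels = I(list(NULL)), is_missing = TRUE,
               n_event = miss_e, n_nonevent = miss_ne, woe = NA_real_)
  }

  if (length(v) == 0L) {  # everything missing
    return(finish(missing_bin_row()))
  }

  # Order the non-missing support into cells.
  if (type == "continuous") {
    if (length(unique(v)) == 1L) {
      edges <- numeric(0)
      cell <- rep(1L, length(v))
    } else {
      probs <- seq_len(params$pre_bins - 1L) / params$pre_bins
      edges <- unique(stats::quantile(v, probs = probs, type = 7,
                                      names = FALSE))
      cell <- findInterval(v, edges) + 1L
    }
    m <- length(edges) + 1L
    cell_levels <- NULL
  } else {
    lev <- sort(unique(v))
    cnt_e <- vapply(lev, function(l) sum(yv[v == l] == 1L), integer(1))
    cnt_n <- vapply(lev, function(l) sum(yv[v == l] == 0L), integer(1))
    rate <- (cnt_e + 0.5) / (cnt_e + cnt_n + 1)
    ord <- order(rate, lev)
    lev <- lev[ord]
    cell <- match(v, lev)
    m <- length(lev)
    cell_levels <- lev
    edges <- NULL
  }
  e <- vapply(seq_len(m), function(i) sum(yv[cell == i] == 1L), integer(1))
  ne <- vapply(seq_len(m), function(i) sum(yv[cell == i] == 0L), integer(1))
  # drop empty pre-bin cells (possible when quantile edges tie)
  keep <- (e + ne) > 0L
  if (type == "continuous" && !all(keep)) {
    kept <- which(keep)
    edges <- edges[kept[-length(kept)]]
    e <- e[keep]
    ne <- ne[keep]
    m <- length(e)
  }

  min_count <- max(1L, ceiling(params$min_bin_fraction * length(v)))
  cand <- dp_partition(e, ne, E, NE, s, min_count, params$max_bins,
                       has_missing, miss_e, miss_ne)
  feasible <- which(!vapply(cand, is.null, logical(1)))
  if (length(feasible) == 0L) {
    # constraints unsatisfiable for every b: fall back to a single bin
    cand <- dp_partition(e, ne, E, NE, s, 1L, 1L, has_missing,
                         miss_e, miss_ne)
    feasible <- 1L
  }
  # A chance split contributes ~chi-square(1) * (1/E + 1/NE) to IV, and
  # the DP takes the best of ~m candidate boundaries per extra bin, so
  # the default charge is a Bonferroni-corrected chi-square quantile on
  # that scale.
  penalty <- params$complexity_penalty %||%
    stats::qchisq(1 - 0.05 / max(m - 1L, 1L), 1)
  per_bin_charge <- penalty * (1 / E + 1 / NE)
  score <- vapply(feasible, function(b) {
    cand[[b]]$iv - per_bin_charge * (b - 1L)
  }, numeric(1))
  b_star <- feasible[which.max(score)]
  bounds <- cand[[b_star]]$bounds

  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  rows <- lapply(seq_along(bounds), function(k) {
    idx <- starts[k]:bounds[k]
    if (type == "continuous") {
      data.frame(
        lo = if (k == 1L) -Inf else edges[starts[k] - 1L],
        hi = if (k == length(bounds)) Inf else edges[bounds[k]],
        levels = I(list(NULL)), is_missing = FALSE,
        n_event = sum(e[idx]), n_nonevent = sum(ne[idx]),
        woe = NA_real_)
    } else {
      data.frame(
        lo = NA_real_, hi = NA_real_,
        levels = I(list(cell_levels[idx])), is_missing = FALSE,
        n_event = sum(e[idx]), n_nonevent = sum(ne[idx]),
        woe = NA_real_)
    }
  })
  bins_df <- do.call(rbind, rows)
  if (has_missing) bins_df <- rbind(bins_df, missing_bin_row())
  finish(bins_df)
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("<binning_scheme> ", x$variable, " (", x$type, "): ",
      nrow(x$bins), " bins, IV = ", sprintf("%.4f", x$iv), "\n", sep = "")
  invisible(x)
}

#' Apply a fitted scheme to a column
#'
#' Each value is replaced by its bin's Weight of Evidence.  Missing
#' values take the missing bin's WoE when that bin was fitted and 0
#' (neutral evidence) otherwise; categories unseen in training also map
#' to 0.  The output never contains missing entries.
#'
#' @param scheme A `binning_scheme`.
#' @param values Column to transform (may contain `NA` and unseen
#'   levels).
#' @return Numeric WoE-coded vector.
#' @export
woe_transform <- function(scheme, values) {
  bins <- scheme$bins
  reg <- which(!bins$is_missing)
  miss_woe <- if (any(bins$is_missing)) bins$woe[bins$is_missing][1L] else 0
  out <- rep(miss_woe, length(values))
  ok <- !is.na(values)
  if (length(reg) > 0L && any(ok)) {
    if (scheme$type == "continuous") {
      interior <- bins$hi[reg]
      interior <- interior[is.finite(interior)]
      idx <- findInterval(as.numeric(values[ok]), interior) + 1L
      out[ok] <- bins$woe[reg][idx]
    } else {
      lev <- unlist(lapply(reg, function(i) bins$levels[[i]]))
      woe_of <- unlist(lapply(reg, function(i) {
        rep(bins$woe[i], length(bins$levels[[i]]))
      }))
      pos <- match(as.character(values[ok]), lev)
      w <- woe_of[pos]
      w[is.na(pos)] <- 0  # unseen category: neutral evidence
      out[ok] <- w
    }
  } else if (any(ok)) {
    out[ok] <- 0
  }
  out
}

#' Fit binning schemes for every variable of a training cohort
#'
#' One scheme per dictionary variable, fitted on the supplied training
#' cohort only.  Variables whose fit fails are excluded with a logged
#' reason.  The returned manifest lists per-variable IV in descending
#' order.
#'
#' @param cohort Training `cohort_table` with both classes present.
#' @param params A [binning_params()].
#' @return An object of class `woe_fit`: `schemes` (named list),
#'   `manifest` (tibble `variable`, `kind`, `n_bins`, `iv`), `excluded`,
#'   `params`.
#' @export
fit_all_binnings <- function(cohort, params = binning_params()) {
  assert_both_classes(cohort$y)
  schemes <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(cohort$specs))) {
    nm <- cohort$specs$name[i]
    sc <- tryCatch(
      fit_binning(cohort$x[[nm]], cohort$y, params, variable = nm),
      error = function(e) {
        message("excluding '", nm, "': ", conditionMessage(e))
        NULL
      })
    if (is.null(sc)) {
      excluded <- c(excluded, nm)
    } else {
      schemes[[nm]] <- sc
    }
  }
  manifest <- tibble::tibble(
    variable = names(schemes),
    kind = unname(vapply(schemes, function(s) s$type, character(1))),
    n_bins = unname(vapply(schemes, function(s) nrow(s$bins), integer(1))),
    iv = unname(vapply(schemes, function(s) s$iv, numeric(1)))
  )
  manifest <- manifest[order(-manifest$iv, manifest$variable), ]
  structure(list(schemes = schemes, manifest = manifest,
                 excluded = excluded, params = params),
            class = "woe_fit")
}

#' WoE-encode a cohort with fitted schemes
#'
#' @param fit A `woe_fit` (or a named list of `binning_scheme`s).
#' @param cohort A `cohort_table` whose columns cover the schemes used.
#' @param variables Variables to encode; defaults to all fitted ones.
#' @return Numeric matrix, subjects by variables, with no missing
#'   entries.
#' @export
woe_encode <- function(fit, cohort, variables = NULL) {
  schemes <- if (inherits(fit, "woe_fit")) fit$schemes else fit
  variables <- variables %||% names(schemes)
  absent <- setdiff(variables, names(cohort$x))
  if (length(absent) > 0L) {
    stop("cohort lacks variable(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  X <- vapply(variables, function(nm) {
    woe_transform(schemes[[nm]], cohort$x[[nm]])
  }, numeric(length(cohort$subjects)))
  X <- matrix(X, nrow = length(cohort$subjects),
              dimnames = list(cohort$subjects, variables))
  X
}

# --- serialization ---------------------------------------------------

scheme_to_list <- function(s) {
  list(variable = s$variable, type = s$type, smoothing = s$smoothing,
       n_event_total = s$n_event_total,
       n_nonevent_total = s$n_nonevent_total,
       iv = s$iv, fitted_on = s$fitted_on,
       bins = lapply(seq_len(nrow(s$bins)), function(i) {
         b <- s$bins[i, ]
         list(lo = encode_inf(b$lo), hi = encode_inf(b$hi),
              levels = b$levels[[1L]], is_missing = b$is_missing,
              n_event = b$n_event, n_nonevent = b$n_nonevent,
              woe = b$woe)
       }))
}

encode_inf <- function(x) {
  if (is.na(x)) return(NULL)
  if (x == Inf) return("+Inf")
  if (x == -Inf) return("-Inf")
  x
}

decode_inf <- function(x) {
  if (is.null(x)) return(NA_real_)
  if (identical(x, "+Inf")) return(Inf)
  if (identical(x, "-Inf")) return(-Inf)
  as.numeric(x)
}

list_to_scheme <- function(l) {
  bins <- do.call(rbind, lapply(l$bins, function(b) {
    data.frame(lo = decode_inf(b$lo), hi = decode_inf(b$hi),
               levels = I(list(if (is.null(b$levels)) {
                 NULL
               } else {
                 as.character(unlist(b$levels))
               })),
               is_missing = isTRUE(b$is_missing),
               n_event = as.integer(b$n_event),
               n_nonevent = as.integer(b$n_nonevent),
               woe = as.numeric(b$woe))
  }))
  structure(
    list(variable = l$variable, type = l$type, bins = bins,
         iv = as.numeric(l$iv), smoothing = as.numeric(l$smoothing),
         n_event_total = as.integer(l$n_event_total),
         n_nonevent_total = as.integer(l$n_nonevent_total),
         fitted_on = l$fitted_on),
    class = "binning_scheme")
}

#' Serialize binning schemes to a structured text file
#'
#' JSON with full floating-point precision; [read_binning_schemes()]
#' restores the schemes bit-exactly.
#'
#' @param fit A `woe_fit` or named list of schemes.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_binning_schemes <- function(fit, path) {
  schemes <- if (inherits(fit, "woe_fit")) fit$schemes else fit
  jsonlite::write_json(lapply(schemes, scheme_to_list), path,
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Reload binning schemes written by [write_binning_schemes()]
#'
#' @param path File path.
#' @return Named list of `binning_scheme` objects.
#' @export
read_binning_schemes <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, list_to_scheme)
}
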