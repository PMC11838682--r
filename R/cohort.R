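# Cohort data model: variable dictionary, table loading/validation,
# baseline-difference features, stratified splitting, and group summaries.

VALID_KINDS <- c("continuous", "categorical", "binary")
VALID_TIMEPOINTS <- c("baseline", "acute", "asymptomatic", "rtp", "static")
TIMEPOINT_LABELS <- c(
  baseline = "Baseline", acute = "Acute",
  asymptomatic = "Asymptomatic", rtp = "RTP"
)
DEFAULT_MISSING_STRINGS <- c("", "NA", "NaN")

#' Build a variable dictionary
#'
#' A variable dictionary declares, for each predictor, its `name`, its
#' `kind` (continuous, categorical or binary) and the assessment
#' `timepoint` it belongs to (baseline, acute, asymptomatic, rtp, or
#' static for variables such as demographics that are not tied to a
#' timepoint).  `higher_is_worse` is optional documentation of the
#' clinical direction of a score and is never used computationally.
#'
#' @param name Character vector of unique variable names.
#' @param kind Character vector (recycled) of variable kinds.
#' @param timepoint Character vector (recycled) of timepoints.
#' @param higher_is_worse Optional logical vector (recycled).
#' @return A tibble with one row per variable.
#' @export
variable_specs <- function(name, kind = "continuous", timepoint = "static",
                           higher_is_worse = NA) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("variable names must be unique within a dictionary", call. = FALSE)
  }
  kind <- rep_len(as.character(kind), length(name))
  timepoint <- rep_len(as.character(timepoint), length(name))
  higher_is_worse <- rep_len(as.logical(higher_is_worse), length(name))
  if (!all(kind %in% VALID_KINDS)) {
    stop("kind must be one of: ", paste(VALID_KINDS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(timepoint %in% VALID_TIMEPOINTS)) {
    stop("timepoint must be one of: ",
         paste(VALID_TIMEPOINTS, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(name = name, kind = kind, timepoint = timepoint,
                 higher_is_worse = higher_is_worse)
}

#' Construct a cohort table
#'
#' The central container of the package: `N` subjects by `P` mixed-type
#' predictors with an explicit missing state (`NA`), a binary outcome
#' with no missing entries, a variable dictionary, and an optional
#' per-subject group label (typically Sport).
#'
#' Continuous columns are coerced to numeric; categorical and binary
#' columns to character.  A binary variable may take at most two observed
#' levels plus missing.
#'
#' @param data Data frame holding the predictor columns, the outcome
#'   column and (optionally) id/group columns.
#' @param specs Variable dictionary from [variable_specs()].
#' @param outcome Name of the 0/1 outcome column in `data`.
#' @param id Optional name of a subject-identifier column; defaults to
#'   row numbers.
#' @param group Optional name of a grouping column (may also appear in
#'   `specs` as a predictor).
#' @return An object of class `cohort_table` with elements `subjects`,
#'   `x` (tibble of predictors), `y` (integer outcome), `specs`, `group`
#'   and `group_name`.
#' @export
cohort_table <- function(data, specs, outcome = "outcome", id = NULL,
                         group = NULL) {
  data <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found in table", call. = FALSE)
  }
  y <- data[[outcome]]
  if (is.character(y)) y <- suppressWarnings(as.numeric(y))
  if (is.logical(y)) y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column '", outcome,
         "' must be binary 0/1 with no missing entries", call. = FALSE)
  }
  missing_cols <- setdiff(specs$name, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: column(s) not found in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  subjects <- if (!is.null(id)) {
    as.character(data[[id]])
  } else {
    as.character(seq_len(nrow(data)))
  }
  x <- data[specs$name]
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    col <- x[[nm]]
    if (specs$kind[i] == "continuous") {
      if (is.character(col)) {
        num <- suppressWarnings(as.numeric(col))
        bad <- !is.na(col) & is.na(num)
        if (any(bad)) {
          stop("schema error: non-numeric entries in continuous column '",
               nm, "'", call. = FALSE)
        }
        col <- num
      }
      x[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      lev <- unique(col[!is.na(col)])
      if (specs$kind[i] == "binary" && length(lev) > 2L) {
        stop("schema error: binary column '", nm, "' has ",
             length(lev), " observed levels", call. = FALSE)
      }
      x[[nm]] <- col
    }
  }
  grp <- NULL
  if (!is.null(group)) {
    if (!group %in% names(data)) {
      stop("group column '", group, "' not found in table", call. = FALSE)
    }
    grp <- as.character(data[[group]])
  }
  structure(
    list(subjects = subjects, x = tibble::as_tibble(x),
         y = as.integer(y), specs = specs, group = grp,
         group_name = group),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", length(x$subjects), " subjects x ",
      nrow(x$specs), " variables; ", sum(x$y), " events (rate ",
      sprintf("%.3f", mean(x$y)), ")\n", sep = "")
  invisible(x)
}

n_subjects <- function(cohort) length(cohort$subjects)
n_variables <- function(cohort) nrow(cohort$specs)

#' Subset a cohort by subject index
#'
#' @param cohort A `cohort_table`.
#' @param idx Integer or logical index over subjects.
#' @return A `cohort_table` restricted to the selected subjects.
#' @export
subset_cohort <- function(cohort, idx) {
  structure(
    list(subjects = cohort$subjects[idx],
         x = cohort$x[idx, , drop = FALSE],
         y = cohort$y[idx],
         specs = cohort$specs,
         group = if (!is.null(cohort$group)) cohort$group[idx] else NULL,
         group_name = cohort$group_name),
    class = "cohort_table"
  )
}

#' Drop variables from a cohort
#' @noRd
drop_variables <- function(cohort, names_to_drop) {
  keep <- !(cohort$specs$name %in% names_to_drop)
  cohort$specs <- cohort$specs[keep, , drop = FALSE]
  cohort$x <- cohort$x[cohort$specs$name]
  cohort
}

#' Load a cohort from a delimited table and a dictionary file
#'
#' The table is a delimited text file with a header row; the dictionary
#' is a YAML file declaring the outcome column and, per variable, `name`,
#' `kind` and `timepoint` (plus optional `higher_is_worse`).  Top-level
#' dictionary keys `outcome` (required), `id`, `group` and
#' `missing_strings` are recognized.  Any cell equal to one of the
#' missing sentinels (default: empty string, `"NA"`, `"NaN"`) is
#' normalized to the single missing state.
#'
#' @param table_file Path to the delimited table (comma by default; tab
#'   is used for `.tsv`/`.txt` files or when `sep = "\t"`).
#' @param dictionary_file Path to the YAML variable dictionary.
#' @param sep Field separator; `NULL` to infer from the file extension.
#' @param missing_strings Sentinel strings treated as missing; a
#'   `missing_strings` entry in the dictionary overrides this.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(table_file, dictionary_file, sep = NULL,
                        missing_strings = DEFAULT_MISSING_STRINGS) {
  dict <- yaml::read_yaml(dictionary_file)
  if (is.null(dict$outcome)) {
    stop("dictionary must declare an 'outcome' column", call. = FALSE)
  }
  if (!is.null(dict$missing_strings)) {
    missing_strings <- as.character(dict$missing_strings)
  }
  vars <- dict$variables
  if (is.null(vars) || length(vars) == 0L) {
    stop("dictionary declares no variables", call. = FALSE)
  }
  specs <- variable_specs(
    name = vapply(vars, function(v) v$name, character(1)),
    kind = vapply(vars, function(v) v$kind %||% "continuous", character(1)),
    timepoint = vapply(vars, function(v) v$timepoint %||% "static",
                       character(1)),
    higher_is_worse = vapply(vars, function(v) {
      if (is.null(v$higher_is_worse)) NA else isTRUE(v$higher_is_worse)
    }, logical(1))
  )
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", table_file, ignore.case = TRUE)) {
      "\t"
    } else {
      ","
    }
  }
  raw <- utils::read.table(table_file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  for (nm in names(raw)) {
    raw[[nm]][raw[[nm]] %in% missing_strings] <- NA_character_
  }
  cohort <- cohort_table(raw, specs, outcome = dict$outcome,
                         id = dict$id, group = dict$group)
  message("loaded cohort: ", n_subjects(cohort), " rows, ",
          n_variables(cohort), " declared variables")
  cohort
}

#' Write a cohort as delimited text plus a dictionary file
#'
#' Inverse of [load_cohort()]: emits `<prefix>_table.csv` and
#' `<prefix>_dictionary.yaml`, and, when ground truth from the synthetic
#' generator is supplied, a `<prefix>_truth.json` sidecar.
#'
#' @param cohort A `cohort_table`.
#' @param prefix Path prefix for the output files.
#' @param truth Optional ground-truth list from [generate_cohort()].
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix, truth = NULL) {
  tab <- data.frame(subject_id = cohort$subjects, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(cohort$x, check.names = FALSE))
  tab$outcome <- cohort$y
  if (!is.null(cohort$group) &&
      !(cohort$group_name %in% cohort$specs$name)) {
    tab[[cohort$group_name]] <- cohort$group
  }
  table_path <- paste0(prefix, "_table.csv")
  dict_path <- paste0(prefix, "_dictionary.yaml")
  utils::write.csv(tab, table_path, row.names = FALSE, na = "")
  dict <- list(
    outcome = "outcome", id = "subject_id",
    variables = lapply(seq_len(nrow(cohort$specs)), function(i) {
      list(name = cohort$specs$name[i], kind = cohort$specs$kind[i],
           timepoint = cohort$specs$timepoint[i])
    })
  )
  if (!is.null(cohort$group_name)) dict$group <- cohort$group_name
  yaml::write_yaml(dict, dict_path)
  paths <- c(table = table_path, dictionary = dict_path)
  if (!is.null(truth)) {
    truth_path <- paste0(prefix, "_truth.json")
    jsonlite::write_json(
      list(informative_set = truth$informative_set,
           latent_score = truth$latent_score,
           bayes_auc = truth$bayes_auc),
      truth_path, auto_unbox = TRUE, digits = I(17))
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Append baseline-minus-timepoint difference features
#'
#' For every continuous measure assessed at baseline and again at a later
#' timepoint, appends the change score `baseline value - later value` as
#' a new continuous variable named
#' `"<Measure> Difference Baseline <Timepoint>"`.  The difference is
#' missing whenever either operand is missing.  Measures without a
#' baseline counterpart (e.g. instruments administered only once) are
#' skipped with a log message; original columns are always retained.
#'
#' Matching relies on the dictionary naming convention
#' `"<Measure> <TimepointLabel>"` with labels Baseline, Acute,
#' Asymptomatic and RTP.
#'
#' @param cohort A `cohort_table`.
#' @return The cohort with difference variables appended.
#' @export
build_difference_features <- function(cohort) {
  specs <- cohort$specs
  strip_label <- function(nm, tp) {
    sub(paste0(" ", TIMEPOINT_LABELS[[tp]], "$"), "", nm)
  }
  base_idx <- which(specs$kind == "continuous" &
                      specs$timepoint == "baseline")
  base_measures <- stats::setNames(
    specs$name[base_idx],
    vapply(specs$name[base_idx], strip_label, character(1), tp = "baseline")
  )
  later_idx <- which(specs$kind == "continuous" &
                       specs$timepoint %in% c("acute", "asymptomatic", "rtp"))
  new_cols <- list()
  new_specs <- list()
  for (i in later_idx) {
    nm <- specs$name[i]
    tp <- specs$timepoint[i]
    measure <- strip_label(nm, tp)
    if (!measure %in% names(base_measures)) {
      message("no baseline counterpart for '", nm, "'; skipped")
      next
    }
    diff_name <- paste(measure, "Difference Baseline", TIMEPOINT_LABELS[[tp]])
    if (diff_name %in% specs$name) next
    new_cols[[diff_name]] <-
      cohort$x[[base_measures[[measure]]]] - cohort$x[[nm]]
    new_specs[[diff_name]] <- tibble::tibble(
      name = diff_name, kind = "continuous", timepoint = tp,
      higher_is_worse = NA)
  }
  if (length(new_cols) > 0L) {
    cohort$x <- tibble::as_tibble(
      cbind(cohort$x, tibble::as_tibble(new_cols), stringsAsFactors = FALSE))
    cohort$specs <- rbind(specs, do.call(rbind, unname(new_specs)))
  }
  cohort
}

#' Stratified train/test split with a category-coverage rejection rule
#'
#' Each outcome class `c` with `n_c` members contributes
#' `round(n_c * test_fraction)` subjects (round half up) to the test set,
#' drawn uniformly at random under `seed`, so the injury rate is matched
#' between sets.  A draw in which any level of any categorical or binary
#' variable occurs only in the test set is rejected and redrawn, up to
#' `max_retries` times; splitting 194 subjects with 120 events at
#' fraction 0.2 yields the 96/59 train and 24/15 test class composition.
#'
#' @param cohort A `cohort_table` with both classes present.
#' @param test_fraction Proportion in (0, 1) assigned to the test set.
#' @param seed Integer seed; the same seed always reproduces the same
#'   membership lists.
#' @param max_retries Redraw bound for the rejection rule.
#' @return A list of class `split_result` with `train`, `test`, `seed`
#'   and `rejected_attempts`.
#' @export
stratified_split <- function(cohort, test_fraction, seed,
                             max_retries = 1000L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- assert_both_classes(cohort$y)
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  if (length(idx1) < 2L || length(idx0) < 2L) {
    stop("each outcome class needs at least 2 members to split",
         call. = FALSE)
  }
  n_test1 <- round_half_up(length(idx1) * test_fraction)
  n_test0 <- round_half_up(length(idx0) * test_fraction)
  cat_vars <- cohort$specs$name[cohort$specs$kind %in%
                                  c("categorical", "binary")]
  local_seed(seed, {
    rejected <- 0L
    offender <- NULL
    repeat {
      test_idx <- sort(c(sample(idx1, n_test1), sample(idx0, n_test0)))
      train_idx <- setdiff(seq_along(y), test_idx)
      offender <- NULL
      for (v in cat_vars) {
        col <- cohort$x[[v]]
        test_lev <- unique(col[test_idx])
        test_lev <- test_lev[!is.na(test_lev)]
        orphan <- setdiff(test_lev, col[train_idx])
        if (length(orphan) > 0L) {
          offender <- c(v, orphan[1L])
          break
        }
      }
      if (is.null(offender)) break
      rejected <- rejected + 1L
      message("split rejected (attempt ", rejected, "): level '",
              offender[2L], "' of '", offender[1L],
              "' only present in test set")
      if (rejected > max_retries) {
        stop("stratified_split: retry bound exhausted; level '",
             offender[2L], "' of variable '", offender[1L],
             "' cannot be covered by the training set", call. = FALSE)
      }
    }
    structure(
      list(train = subset_cohort(cohort, train_idx),
           test = subset_cohort(cohort, test_idx),
           seed = seed, rejected_attempts = rejected),
      class = "split_result"
    )
  })
}

#' Summarize a cohort by group
#'
#' Per group: non-event count, event count, and event rate
#' `events / (events + non-events)` rounded to three decimals, plus
#' mean and standard deviation of any requested continuous variables.
#' This reproduces the layout of a cohort-composition table (counts and
#' event rates by sport and sex).
#'
#' @param cohort A `cohort_table`.
#' @param group_by Character vector of grouping column names (predictor
#'   columns or the cohort's group label).
#' @param summarize_vars Optional names of continuous variables to
#'   report as `<var>_mean` / `<var>_sd` columns.
#' @param digits Decimal places for the event rate.
#' @return A tibble, one row per observed group.
#' @export
cohort_summary <- function(cohort, group_by, summarize_vars = NULL,
                           digits = 3L) {
  get_col <- function(nm) {
    if (nm %in% names(cohort$x)) {
      return(as.character(cohort$x[[nm]]))
    }
    if (!is.null(cohort$group_name) && nm == cohort$group_name) {
      return(cohort$group)
    }
    stop("grouping column '", nm, "' not found", call. = FALSE)
  }
  gcols <- lapply(group_by, get_col)
  names(gcols) <- group_by
  key <- do.call(paste, c(gcols, sep = "\r"))
  groups <- split(seq_along(key), key)
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 0L) return(NULL)
    yv <- cohort$y[idx]
    out <- as.list(vapply(gcols, function(g) g[idx[1L]], character(1)))
    out$n_non_event <- sum(yv == 0L)
    out$n_event <- sum(yv == 1L)
    out$event_rate <- round(out$n_event / length(yv), digits)
    for (v in summarize_vars) {
      vals <- cohort$x[[v]][idx]
      out[[paste0(v, "_mean")]] <- mean(vals, na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- stats::sd(vals, na.rm = TRUE)
    }
    tibble::as_tibble(out)
  })
  res <- do.call(rbind, rows)
  res[do.call(order, as.list(res[group_by])), , drop = FALSE]
}

#' Injury counts by sport and sex for a collegiate concussion cohort
#'
#' Published cohort-composition counts (non-event and event totals by
#' sport and sex, 194 subjects, 120 events overall) used as the default
#' sport event-rate profile of the synthetic generator and as a worked
#' example for [cohort_summary()].
#'
#' @return A tibble with columns `sport`, `sex`, `non_event`, `event`.
#' @export
study_injury_counts <- function() {
  tibble::tribble(
    ~sport, ~sex, ~non_event, ~event,
    "Baseball/Softball", "female", 4L, 8L,
    "Baseball/Softball", "male", 4L, 3L,
    "Basketball", "female", 3L, 7L,
    "Basketball", "male", 1L, 6L,
    "Cheer", "female", 3L, 3L,
    "Cheer", "male", 1L, 1L,
    "Field Hockey", "female", 1L, 8L,
    "Football", "male", 10L, 18L,
    "Lacrosse", "female", 7L, 12L,
    "Lacrosse", "male", 7L, 8L,
    "Rowing", "female", 6L, 5L,
    "Soccer", "female", 6L, 10L,
    "Soccer", "male", 3L, 6L,
    "Swimming and Diving", "female", 7L, 3L,
    "Swimming and Diving", "male", 2L, 0L,
    "Tennis", "female", 1L, 0L,
    "Tennis", "male", 1L, 2L,
    "Track and Field", "female", 2L, 9L,
    "Volleyball", "female", 5L, 11L
  )
}

#' Expand grouped injury counts into a subject-level cohort
#'
#' Turns a counts table such as [study_injury_counts()] into a
#' `cohort_table` with one row per subject and categorical Sport/Sex
#' predictors, so that [cohort_summary()] and [stratified_split()] can
#' operate on it.
#'
#' @param counts Tibble with `sport`, `sex`, `non_event`, `event`.
#' @return A `cohort_table`.
#' @export
counts_to_cohort <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n0 <- counts$non_event[i]
    n1 <- counts$event[i]
    data.frame(Sport = counts$sport[i], Sex = counts$sex[i],
               outcome = rep(c(0L, 1L), c(n0, n1)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  specs <- variable_specs(name = c("Sport", "Sex"),
                          kind = c("categorical", "binary"))
  cohort_table(tab, specs, outcome = "outcome", group = "Sport")
}
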