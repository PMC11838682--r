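# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (explicit loops, enumeration) so
# they stay independent of the package's implementations.

# Pairwise-concordance AUC by explicit enumeration of all event/
# non-event pairs, ties counted 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Smoothed WoE of one bin by direct plug-in.
brute_woe <- function(e, ne, E, NE, s, B) {
  log(((e + s) / (E + s * B)) / ((ne + s) / (NE + s * B)))
}

# Total smoothed IV of a partition of cells (counts e, ne; partition
# given as a list of index vectors), plus an optional missing bin.
brute_iv <- function(e, ne, E, NE, s, parts, miss = NULL) {
  B <- length(parts) + !is.null(miss)
  tot <- 0
  for (idx in parts) {
    pe <- (sum(e[idx]) + s) / (E + s * B)
    pn <- (sum(ne[idx]) + s) / (NE + s * B)
    tot <- tot + (pe - pn) * log(pe / pn)
  }
  if (!is.null(miss)) {
    pe <- (miss[1] + s) / (E + s * B)
    pn <- (miss[2] + s) / (NE + s * B)
    tot <- tot + (pe - pn) * log(pe / pn)
  }
  tot
}

# All contiguous partitions of m cells (list of lists of index vectors).
all_contiguous_partitions <- function(m) {
  out <- list()
  for (k in 0:(m - 1)) {
    combos <- if (k == 0) list(integer(0)) else
      utils::combn(m - 1, k, simplify = FALSE)
    for (cuts in combos) {
      bounds <- c(cuts, m)
      starts <- c(1, utils::head(bounds, -1) + 1)
      out[[length(out) + 1L]] <-
        lapply(seq_along(bounds), function(i) starts[i]:bounds[i])
    }
  }
  out
}

# Small mixed-type cohort with a known structure, built in code.
make_tiny_cohort <- function(n = 60, seed = 42, missing = TRUE) {
  set.seed(seed)
  x1 <- rnorm(n, 10, 3)
  x2 <- sample(c("A", "B", "C"), n, replace = TRUE)
  eta <- -0.5 + 0.8 * (x1 > 10) + 0.6 * (x2 == "C")
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  if (missing) {
    x1[sample(n, round(0.2 * n))] <- NA
    x2[sample(n, round(0.2 * n))] <- NA
  }
  df <- data.frame(score = x1, grade = x2, outcome = y,
                   stringsAsFactors = FALSE)
  cohort_table(df, variable_specs(c("score", "grade"),
                                  kind = c("continuous", "categorical")))
}

# Cohort matching the published composition: 194 subjects, 120 events,
# Sport/Sex categoricals.
make_table1_cohort <- function() {
  counts_to_cohort(study_injury_counts())
}
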