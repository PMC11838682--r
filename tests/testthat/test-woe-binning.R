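# Weight-of-Evidence values, Information Value, optimal binning and the
# WoE transform.

test_that("woe_value matches direct log-ratios and guards zero counts", {
  # equal class proportions: zero evidence
  expect_equal(woe_value(20, 20, 100, 100, smoothing = 0, n_bins = 2), 0)
  # 30/100 events vs 10/100 non-events, no smoothing: ln 3
  expect_equal(woe_value(30, 10, 100, 100, smoothing = 0, n_bins = 2),
               log(3), tolerance = 1e-12)
  # zero-count bin with pseudo-counts stays finite and positive
  v <- woe_value(5, 0, 50, 50, smoothing = 0.5, n_bins = 2)
  expect_equal(v, brute_woe(5, 0, 50, 50, 0.5, 2), tolerance = 1e-12)
  expect_true(is.finite(v) && v > 0)
  # zero count without smoothing is an error
  expect_error(woe_value(5, 0, 50, 50, smoothing = 0, n_bins = 2),
               "smoothing")
})

test_that("information_value matches hand evaluation and degenerate cases", {
  mk_scheme <- function(e, ne, s) {
    bins <- do.call(rbind, lapply(seq_along(e), function(i) {
      data.frame(lo = NA, hi = NA, levels = I(list(NULL)),
                 is_missing = FALSE, n_event = e[i], n_nonevent = ne[i],
                 woe = NA)
    }))
    structure(list(variable = "v", type = "continuous", bins = bins,
                   smoothing = s, n_event_total = sum(e),
                   n_nonevent_total = sum(ne)),
              class = "binning_scheme")
  }
  # event proportions (0.3, 0.7) vs non-event (0.1, 0.9), no smoothing:
  # 0.2 ln 3 + (-0.2) ln(7/9)
  expect_equal(information_value(mk_scheme(c(30, 70), c(10, 90), 0)),
               0.2 * log(3) - 0.2 * log(7 / 9), tolerance = 1e-12)
  # single bin: identical distributions, IV 0
  expect_equal(information_value(mk_scheme(100, 100, 0)), 0)
  # merging two bins with equal woe leaves IV unchanged (no smoothing)
  split_iv <- information_value(mk_scheme(c(30, 30, 40), c(10, 10, 80), 0))
  merged_iv <- information_value(mk_scheme(c(60, 40), c(20, 80), 0))
  expect_equal(split_iv, merged_iv, tolerance = 1e-12)
})

test_that("fitted bins reproduce brute-force smoothed log-ratios by direct counting", {
  co <- make_tiny_cohort(n = 300, seed = 8)
  for (nm in c("score", "grade")) {
    sc <- fit_binning(co$x[[nm]], co$y, variable = nm)
    E <- sum(co$y == 1L)
    NE <- sum(co$y == 0L)
    B <- nrow(sc$bins)
    vals <- co$x[[nm]]
    for (i in seq_len(B)) {
      b <- sc$bins[i, ]
      in_bin <- if (b$is_missing) {
        is.na(vals)
      } else if (sc$type == "continuous") {
        !is.na(vals) & vals >= b$lo & vals < b$hi
      } else {
        !is.na(vals) & vals %in% b$levels[[1]]
      }
      e <- sum(co$y[in_bin] == 1L)
      ne <- sum(co$y[in_bin] == 0L)
      expect_identical(c(b$n_event, b$n_nonevent), c(e, ne))
      expect_equal(b$woe, brute_woe(e, ne, E, NE, sc$smoothing, B),
                   tolerance = 1e-12)
    }
    expect_gte(sc$iv, 0)
  }
})

test_that("the DP attains the exhaustive maximum IV over contiguous partitions", {
  # six equally frequent distinct values with assorted class balance
  set.seed(5)
  reps <- 30
  vals <- rep(1:6, each = reps)
  probs <- c(0.2, 0.7, 0.3, 0.6, 0.25, 0.65)
  y <- rbinom(length(vals), 1, probs[vals])
  params <- binning_params(min_bin_fraction = 0, max_bins = 6,
                           complexity_penalty = 0)
  sc <- fit_binning(vals, y, params)
  e <- vapply(1:6, function(v) sum(y[vals == v] == 1L), integer(1))
  ne <- vapply(1:6, function(v) sum(y[vals == v] == 0L), integer(1))
  best <- max(vapply(all_contiguous_partitions(6), function(parts) {
    brute_iv(e, ne, sum(e), sum(ne), 0.5, parts)
  }, numeric(1)))
  expect_equal(sc$iv, best, tolerance = 1e-12)
  # and the DP beats every greedy contiguous merge by construction;
  # spot-check IV monotonicity under merging (no smoothing, positive counts)
  for (parts in all_contiguous_partitions(4)) {
    if (length(parts) < 2) next
    iv_fine <- brute_iv(e[1:4], ne[1:4], sum(e[1:4]), sum(ne[1:4]), 0, parts)
    for (j in seq_len(length(parts) - 1)) {
      merged <- parts
      merged[[j]] <- c(merged[[j]], merged[[j + 1]])
      merged[[j + 1]] <- NULL
      iv_coarse <- brute_iv(e[1:4], ne[1:4], sum(e[1:4]), sum(ne[1:4]), 0,
                            merged)
      expect_lte(iv_coarse, iv_fine + 1e-12)
    }
  }
})

test_that("true threshold edges are recovered within one pre-bin cell", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n, 10, 3)
  eta <- -1 + 1.0 * (x >= 9) + 1.0 * (x >= 12)
  y <- rbinom(n, 1, plogis(eta))
  sc <- fit_binning(x, y)
  edges <- sc$bins$hi[!sc$bins$is_missing]
  edges <- edges[is.finite(edges)]
  q <- quantile(x, probs = (1:19) / 20, type = 7, names = FALSE)
  cell_width_at <- function(t) {
    i <- findInterval(t, q)
    lo <- if (i >= 1) q[i] else min(x)
    hi <- if (i < length(q)) q[i + 1] else max(x)
    hi - lo
  }
  for (target in c(9, 12)) {
    expect_lt(min(abs(edges - target)), 2 * cell_width_at(target),
              label = sprintf("edge near %g", target))
  }
})

test_that("an outcome-independent variable collapses to few bins with tiny IV", {
  set.seed(3)
  n <- 1000
  x <- rnorm(n, 10, 3)
  y <- rbinom(n, 1, 0.6)
  ivs <- numeric(50)
  nb <- integer(50)
  for (i in 1:50) {
    sc <- fit_binning(x, sample(y), variable = "null")
    ivs[i] <- sc$iv
    nb[i] <- nrow(sc$bins)
  }
  expect_lt(median(ivs), 0.01)
  expect_lte(median(nb), 2)
})

test_that("degenerate columns fit gracefully", {
  y <- rep(c(0L, 1L), 20)
  # all values missing: the scheme is the missing bin alone
  sc <- fit_binning(rep(NA_real_, 40), y)
  expect_identical(nrow(sc$bins), 1L)
  expect_true(sc$bins$is_missing)
  # constant non-missing values: one bin plus the missing bin
  v <- c(rep(5, 30), rep(NA, 10))
  sc2 <- fit_binning(v, y)
  expect_identical(nrow(sc2$bins), 2L)
  expect_identical(sum(sc2$bins$is_missing), 1L)
})

test_that("woe_transform maps values, missing and unseen levels per contract", {
  co <- make_tiny_cohort(n = 200, seed = 15)
  sc <- fit_binning(co$x$score, co$y, variable = "score")
  z <- woe_transform(sc, co$x$score)
  expect_false(anyNA(z))
  # training column takes at most B distinct values, one per bin
  expect_lte(length(unique(z)), nrow(sc$bins))
  # a value inside a bin gets that bin's woe (probe just under each
  # finite upper edge, which lies in [lo, hi))
  reg <- sc$bins[!sc$bins$is_missing, ]
  for (i in which(is.finite(reg$hi))) {
    expect_equal(woe_transform(sc, reg$hi[i] - 1e-9), reg$woe[i])
  }
  # missing maps to the missing bin's woe
  expect_equal(woe_transform(sc, NA_real_),
               sc$bins$woe[sc$bins$is_missing])
  # categorical: unseen level is neutral evidence
  scg <- fit_binning(co$x$grade, co$y, variable = "grade")
  expect_identical(woe_transform(scg, "ZZZ"), 0)
})

test_that("fit_all_binnings conserves variables and orders the IV manifest", {
  g <- generate_cohort(generator_spec(n_subjects = 400, n_noise = 8,
                                      n_categorical = 2, seed = 44))
  fit <- fit_all_binnings(g$cohort)
  expect_setequal(names(fit$schemes), g$cohort$specs$name)
  expect_identical(nrow(fit$manifest), nrow(g$cohort$specs))
  # manifest IVs equal independent information_value calls, descending
  recomputed <- vapply(fit$manifest$variable, function(nm) {
    information_value(fit$schemes[[nm]])
  }, numeric(1))
  expect_equal(fit$manifest$iv, unname(recomputed), tolerance = 1e-12)
  expect_true(all(diff(fit$manifest$iv) <= 1e-12))
  # encoding the fit produces a complete numeric matrix
  X <- woe_encode(fit, g$cohort)
  expect_false(anyNA(X))
  expect_identical(dim(X), c(400L, nrow(g$cohort$specs)))
})

test_that("scheme serialization round trip is bit-exact", {
  co <- make_tiny_cohort(n = 150, seed = 23)
  fit <- fit_all_binnings(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_binning_schemes(fit, path)
  back <- read_binning_schemes(path)
  expect_identical(names(back), names(fit$schemes))
  for (nm in names(back)) {
    expect_identical(back[[nm]]$bins$woe, fit$schemes[[nm]]$bins$woe)
    expect_identical(back[[nm]]$iv, fit$schemes[[nm]]$iv)
    expect_identical(
      woe_transform(back[[nm]], co$x[[nm]]),
      woe_transform(fit$schemes[[nm]], co$x[[nm]]))
  }
})

test_that("test-set transformation never reads test labels", {
  g <- generate_cohort(generator_spec(n_subjects = 300, n_noise = 6,
                                      n_categorical = 1, seed = 61))
  sp <- suppressMessages(stratified_split(g$cohort, 0.3, seed = 1))
  fit <- fit_all_binnings(sp$train)
  X1 <- woe_encode(fit, sp$test)
  flipped <- sp$test
  flipped$y <- 1L - flipped$y
  X2 <- woe_encode(fit, flipped)
  expect_identical(X1, X2)
})
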