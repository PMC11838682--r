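# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; stratified test-set sizes use
#' conventional round-half-up so that 74 * 0.2 = 14.8 -> 15.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' operations do not perturb the user's random stream.
#' @noRd
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

assert_binary_outcome <- function(y) {
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) {
    stop("outcome must be coded 0/1", call. = FALSE)
  }
  invisible(as.integer(y))
}

assert_both_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  invisible(y)
}
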