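#' @keywords internal
"_PACKAGE"

# Internal error helpers. Validation failures signal a condition of class
# "semg_validation_error" so callers (and tests) can distinguish bad input
# from genuine runtime faults.

abort_validation <- function(msg, class = "semg_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_that <- function(cond, msg, class = "semg_validation_error") {
  if (!isTRUE(cond)) abort_validation(msg, class)
  invisible(TRUE)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    abort_validation(sprintf("%s contains non-finite values", what))
  }
  invisible(TRUE)
}

#' Derive a reproducible integer sub-seed from a master seed and a string key
#'
#' Cohort simulation gives every subject an independent random substream so
#' that a cohort is reproducible even if subjects are generated in a
#' different order. The substream seed is a stable (platform-independent)
#' hash of the subject identifier folded into the master seed.
#'
#' @param seed master seed (integer).
#' @param key  character key, e.g. a subject id.
#' @return an integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer((h + as.numeric(seed) %% 2147483647 * 2654435) %% 2147483647)
}

# Ordered fatigue class labels used throughout the package.
fatigue_classes <- function(task = c("threeclass", "binary")) {
  task <- match.arg(task)
  if (task == "binary") c("NoFatigue", "Fatigue")
  else c("NoFatigue", "ModerateFatigue", "HardFatigue")
}
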