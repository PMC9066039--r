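#' @keywords internal
"_PACKAGE"

# Canonical ordering of the five lactation stages (days relative to
# parturition; negative = before, positive = after).
STAGE_LEVELS <- c("-14", "-10", "-6", "-2", "+1")

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the previous RNG
#' state so that library internals never perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from a global seed. Kept below 2^31 so it is
# always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 97 * index) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce stage labels to the canonical ordered factor, validating values.
# Numeric input (e.g. a design table read back from TSV, where "+1" parses
# as 1) is mapped to the signed canonical labels.
as_stage <- function(x) {
  if (is.numeric(x)) {
    x <- ifelse(x > 0, paste0("+", format(x, trim = TRUE, scientific = FALSE)),
                format(x, trim = TRUE, scientific = FALSE))
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), STAGE_LEVELS)
  if (length(bad) > 0) {
    stopf("unknown stage label(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(STAGE_LEVELS, collapse = ", "))
  }
  factor(x, levels = STAGE_LEVELS, ordered = TRUE)
}
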