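# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Headline persistence figures are reported as truncated (floored) integer
# percentages; the small epsilon guards values that are integers up to
# floating-point representation.
#' Truncate a probability to an integer percentage
#'
#' Converts a probability (or vector of probabilities) to the integer
#' percentage obtained by truncation (floor), the convention used for the
#' model's headline persistence figures.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Integer vector of truncated percentages.
#' @examples
#' truncate_pct(0.595)  # 59
#' @export
truncate_pct <- function(p) {
  stopifnot(is.numeric(p))
  as.integer(floor(100 * p + 1e-9))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop(sprintf("`%s` must be a single number >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
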