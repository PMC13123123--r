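#' @keywords internal
"_PACKAGE"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so simulation functions are pure functions of their
#' seed and never disturb the caller's random stream.
#'
#' @param seed single non-negative integer-valued seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Stable string hashing (31-multiplier fold modulo 2^31 - 1) so that the
#' per-participant / per-trial streams of a cohort can be regenerated
#' individually without replaying the whole cohort.
#'
#' @param master master seed (non-negative integer).
#' @param ... character or numeric labels identifying the child stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, "P01", "MAS", "small_rom")
child_seed <- function(master, ...) {
  mod <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% mod
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0(as.character(lab), "|"))) {
      h <- (h * 31 + code) %% mod
    }
  }
  as.integer(h)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
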