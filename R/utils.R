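# Internal helpers shared across the package.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Package-level progress/diagnostic logging
#'
#' Controlled by `options(bloomtrack.verbose = TRUE)`; silent by default so
#' programmatic use stays quiet.
#' @noRd
bt_log <- function(...) {
  if (isTRUE(getOption("bloomtrack.verbose", FALSE))) {
    message("[bloomtrack] ", ...)
  }
  invisible(NULL)
}

#' Stop with a consistent error prefix
#' @noRd
bt_stop <- function(...) stop(..., call. = FALSE)

#' Average ranks (midranks) of a numeric vector, ties averaged
#' @noRd
midrank <- function(x) rank(x, ties.method = "average")

#' Check a numeric scalar
#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
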