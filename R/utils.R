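#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
cf_stop <- function(msg, class = "citfoot_error", ...) {
  stop(structure(
    class = c(class, "citfoot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    cf_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")),
            class = "citfoot_validation_error")
  }
  invisible(df)
}

#' Seed-scoped RNG: run `expr` under `seed` without clobbering the caller's
#' RNG stream (generators must be reproducible and side-effect free).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cf_stop("seed must be a single integer", class = "citfoot_validation_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
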