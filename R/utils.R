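# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's
#' `.Random.seed` afterwards so generators are pure functions of their seed.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629) + 1L
}

stop_cf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_cf(fmt, ...)
  invisible(TRUE)
}

# Cheap content hash used for the distance-matrix cache: not cryptographic,
# just sensitive enough that editing a mesh invalidates cached geodesics.
content_key <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (is.numeric(x)) sprintf("%.6g", c(length(x), sum(x * seq_along(x)), sum(x)))
    else as.character(x)
  })
  paste(unlist(parts), collapse = "|")
}
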