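# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a locally seeded RNG
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so no global state leaks between operations. A `NULL`
#' seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# stop() without the call, with sprintf-style formatting
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# checks that x is a single non-missing value of the given predicate
assert_scalar <- function(x, pred, what) {
  if (length(x) != 1L || is.na(x) || !pred(x))
    stop2("'%s' must be a single %s value", deparse(substitute(x)), what)
  invisible(x)
}

# row-wise variance of a numeric matrix (unbiased)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
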