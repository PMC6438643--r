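#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions
#' do not disturb the global random stream. A `NULL` seed evaluates the
#' expression against the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a master seed and a label path
#'
#' Deterministic 31-bit hash so every stochastic stage of a pipeline gets
#' its own reproducible stream. Returns `NULL` for a `NULL` master seed.
#' @noRd
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
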