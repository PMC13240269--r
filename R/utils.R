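## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), inherits = FALSE))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Deterministically derive a child seed from a pipeline seed and a stage tag.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(tag)
  s <- 0
  for (v in raw) s <- (s * 31 + v) %% 2147483629
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
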