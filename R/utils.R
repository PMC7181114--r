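# Internal helpers shared across the package.

#' Derive a reproducible integer seed from mixed components
#'
#' Folds integers and strings into a single seed in `[0, 2^31 - 2]` with a
#' multiplicative-congruential mix. Used to give every (stage, subject, window,
#' slice) its own deterministic random stream derived from one global seed, so
#' results do not depend on evaluation order.
#'
#' @param ... integers and/or character scalars/vectors to fold in.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- 0
  for (p in parts) {
    if (is.character(p)) {
      cp <- utf8ToInt(p)
      # positional weighting so "ab" and "ba" differ
      p <- sum(cp * seq_along(cp)) %% 2147483647
    }
    # 69069: classic MCG multiplier; products stay < 2^53 so doubles are exact
    h <- (h * 69069 + as.numeric(p) %% 2147483647) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
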