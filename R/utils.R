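# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic integer seed derived from a master seed and a stage
#' label, so individual pipeline stages and simulation replicates are
#' independently reproducible from one configured seed.  Polynomial
#' string hash mod (2^31 - 1); all intermediate values stay below 2^53 so
#' double arithmetic is exact.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return An integer seed in [1, 2^31 - 1).
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 2654435 + h + 1) %% 2147483647)
}

# Probabilities are kept away from 0/1 before taking logs; Bernoulli
# likelihood contributions then never reach -Inf.
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

stop_if_not_aligned <- function(n_a, n_b, what_a, what_b) {
  if (n_a != n_b) {
    stop(sprintf("%s has length %d but %s has length %d; inputs must be aligned to the same grid",
                 what_a, n_a, what_b, n_b), call. = FALSE)
  }
  invisible(TRUE)
}
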