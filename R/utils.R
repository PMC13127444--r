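#' Derive a reproducible sub-seed from a master seed
#'
#' All randomized operations take an explicit seed. Composite operations
#' (the study simulator, Monte-Carlo mining, the pipeline) derive one
#' sub-seed per internal step with a counter scheme, so each step is
#' independently reproducible: `sub = (master * 7919 + k) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param k non-negative integer counter.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483647 # 2^31 - 1
  as.integer(((abs(master) %% m) * 7919 + k) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_structural <- function(...) {
  stop(structure(class = c("redoxtaxa_structural_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
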