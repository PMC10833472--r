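#' Derive a per-stage random seed from a global seed
#'
#' Stages draw from independent substreams so that adding or re-ordering a
#' stage never perturbs another stage's random numbers. The substream seed is
#' a deterministic 31-bit hash of the global seed and the stage name.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. "noise", "simulate").
#' @return An integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Benjamini-Hochberg step-up adjustment lives in deg.R (bh_adjust) but is
# used package-wide.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
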