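#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' Stage-level substreams make each pipeline stage reproducible independently
#' of the order in which stages run.  The derivation is a small deterministic
#' integer hash of the tag folded into the master seed, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param tag character scalar naming the consumer (e.g. "rarefy", "bnti").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# shared assertion helper: stop with the caller-supplied message
.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
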