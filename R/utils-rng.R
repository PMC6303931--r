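#' Derive a reproducible substream seed
#'
#' Maps a base seed plus an arbitrary key (individual id, session label,
#' channel name, ...) to an integer seed. Draws for one individual/session are
#' taken from the substream keyed by that individual and session, so adding or
#' removing fish from a cohort never perturbs the draws of the others.
#'
#' @param seed Integer base seed of the cohort.
#' @param ... Further key components (coerced to character).
#' @return A single integer in `[0, 2^31 - 20)`.
#' @examples
#' substream_seed(1, "g01_f03", "latency", "group")
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 5381
  for (cp in utf8ToInt(key)) h <- (h * 33 + cp) %% 2147483629
  as.integer(h)
}

# run expr under a substream seed, restoring the caller's RNG state
with_substream <- function(seed, ..., expr) {
  withr::with_seed(substream_seed(seed, ...), expr)
}
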