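#' Derive a reproducible sub-stream seed from a root seed
#'
#' Deterministically maps a root seed and a stream label to an integer seed
#' below 2^31, so that the track, brightness, isotherm and reaction
#' generators each consume an independent, reproducible RNG stream.
#'
#' @param seed integer root seed.
#' @param stream character label of the stream (e.g. `"tracks"`).
#' @param index optional integer (e.g. a replicate or corral index) folded
#'   into the derivation.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime as in the Lehmer LCG
  h <- (as.numeric(seed) %% m)
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 48271 + as.numeric(index) * 16807) %% m
  as.integer(h)
}

# internal: check a single positive finite scalar
.check_pos <- function(x, name, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 &&
    (allow_inf || is.finite(x))
  if (!ok) stop(sprintf("`%s` must be a positive %sscalar", name,
                        if (allow_inf) "" else "finite "), call. = FALSE)
  invisible(x)
}

# internal: canonical track table column order
.track_cols <- c("track_id", "frame", "t", "x", "y", "intensity")

# internal: empty track table
.empty_tracks <- function() {
  data.frame(track_id = integer(), frame = integer(), t = numeric(),
             x = numeric(), y = numeric(), intensity = numeric())
}
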