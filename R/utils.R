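# Internal error helpers: every user-facing failure carries a subclass so
# callers (and the test-suite) can distinguish validation problems from
# genuinely insufficient data.

stop_validation <- function(msg, ...) {
  abort(msg, class = "gaitlf_error_validation", ...)
}

stop_insufficient <- function(msg, ...) {
  abort(msg, class = "gaitlf_error_insufficient_data", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "gaitlf_error_format", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "gaitlf_error_degenerate", ...)
}

stop_conditioning <- function(msg, ...) {
  abort(msg, class = "gaitlf_error_conditioning", ...)
}

# Segment id of sample indices given segment end indices (junctions between
# stitched trials). `boundaries` holds the last sample index of every segment
# except the final one.
segment_of <- function(idx, boundaries) {
  if (length(boundaries) == 0L) {
    return(rep(1L, length(idx)))
  }
  findInterval(idx, boundaries + 0.5) + 1L
}

# Evenly spaced deterministic subsample of an index vector.
subsample_idx <- function(idx, max_n) {
  if (length(idx) <= max_n) {
    return(idx)
  }
  idx[unique(round(seq(1L, length(idx), length.out = max_n)))]
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
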