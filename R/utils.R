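`%||%` <- function(a, b) if (is.null(a)) b else a

.fmtOrNA <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)

## Linear interpolation with nearest-sample extrapolation beyond the span.
.interpNearest <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2, ties = "ordered")$y
}

## Derive a bounded child seed from a parent seed and an index; keeps every
## seed handed to set.seed() inside the 32-bit integer range.
.childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% .Machine$integer.max)
}

## Row mask of time points falling inside any (start, end] exclusion interval.
.inExclusion <- function(times, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L)
    return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(exclusions)))
    out <- out | (times >= exclusions[i, 1L] & times <= exclusions[i, 2L])
  out
}
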