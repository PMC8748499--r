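## Small internal helpers.

## data.frame constructor without the validation overhead of
## data.frame(); columns must already be equal-length vectors.
fast_df <- function(cols) {
  n <- if (length(cols)) length(cols[[1]]) else 0L
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}
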