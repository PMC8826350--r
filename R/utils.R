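# small shared helpers

# round-half-up at `digits` decimals; base round() is round-half-even
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse an id vector for messages, truncating long lists
.id_preview <- function(ids, max = 5) {
  if (length(ids) <= max) return(paste(ids, collapse = ", "))
  paste0(paste(ids[seq_len(max)], collapse = ", "), ", ... (",
         length(ids), " total)")
}
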