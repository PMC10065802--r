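# Minimal hand-built trace for normalisation edge cases.
new_trace_for_test <- function(vals, gene = "g") {
  tibble::tibble(
    position = seq(0, 100, length.out = length(vals)),
    gene = gene,
    intensity = as.numeric(vals)
  )
}
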