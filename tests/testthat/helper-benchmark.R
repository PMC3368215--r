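# The desk-scale benchmark is expensive (ten phasing runs); compute it once
# and share it across the acceptance test blocks.
.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.bench_cache$bench))
    .bench_cache$bench <- founder_benchmark(
      seed = 1, n_reps = 5, n_markers = 2000, length_morgans = 0.3,
      demography = demography_config(sample_size = 100),
      params = model_params(), mask_rate = 0.01)
  .bench_cache$bench
}
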