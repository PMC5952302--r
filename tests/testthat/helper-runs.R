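# Reduced-scale experiments are the expensive shared fixtures of this
# suite; run each (protocol, sample) at most once per session.
.run_cache <- new.env(parent = emptyenv())

cached_smoke <- function(protocol, sample_id = 1, base_seed = 0) {
  key <- paste(protocol, sample_id, base_seed, sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_experiment(
      smoke_config(protocol, sample_id = sample_id, base_seed = base_seed))
  .run_cache[[key]]
}
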