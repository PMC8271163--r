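# The default-condition CRAC pipeline is expensive (~minutes), so it is run
# once per session and shared across test files.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$p))
    .pipeline_cache$p <- run_crac_pipeline(simulate_config(seed = 1L))
  .pipeline_cache$p
}
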