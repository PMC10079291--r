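# cache the default-conditions pipeline run so several tests can share it
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$res))
    .pipeline_cache$res <- run_pipeline(sim_config(seed = 1))
  .pipeline_cache$res
}
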