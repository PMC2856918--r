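# One full default-scale pipeline run shared by the acceptance tests
# (reference design: 8 subjects, 20 + 20 trials x 3 conditions, 64 sensors).
# Memoized so the cohort is generated and analyzed exactly once per session.

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_report <- function() {
  if (is.null(.acceptance_cache$report)) {
    cfg <- pipeline_config(
      generator = list(rng_seed = 1),
      coupling = list(run_ws_perm = FALSE),
      seed = 1, verbose = FALSE)
    .acceptance_cache$report <- run_pipeline(cfg)
  }
  .acceptance_cache$report
}
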