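# The reference scenario run (0.5 mm voxels, 300 s) shared by the
# dose/coverage acceptance checks; computed once per test session, on first
# use.
.run_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- run_pipeline(mih_config(), quiet = TRUE)
  }
  .run_cache$run
}

probe_value <- function(run, probe, time) {
  p <- run$probes
  p$T_C[p$probe == probe & p$time_s == time]
}
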