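## Shared reduced-scale population study for the acceptance checks.
## Built once on first use and reused by every block that needs it.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_study(n_models = 140, seed = 1234,
                                    fastpace = TRUE, uptake_block = TRUE)
  }
  .study_cache$study
}
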