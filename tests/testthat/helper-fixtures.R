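# Shared fixtures: the published Condition A reference table (transcribed
# once; coordinates/distances/fields are what the pipeline must recompute)
# and the bundled measured recording set.

table1_reference <- function() {
  utils::read.csv(test_path("data-table1.csv"), stringsAsFactors = FALSE)
}

# electrodes whose printed field column disagrees with their own printed
# voltage and distance; excluded from numeric field comparisons
INCONSISTENT_EF_ELECTRODES <- c("F3", "F4", "P3", "P4")

condition_a_recordings <- function() {
  load_recordings(phantom_example("condition_a_recordings.csv"),
                  phantom_example("condition_a_meta.json"))
}

study_layout <- function() montage_layout(240.80)

noiseless_params <- function(...) forward_model_params(noise_cv = 0, ...)
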