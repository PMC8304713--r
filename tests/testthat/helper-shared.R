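# Shared fixtures built once per test run (low-noise synthetic dataset
# and a small fitted ensemble reused across module tests).

.shared <- new.env(parent = emptyenv())

shared_gen <- function() {
  if (is.null(.shared$gen))
    .shared$gen <- generate_records(generator_spec(noise_sd = 0.02, seed = 11))
  .shared$gen
}

shared_features <- function() {
  if (is.null(.shared$fm)) {
    gen <- shared_gen()
    .shared$fm <- build_feature_matrix(gen$records, gen$components)
  }
  .shared$fm
}

shared_ensemble <- function() {
  if (is.null(.shared$ens)) {
    fm <- shared_features()
    .shared$ens <- build_ensemble(fm$x, fm$y, n_target = 10L, seed = 11L)
  }
  .shared$ens
}
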