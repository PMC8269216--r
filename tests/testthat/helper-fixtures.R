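# Shared fixtures, all built in code at test time.

random_profile <- function(L, seed) {
  generate_pssm_fixture(L, "random", seed = seed)
}

random_record <- function(L, seed, id = paste0("rec", seed)) {
  set.seed(seed)
  protein_record(id, paste(sample(AA_ALPHABET, L, replace = TRUE),
                           collapse = ""))
}

# A profile whose normalized matrix is set directly (for hand-constructed
# exact cases such as one-hot rows).
manual_profile <- function(norm, id = "manual",
                           sequence = paste(rep("A", nrow(norm)),
                                            collapse = "")) {
  prof <- generate_pssm_fixture(nrow(norm), "zero")
  prof$protein_id <- id
  prof$sequence <- sequence
  colnames(norm) <- AA_ALPHABET
  prof$norm <- norm
  prof
}

# Training on even a tiny dataset costs seconds, so evaluation tests share
# one cached separable model.
.fixture_env <- new.env(parent = emptyenv())

tiny_model_fixture <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- generate_dataset(synth_spec(n_pos = 12L, n_neg = 30L,
                                      length_range = c(30L, 50L),
                                      delta = 6, seed = 301L))
    .fixture_env$ds <- ds
    .fixture_env$model <- train_virion_ensemble(ds, seed = 302L,
                                      exponents = c(-10L, 0L, 10L),
                                      folds = 3L)
  }
  list(ds = .fixture_env$ds, model = .fixture_env$model)
}
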