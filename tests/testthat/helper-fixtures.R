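# quick training setup shared by tests that only need a trained-ish model
quick_config <- function(epochs = 2, seed = 1) {
  train_config(epochs = epochs, seed = seed)
}

tiny_train_set <- function(L = 4, N = 120, mu = 0, alpha = 0.5, seed = 7) {
  generate_dataset(all_strands(L), N, alpha = alpha, mu = mu,
                   role = "train", seed = seed)
}
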