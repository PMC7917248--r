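# Shared fixtures: everything is built in code at test time.

# A small model configuration that keeps forward/backward passes fast while
# exercising every architectural element (three conv layers, four-layer MLP,
# projections, three-layer head).
tiny_config <- function(...) {
  defaults <- list(
    mlp_widths = c(32L, 16L, 8L, 12L),
    cnn_filters = c(6L, 6L, 6L),
    cnn_kernel_lengths = c(3L, 4L, 5L),
    shared_dim = 10L,
    fc_widths = c(16L, 16L, 8L),
    dropout_rates = c(0.1, 0.1),
    max_len = 40L,
    batch_size = 16L,
    learning_rate = 1e-3,
    epochs = 2L,
    seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# A hand-built affinity matrix with simple molecules and short sequences.
toy_affinity_matrix <- function(kd) {
  smiles <- c("CCO", "CCN", "CCC", "CCS", "CCCO", "CCCN")[seq_len(nrow(kd))]
  seqs <- vapply(seq_len(ncol(kd)), function(j) {
    paste(rep(c("M", "K", "V", "L"), length.out = 8 + j), collapse = "")
  }, "")
  affinity_matrix(
    drug_ids = paste0("d", seq_len(nrow(kd))),
    drug_smiles = smiles,
    protein_ids = paste0("p", seq_len(ncol(kd))),
    protein_seqs = seqs,
    kd = kd
  )
}

# Small synthetic dataset for training tests.
tiny_dataset <- function(n_drugs = 10, n_proteins = 4, seed = 5, noise_sd = 0.2) {
  spec <- synthetic_spec(n_drugs, n_proteins, latent_dim = 2,
                         signal_scale = 1, noise_sd = noise_sd, seed = seed)
  generate_extended_dataset(spec)
}

# O(n^2) reference implementation of the concordance index: loop over all
# ordered pairs, count concordant = 1, predicted tie = 0.5, discordant = 0.
ci_bruteforce <- function(y_true, y_pred) {
  n <- length(y_true)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y_true[i] > y_true[j]) {
        den <- den + 1
        if (y_pred[i] > y_pred[j]) num <- num + 1
        else if (y_pred[i] == y_pred[j]) num <- num + 0.5
      }
    }
  }
  num / den
}
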