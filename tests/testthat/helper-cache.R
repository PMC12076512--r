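# Shared, lazily built fixtures. Heavy objects (the toy trained model, the
# fixture corpora) are constructed once per test run and reused across test
# files.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- force(expr)
  .test_cache[[name]]
}

test_corpus <- function() {
  cached("corpus60", make_corpus(60, seed = 11))
}

# toy model deliberately small: 50 drug-like fixture molecules (half built
# around the pharmacophore ring), 512-bit folded ECFP4 input, 16-d latent,
# 2x128 GRU, 200 epochs -- the overfit regime the reconstruction and
# analog/trend checks run in
toy_model_bundle <- function() {
  cached("toy_model", {
    corp <- make_corpus(50, seed = 21, with_pharmacophore = 0.5)
    smis <- corp$canonical_smiles
    vocab <- build_vocabulary(smis, "smiles")
    sl <- max(nchar(smis)) + 5L
    seqs <- tokenize_sequences(smis, vocab, sl)
    fps <- compute_fingerprints(smis, "ecfp4", 512)
    cfg <- profis_config(
      fp_length = 512, vocab_size = length(vocab$full), latent_dim = 16,
      encoder_hidden = c(192, 192), gru_layers = 2, gru_hidden = 128,
      embed_dim = 48, omega_dim = 48, seq_len = sl, beta = 0.1,
      anneal_epochs = 50, lr = 3e-3, batch_size = 25, epochs = 200
    )
    model <- profis_train(fps, seqs, vocab, cfg, seed = 5)
    list(model = model, corpus = corp, fps = fps, vocab = vocab,
         smiles = smis, seqs = seqs)
  })
}

activity_bundle <- function() {
  cached("activity", {
    act <- make_activity_dataset(400, seed = 31)
    act <- act[act$activity != "excluded", , drop = FALSE]
    act
  })
}

# synthetic separable latent dataset keyed to the fixture activity labels:
# class centers displaced along a random direction, isotropic unit noise
separable_latents <- function(act, d = 16, displacement = 4, seed = 101) {
  withr::with_seed(seed, {
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    n <- nrow(act)
    centers <- outer(ifelse(act$activity == "active", displacement / 2,
                            -displacement / 2), dir)
    centers + matrix(stats::rnorm(n * d), n, d)
  })
}
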