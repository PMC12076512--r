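test_that("the KL annealing schedule has the contracted endpoints and shape", {
  expect_equal(kld_weight(0), 0)
  expect_equal(kld_weight(25, beta = 0.1, anneal_epochs = 50), 0.05)
  expect_equal(kld_weight(50), 0.1)
  expect_equal(kld_weight(120), 0.1)
  w <- kld_weight(0:80)
  expect_true(all(diff(w) >= -1e-15)) # monotone non-decreasing
})

test_that("the KL divergence matches its closed form", {
  mu0 <- matrix(0, 1, 32); lv0 <- matrix(0, 1, 32)
  expect_equal(kld_divergence(mu0, lv0), 0)
  expect_equal(kld_divergence(matrix(1, 1, 32), lv0), 16)
  # non-negativity on random inputs
  withr::with_seed(2, {
    for (i in 1:20) {
      expect_gte(kld_divergence(matrix(rnorm(8), 2), matrix(rnorm(8), 2)), 0)
    }
  })
})

test_that("the loss decomposes exactly and vanishes at perfect reconstruction", {
  # logits placing probability ~1 on each target token
  V <- 5; TT <- 4
  tg <- rbind(c(4L, 5L, 3L, 1L))
  logits <- array(-1e3, c(1, V, TT))
  for (t in 1:3) logits[1, tg[1, t], t] <- 1e3
  out <- profis_loss(logits, tg, matrix(0, 1, 8), matrix(0, 1, 8), beta_t = 0.1)
  expect_equal(out$total, 0, tolerance = 1e-9)
  expect_equal(out$reconstruction, 0, tolerance = 1e-9)
  expect_equal(out$kld, 0)

  withr::with_seed(6, {
    logits2 <- array(rnorm(1 * V * TT), c(1, V, TT))
    mu <- matrix(rnorm(8), 1); lv <- matrix(rnorm(8), 1)
    o2 <- profis_loss(logits2, tg, mu, lv, beta_t = 0.07)
    expect_equal(o2$total, o2$reconstruction + 0.07 * o2$kld)
  })
})

test_that("analytic gradients agree with finite differences on a tiny network", {
  cfg <- profis_config(
    fp_length = 6, vocab_size = 8, latent_dim = 3, encoder_hidden = c(5, 4),
    gru_layers = 2, gru_hidden = 4, embed_dim = 3, omega_dim = 3,
    seq_len = 5
  )
  withr::with_seed(3, {
    params <- profis:::init_profis_params(cfg)
    X <- matrix(rbinom(12, 1, 0.5), 2, 6)
    S <- rbind(c(5L, 6L, 3L, 1L, 1L), c(7L, 4L, 6L, 3L, 1L))
  })
  loss_of <- function(par) {
    set.seed(42)
    profis:::profis_forward_backward(par, cfg, X, S, beta_t = 0.05)$total
  }
  set.seed(42)
  fb <- profis:::profis_forward_backward(params, cfg, X, S, beta_t = 0.05)
  fa <- profis:::unlist_params(params)
  fg <- profis:::unlist_params(fb$grads)
  withr::with_seed(10, {
    for (nm in sample(names(fa), 10)) {
      i <- sample(length(fa[[nm]]), 1)
      eps <- 1e-5
      fp <- fa; fp[[nm]][i] <- fp[[nm]][i] + eps
      fm <- fa; fm[[nm]][i] <- fm[[nm]][i] - eps
      num <- (loss_of(profis:::relist_params(fp, params)) -
              loss_of(profis:::relist_params(fm, params))) / (2 * eps)
      expect_equal(fg[[nm]][i], num, tolerance = 1e-4)
    }
  })
})

test_that("encoding is deterministic on the mean path and seeded when stochastic", {
  bundle <- toy_model_bundle()
  m <- bundle$model
  fp <- bundle$fps[1:3, ]
  z1 <- profis_encode(m, fp)
  z2 <- profis_encode(m, fp)
  expect_identical(z1, z2)
  zs1 <- profis_encode(m, fp, stochastic = TRUE, seed = 4)
  zs2 <- profis_encode(m, fp, stochastic = TRUE, seed = 4)
  zs3 <- profis_encode(m, fp, stochastic = TRUE, seed = 5)
  expect_identical(zs1, zs2)
  expect_false(identical(zs1, zs3))
  expect_false(identical(z1, zs1))
  expect_error(profis_encode(m, matrix(0, 1, 7)), class = "profis_shape_error")
})

test_that("greedy decoding is deterministic, bounded, and end-token terminated", {
  bundle <- toy_model_bundle()
  m <- bundle$model
  z <- profis_encode(m, bundle$fps[1:5, ])
  d1 <- profis_decode(m, z)
  d2 <- profis_decode(m, z)
  expect_identical(d1, d2)
  v <- m$vocab
  toks <- tokenize_sequences(d1, v, m$config$seq_len)
  expect_true(all(rowSums(toks != v$pad) <= m$config$seq_len))
  # sampled decoding is seeded
  s1 <- profis_decode(m, z, mode = "sample", temperature = 0.7, seed = 2)
  s2 <- profis_decode(m, z, mode = "sample", temperature = 0.7, seed = 2)
  expect_identical(s1, s2)
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  corp <- head(test_corpus(), 8)
  v <- build_vocabulary(corp$canonical_smiles, "smiles")
  sl <- max(nchar(corp$canonical_smiles)) + 3L
  seqs <- tokenize_sequences(corp$canonical_smiles, v, sl)
  fps <- compute_fingerprints(corp$canonical_smiles, "ecfp4", 128)
  cfg <- profis_config(
    fp_length = 128, vocab_size = length(v$full), latent_dim = 4,
    encoder_hidden = c(16, 16), gru_layers = 1, gru_hidden = 16,
    embed_dim = 8, omega_dim = 8, seq_len = sl, epochs = 3, batch_size = 4,
    lr = 1e-3
  )
  m1 <- profis_train(fps, seqs, v, cfg, seed = 77)
  m2 <- profis_train(fps, seqs, v, cfg, seed = 77)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params$enc$W1, m2$params$enc$W1)
  # loss decomposition holds in the log
  expect_equal(m1$loss_log$total,
               m1$loss_log$reconstruction + m1$loss_log$beta_t * m1$loss_log$kld)
})

test_that("latent sampling follows the prior and the aggregated posterior", {
  z <- sample_latents(1000, latent_dim = 8, mode = "prior", seed = 3)
  expect_true(all(abs(colMeans(z)) < 4 / sqrt(1000) + 0.05))
  # degenerate train set: all draws at the single point
  tz <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  zp <- sample_latents(10, mode = "aggregated_posterior", train_z = tz, seed = 1)
  expect_true(all(abs(sweep(zp, 2, c(1, 2, 3))) < 1e-12))
  expect_identical(sample_latents(5, latent_dim = 3, seed = 9),
                   sample_latents(5, latent_dim = 3, seed = 9))
  expect_error(sample_latents(5, mode = "aggregated_posterior"),
               class = "profis_bad_config")
})
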