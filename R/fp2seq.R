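# The fingerprint-to-sequence network: a stochastic encoder maps a binary
# fingerprint to a low-dimensional Gaussian posterior (reparametrized
# sampling keeps it differentiable); a stacked GRU decoder, conditioned on
# the latent vector at every timestep, autoregressively emits token
# sequences. Trained with teacher forcing under a two-term loss:
# pad-masked cross-entropy plus a KL regularizer against the standard
# normal, whose weight follows a cosine ramp over the first anneal epochs.

#' Model configuration
#'
#' The reference configuration embeds fingerprints in a 32-dimensional
#' latent space through a (1024, 1024) ReLU encoder, and decodes with a
#' 3-layer GRU of hidden size 512 over sequences of length 100 with
#' KL weight `beta = 0.1` annealed over the first 50 epochs. Every field
#' scales down for small experiments.
#'
#' @param fp_length input fingerprint width.
#' @param vocab_size token count of the target vocabulary (specials
#'   included).
#' @param latent_dim latent dimensionality.
#' @param encoder_hidden sizes of the two encoder layers.
#' @param gru_layers,gru_hidden decoder depth and hidden width.
#' @param embed_dim previous-token embedding width.
#' @param omega_dim width of the latent-to-input map feeding the GRU.
#' @param seq_len fixed token sequence length.
#' @param beta final KL weight.
#' @param anneal_epochs length of the cosine KL ramp.
#' @param lr,clip Adam learning rate and global-norm gradient clip.
#' @param batch_size,epochs training loop controls.
#' @return a list of class `profis_config`.
#' @export
profis_config <- function(fp_length, vocab_size, latent_dim = 32,
                          encoder_hidden = c(1024, 1024), gru_layers = 3,
                          gru_hidden = 512, embed_dim = 128, omega_dim = 128,
                          seq_len = 100, beta = 0.1, anneal_epochs = 50,
                          lr = 1e-3, clip = 5, batch_size = 64, epochs = 100,
                          ce_reduction = c("per_sequence", "per_token")) {
  cfg <- list(
    fp_length = fp_length, vocab_size = vocab_size, latent_dim = latent_dim,
    encoder_hidden = encoder_hidden, gru_layers = gru_layers,
    gru_hidden = gru_hidden, embed_dim = embed_dim, omega_dim = omega_dim,
    seq_len = seq_len, beta = beta, anneal_epochs = anneal_epochs,
    lr = lr, clip = clip, batch_size = batch_size, epochs = epochs,
    ce_reduction = match.arg(ce_reduction)
  )
  class(cfg) <- "profis_config"
  cfg
}

#' Cosine KL annealing schedule
#'
#' `beta * (1 - cos(pi * epoch / anneal_epochs)) / 2` during the ramp
#' (epochs 0 to `anneal_epochs`), the full `beta` afterwards; monotone
#' non-decreasing, 0 at epoch 0 and `beta / 2` at the midpoint.
#'
#' @param epoch non-negative epoch counter (0-based).
#' @param beta final KL weight.
#' @param anneal_epochs ramp length in epochs.
#' @return the KL weight at that epoch.
#' @export
kld_weight <- function(epoch, beta = 0.1, anneal_epochs = 50) {
  stopifnot(all(epoch >= 0))
  ifelse(epoch >= anneal_epochs, beta,
         beta * 0.5 * (1 - cos(pi * epoch / anneal_epochs)))
}

#' Kullback-Leibler divergence of a diagonal Gaussian from the standard normal
#'
#' `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)` summed over latent
#' dimensions and averaged over the batch.
#'
#' @param mu,logvar matrices (batch x latent) of posterior means and
#'   log-variances.
#' @return a non-negative scalar.
#' @export
kld_divergence <- function(mu, logvar) {
  if (is.null(dim(mu))) { mu <- matrix(mu, 1); logvar <- matrix(logvar, 1) }
  mean(rowSums(0.5 * (mu^2 + exp(logvar) - logvar - 1)))
}

#' Two-term training loss
#'
#' Cross-entropy of the token logits against the target sequence, averaged
#' over non-pad positions, plus `beta_t` times the KL divergence of the
#' encoder posterior.
#'
#' @param logits array (batch x vocab x steps) of unnormalized scores.
#' @param targets integer matrix (batch x steps) of target token indices.
#' @param mu,logvar encoder outputs.
#' @param beta_t KL weight at the current epoch.
#' @param pad pad token index (excluded from the reconstruction term).
#' @param reduction `"per_sequence"` (sum over non-pad positions, mean over
#'   the batch; matches the KL term's per-sample scale) or `"per_token"`.
#' @return list with `total`, `reconstruction`, `kld`.
#' @export
profis_loss <- function(logits, targets, mu, logvar, beta_t, pad = 1L,
                        reduction = c("per_sequence", "per_token")) {
  reduction <- match.arg(reduction)
  B <- dim(logits)[1]; V <- dim(logits)[2]; TT <- dim(logits)[3]
  mask <- targets != pad
  ce_sum <- 0
  for (t in seq_len(TT)) {
    p <- softmax_rows(matrix(logits[, , t], B, V))
    rows_t <- which(mask[, t])
    if (length(rows_t) > 0) {
      ce_sum <- ce_sum - sum(log(pmax(p[cbind(rows_t, targets[rows_t, t])], 1e-12)))
    }
  }
  ce <- ce_sum / if (reduction == "per_token") max(1, sum(mask)) else B
  kld <- kld_divergence(mu, logvar)
  list(total = ce + beta_t * kld, reconstruction = ce, kld = kld)
}

init_profis_params <- function(cfg) {
  h1 <- cfg$encoder_hidden[1]; h2 <- cfg$encoder_hidden[2]
  L <- cfg$latent_dim
  gru_in <- cfg$omega_dim + cfg$embed_dim
  gru <- list()
  for (l in seq_len(cfg$gru_layers)) {
    gru[[paste0("l", l)]] <- init_gru_layer(
      if (l == 1) gru_in else cfg$gru_hidden, cfg$gru_hidden
    )
  }
  list(
    enc = list(
      W1 = init_mat(cfg$fp_length, h1), b1 = numeric(h1),
      W2 = init_mat(h1, h2), b2 = numeric(h2),
      Wmu = init_mat(h2, L), bmu = numeric(L),
      Wlv = init_mat(h2, L), blv = numeric(L)
    ),
    dec = c(
      list(
        Womega = init_mat(L, cfg$omega_dim), bomega = numeric(cfg$omega_dim),
        Emb = init_mat(cfg$vocab_size, cfg$embed_dim)
      ),
      gru,
      list(Wpsi = init_mat(cfg$gru_hidden, cfg$vocab_size),
           bpsi = numeric(cfg$vocab_size))
    )
  )
}

encoder_forward <- function(p, X) {
  a1 <- sweep(X %*% p$W1, 2, p$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% p$W2, 2, p$b2, "+"); h2 <- pmax(a2, 0)
  mu <- sweep(h2 %*% p$Wmu, 2, p$bmu, "+")
  lv <- sweep(h2 %*% p$Wlv, 2, p$blv, "+")
  lv <- pmin(pmax(lv, -10), 10)
  list(mu = mu, logvar = lv, h1 = h1, h2 = h2, X = X)
}

# one teacher-forced pass with loss and gradients
profis_forward_backward <- function(params, cfg, X, S, beta_t, pad = 1L,
                                    start = 2L) {
  B <- nrow(X); TT <- ncol(S); H <- cfg$gru_hidden; NL <- cfg$gru_layers
  V <- cfg$vocab_size
  enc <- encoder_forward(params$enc, X)
  eps <- matrix(stats::rnorm(B * cfg$latent_dim), B)
  sig <- exp(0.5 * enc$logvar)
  z <- enc$mu + sig * eps
  omz <- sweep(z %*% params$dec$Womega, 2, params$dec$bomega, "+")

  prev <- cbind(rep(start, B), S[, -TT, drop = FALSE])
  mask <- S != pad
  # reconstruction normalizer: per-sequence sums averaged over the batch
  # keep the CE term on the same per-sample scale as the KL term; the
  # per-token mean is available for length-insensitive monitoring
  n_tok <- if (identical(cfg$ce_reduction, "per_token")) {
    max(1, sum(mask))
  } else {
    B
  }

  h <- lapply(seq_len(NL), function(l) matrix(0, B, H))
  caches <- vector("list", TT)
  ce_sum <- 0
  dlogits_list <- vector("list", TT)
  for (t in seq_len(TT)) {
    emb <- params$dec$Emb[prev[, t], , drop = FALSE]
    x <- cbind(omz, emb)
    layer_caches <- vector("list", NL)
    for (l in seq_len(NL)) {
      cc <- gru_cell_forward(params$dec[[paste0("l", l)]], x, h[[l]])
      layer_caches[[l]] <- cc
      h[[l]] <- cc$h
      x <- cc$h
    }
    logits <- sweep(h[[NL]] %*% params$dec$Wpsi, 2, params$dec$bpsi, "+")
    pmat <- softmax_rows(logits)
    rows_t <- which(mask[, t])
    if (length(rows_t) > 0) {
      ce_sum <- ce_sum - sum(log(pmax(pmat[cbind(rows_t, S[rows_t, t])], 1e-12)))
    }
    dl <- pmat
    dl[cbind(seq_len(B), S[, t])] <- dl[cbind(seq_len(B), S[, t])] - 1
    dl[!mask[, t], ] <- 0
    dlogits_list[[t]] <- dl / n_tok
    caches[[t]] <- layer_caches
  }
  ce <- ce_sum / n_tok
  kld <- kld_divergence(enc$mu, enc$logvar)

  # ---- backward ----
  g <- list(enc = zero_like(params$enc), dec = lapply(params$dec, function(x) {
    if (is.list(x)) zero_like(x) else x * 0
  }))
  dh_carry <- lapply(seq_len(NL), function(l) matrix(0, B, H))
  domz <- matrix(0, B, cfg$omega_dim)
  dEmb <- g$dec$Emb
  for (t in rev(seq_len(TT))) {
    dl <- dlogits_list[[t]]
    htop <- caches[[t]][[NL]]$h
    g$dec$Wpsi <- g$dec$Wpsi + crossprod(htop, dl)
    g$dec$bpsi <- g$dec$bpsi + colSums(dl)
    dh_upper <- dl %*% t(params$dec$Wpsi)
    for (l in rev(seq_len(NL))) {
      dh_new <- dh_carry[[l]] + dh_upper
      res <- gru_cell_backward(params$dec[[paste0("l", l)]], caches[[t]][[l]],
                               dh_new, g$dec[[paste0("l", l)]])
      g$dec[[paste0("l", l)]] <- res$grads
      dh_carry[[l]] <- res$dh
      dh_upper <- res$dx
    }
    dx1 <- dh_upper # gradient on [omz, emb] at step t
    domz <- domz + dx1[, seq_len(cfg$omega_dim), drop = FALSE]
    demb <- dx1[, cfg$omega_dim + seq_len(cfg$embed_dim), drop = FALSE]
    idx <- prev[, t]
    agg <- rowsum(demb, group = idx)
    dEmb[as.integer(rownames(agg)), ] <- dEmb[as.integer(rownames(agg)), ] + agg
  }
  g$dec$Emb <- dEmb
  g$dec$Womega <- crossprod(z, domz)
  g$dec$bomega <- colSums(domz)
  dz <- domz %*% t(params$dec$Womega)
  dmu <- dz + beta_t * enc$mu / B
  dlv <- dz * eps * 0.5 * sig + beta_t * 0.5 * (exp(enc$logvar) - 1) / B
  dlv[enc$logvar <= -10 | enc$logvar >= 10] <- 0
  # encoder backward
  pe <- params$enc
  g$enc$Wmu <- crossprod(enc$h2, dmu); g$enc$bmu <- colSums(dmu)
  g$enc$Wlv <- crossprod(enc$h2, dlv); g$enc$blv <- colSums(dlv)
  dh2 <- dmu %*% t(pe$Wmu) + dlv %*% t(pe$Wlv)
  dh2[enc$h2 <= 0] <- 0
  g$enc$W2 <- crossprod(enc$h1, dh2); g$enc$b2 <- colSums(dh2)
  dh1 <- dh2 %*% t(pe$W2)
  dh1[enc$h1 <= 0] <- 0
  g$enc$W1 <- crossprod(enc$X, dh1); g$enc$b1 <- colSums(dh1)

  list(ce = ce, kld = kld, total = ce + beta_t * kld, grads = g)
}

#' Train the fingerprint-to-sequence model
#'
#' Seeded, teacher-forced training with Adam and cosine KL annealing.
#' The per-epoch loss log records the reconstruction and KL terms and the
#' annealed weight, and satisfies `total = reconstruction + beta_t * kld`
#' exactly.
#'
#' @param fingerprints 0/1 matrix (molecules x bits).
#' @param sequences integer token matrix from [tokenize_sequences()].
#' @param vocab the `profis_vocab` the sequences were encoded with.
#' @param config a [profis_config()]; `fp_length`/`vocab_size` must match.
#' @param seed integer seed (weights, shuffling and reparametrization
#'   noise).
#' @return an object of class `profis_model` with elements `params`,
#'   `config`, `vocab`, `loss_log` (tibble), `train_mu` (deterministic
#'   embeddings of the training set).
#' @export
profis_train <- function(fingerprints, sequences, vocab, config, seed = 1) {
  stopifnot(nrow(fingerprints) == nrow(sequences))
  if (ncol(fingerprints) != config$fp_length) {
    profis_abort("fingerprint width does not match config", "profis_shape_error")
  }
  if (length(vocab$full) != config$vocab_size) {
    profis_abort("vocabulary size does not match config", "profis_shape_error")
  }
  X <- fingerprints
  storage.mode(X) <- "double"
  S <- sequences
  N <- nrow(X)
  with_seed(seed, {
    params <- init_profis_params(config)
    state <- adam_state(params)
    log_rows <- vector("list", config$epochs)
    for (e in seq_len(config$epochs)) {
      beta_t <- kld_weight(e - 1, config$beta, config$anneal_epochs)
      ord <- sample.int(N)
      ce_acc <- 0; kld_acc <- 0; nb <- 0
      for (b0 in seq(1, N, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, N)]
        fb <- profis_forward_backward(params, config,
                                      X[idx, , drop = FALSE],
                                      S[idx, , drop = FALSE], beta_t,
                                      pad = 1L, start = 2L)
        if (!is.finite(fb$total)) {
          profis_abort(paste0("non-finite loss at epoch ", e), "profis_diverged")
        }
        upd <- adam_step(params, fb$grads, state, config$lr, config$clip)
        params <- upd$params
        state <- upd$state
        ce_acc <- ce_acc + fb$ce * length(idx)
        kld_acc <- kld_acc + fb$kld * length(idx)
        nb <- nb + length(idx)
      }
      log_rows[[e]] <- tibble::tibble(
        epoch = e, beta_t = beta_t,
        reconstruction = ce_acc / nb, kld = kld_acc / nb,
        total = ce_acc / nb + beta_t * kld_acc / nb
      )
    }
    model <- structure(
      list(params = params, config = config, vocab = vocab,
           loss_log = dplyr::bind_rows(log_rows), seed = seed),
      class = "profis_model"
    )
    model$train_mu <- profis_encode(model, fingerprints, stochastic = FALSE)
    model
  })
}

#' @export
print.profis_model <- function(x, ...) {
  cfg <- x$config
  cat("Fingerprint-to-sequence model (", x$vocab$notation, ")\n", sep = "")
  cat("  fp ", cfg$fp_length, " -> latent ", cfg$latent_dim, " -> GRU ",
      cfg$gru_layers, "x", cfg$gru_hidden, " -> vocab ", cfg$vocab_size,
      "\n", sep = "")
  n <- nrow(x$loss_log)
  if (n > 0) {
    cat(sprintf("  final loss %.4f (reconstruction %.4f, KLD %.4f)\n",
                x$loss_log$total[n], x$loss_log$reconstruction[n],
                x$loss_log$kld[n]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.profis_model <- function(x, ...) x$loss_log

#' @exportS3Method generics::glance
glance.profis_model <- function(x, ...) {
  n <- nrow(x$loss_log)
  tibble::tibble(
    epochs = n,
    final_total = x$loss_log$total[n],
    final_reconstruction = x$loss_log$reconstruction[n],
    final_kld = x$loss_log$kld[n],
    latent_dim = x$config$latent_dim,
    notation = x$vocab$notation
  )
}

#' Embed fingerprints in the latent space
#'
#' The deterministic path returns the posterior mean; the stochastic path
#' draws one reparametrized sample per molecule.
#'
#' @param model a trained `profis_model`.
#' @param fingerprints 0/1 matrix with `config$fp_length` columns.
#' @param stochastic draw from the posterior instead of returning its mean.
#' @param seed seed for the stochastic draw.
#' @return numeric matrix (molecules x latent_dim).
#' @export
profis_encode <- function(model, fingerprints, stochastic = FALSE, seed = 1) {
  if (is.null(dim(fingerprints))) fingerprints <- matrix(fingerprints, nrow = 1)
  if (ncol(fingerprints) != model$config$fp_length) {
    profis_abort("fingerprint width does not match the model", "profis_shape_error")
  }
  X <- fingerprints
  storage.mode(X) <- "double"
  enc <- encoder_forward(model$params$enc, X)
  if (!stochastic) return(enc$mu)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu))
    enc$mu + exp(0.5 * enc$logvar) * eps
  })
}

#' Decode latent vectors to molecular notation strings
#'
#' Autoregressive generation: each step feeds the latent projection
#' concatenated with the previous token's embedding through the GRU stack
#' (hidden states start at zero); `greedy` takes the argmax, `sample` draws
#' from the temperature-scaled distribution. Generation stops at the end
#' token and never exceeds `config$seq_len` steps.
#'
#' @param model a trained `profis_model`.
#' @param z latent matrix (rows = vectors to decode) or a single vector.
#' @param mode `"greedy"` or `"sample"`.
#' @param temperature softmax temperature for sampling.
#' @param seed seed for sampling mode.
#' @return character vector of decoded strings (in the model's notation).
#' @export
profis_decode <- function(model, z, mode = c("greedy", "sample"),
                          temperature = 1.0, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  cfg <- model$config
  p <- model$params
  B <- nrow(z)
  run <- function() {
    omz <- sweep(z %*% p$dec$Womega, 2, p$dec$bomega, "+")
    h <- lapply(seq_len(cfg$gru_layers), function(l) matrix(0, B, cfg$gru_hidden))
    prev <- rep(2L, B) # start token
    done <- rep(FALSE, B)
    out <- matrix(1L, B, cfg$seq_len) # pad
    for (t in seq_len(cfg$seq_len)) {
      x <- cbind(omz, p$dec$Emb[prev, , drop = FALSE])
      for (l in seq_len(cfg$gru_layers)) {
        cc <- gru_cell_forward(p$dec[[paste0("l", l)]], x, h[[l]])
        h[[l]] <- cc$h
        x <- cc$h
      }
      logits <- sweep(h[[cfg$gru_layers]] %*% p$dec$Wpsi, 2, p$dec$bpsi, "+")
      logits[, c(1L, 2L)] <- -Inf # never emit pad or start
      nxt <- if (mode == "greedy") {
        max.col(logits, ties.method = "first")
      } else {
        pr <- softmax_rows(logits / temperature)
        vapply(seq_len(B), function(i) {
          sample.int(ncol(pr), 1, prob = pr[i, ])
        }, integer(1))
      }
      nxt[done] <- 1L
      out[, t] <- ifelse(done, 1L, as.integer(nxt))
      done <- done | nxt == 3L # end token
      prev <- ifelse(done, 3L, as.integer(nxt))
      if (all(done)) break
    }
    out
  }
  out <- if (mode == "sample") with_seed(seed, run()) else run()
  detokenize_sequences(out, model$vocab)
}

#' Draw latent vectors from the prior or the aggregated posterior
#'
#' The prior is the standard normal the KL term regularizes toward; the
#' aggregated posterior is approximated by a diagonal normal moment-matched
#' to the training-set embeddings.
#'
#' @param n number of draws.
#' @param latent_dim latent dimensionality (prior mode).
#' @param mode `"prior"` or `"aggregated_posterior"`.
#' @param train_z training embedding matrix (required for the posterior
#'   mode).
#' @param seed integer seed.
#' @return matrix (n x latent_dim).
#' @export
sample_latents <- function(n, latent_dim = NULL,
                           mode = c("prior", "aggregated_posterior"),
                           train_z = NULL, seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "prior") {
      stopifnot(!is.null(latent_dim))
      matrix(stats::rnorm(n * latent_dim), n)
    } else {
      if (is.null(train_z)) {
        profis_abort("aggregated posterior needs training embeddings",
                     "profis_bad_config")
      }
      mu <- colMeans(train_z)
      sdv <- apply(train_z, 2, stats::sd)
      sdv[!is.finite(sdv)] <- 0
      sweep(matrix(stats::rnorm(n * length(mu)), n) %*% diag(sdv, length(mu)),
            2, mu, "+")
    }
  })
}
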