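# Dense/GRU layer primitives with manual backpropagation, written in base R
# matrix operations. Only what the fingerprint-to-sequence network needs:
# ReLU dense layers, stacked GRU cells (teacher forcing + BPTT), a softmax
# cross-entropy head and an Adam optimizer with global-norm gradient
# clipping. All randomness flows through R's RNG so runs are bit-for-bit
# reproducible under a seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_mat <- function(nr, nc) {
  # PyTorch-style uniform fan-in initialization
  b <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

init_gru_layer <- function(in_dim, hidden) {
  b <- 1 / sqrt(hidden)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -b, b), nr, nc)
  list(
    Wr = u(in_dim, hidden), Wz = u(in_dim, hidden), Wn = u(in_dim, hidden),
    Ur = u(hidden, hidden), Uz = u(hidden, hidden), Un = u(hidden, hidden),
    br = numeric(hidden), bz = numeric(hidden), bn = numeric(hidden),
    cn = numeric(hidden)
  )
}

gru_cell_forward <- function(p, x, h) {
  r <- sigmoid(sweep(x %*% p$Wr + h %*% p$Ur, 2, p$br, "+"))
  zg <- sigmoid(sweep(x %*% p$Wz + h %*% p$Uz, 2, p$bz, "+"))
  a <- sweep(h %*% p$Un, 2, p$cn, "+")
  n <- tanh(sweep(x %*% p$Wn, 2, p$bn, "+") + r * a)
  h_new <- (1 - zg) * n + zg * h
  list(h = h_new, r = r, z = zg, n = n, a = a, x = x, h_prev = h)
}

gru_cell_backward <- function(p, cache, dh_new, grads) {
  dz <- dh_new * (cache$h_prev - cache$n)
  dn <- dh_new * (1 - cache$z)
  dh <- dh_new * cache$z
  dn_pre <- dn * (1 - cache$n^2)
  da <- dn_pre * cache$r
  dr <- dn_pre * cache$a
  dr_pre <- dr * cache$r * (1 - cache$r)
  dz_pre <- dz * cache$z * (1 - cache$z)

  grads$Wn <- grads$Wn + crossprod(cache$x, dn_pre)
  grads$bn <- grads$bn + colSums(dn_pre)
  grads$Un <- grads$Un + crossprod(cache$h_prev, da)
  grads$cn <- grads$cn + colSums(da)
  grads$Wr <- grads$Wr + crossprod(cache$x, dr_pre)
  grads$Ur <- grads$Ur + crossprod(cache$h_prev, dr_pre)
  grads$br <- grads$br + colSums(dr_pre)
  grads$Wz <- grads$Wz + crossprod(cache$x, dz_pre)
  grads$Uz <- grads$Uz + crossprod(cache$h_prev, dz_pre)
  grads$bz <- grads$bz + colSums(dz_pre)

  dh <- dh + da %*% t(p$Un) + dr_pre %*% t(p$Ur) + dz_pre %*% t(p$Uz)
  dx <- dn_pre %*% t(p$Wn) + dr_pre %*% t(p$Wr) + dz_pre %*% t(p$Wz)
  list(dx = dx, dh = dh, grads = grads)
}

zero_like <- function(p) lapply(p, function(m) if (is.matrix(m)) m * 0 else m * 0)

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

adam_state <- function(params) {
  flat <- unlist_params(params)
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

unlist_params <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      if (is.list(x[[nm]])) walk(x[[nm]], paste0(prefix, nm, ".")) else
        out[[paste0(prefix, nm)]] <<- x[[nm]]
    }
  }
  walk(params, "")
  out
}

relist_params <- function(flat, skeleton) {
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      if (is.list(x[[nm]])) {
        x[[nm]] <- walk(x[[nm]], paste0(prefix, nm, "."))
      } else {
        x[[nm]] <- flat[[paste0(prefix, nm)]]
      }
    }
    x
  }
  walk(skeleton, "")
}

adam_step <- function(params, grads, state, lr, clip = 5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- unlist_params(params)
  fg <- unlist_params(grads)
  gn <- sqrt(sum(vapply(fg, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) fg <- lapply(fg, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(fp)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * fg[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * fg[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    fp[[nm]] <- fp[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = relist_params(fp, params), state = state)
}
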