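# Bounded Bayesian optimization over the latent space: a Gaussian-process
# surrogate with expected-improvement acquisition, quasi-random
# initialization, optional sequential domain reduction, and the library
# assembly / drug-likeness filtering around it.

#' Latent search box from reference embeddings
#'
#' Per-dimension bounds `mu - k*sigma` to `mu + k*sigma` computed from a
#' reference embedding set (typically the held-out test-set embeddings).
#' Dimensions with zero variance are widened by `epsilon` with a warning.
#'
#' @param reference_z numeric matrix of latent vectors (rows = molecules).
#' @param k bounds multiplier (default 2; larger boxes trade output validity
#'   for diversity).
#' @param epsilon widening applied to degenerate dimensions.
#' @return object of class `profis_searchbox`: list with `low`, `high`.
#' @export
compute_bounds <- function(reference_z, k = 2.0, epsilon = 1e-3) {
  z <- as.matrix(reference_z)
  stopifnot(nrow(z) >= 2)
  mu <- colMeans(z)
  sdv <- apply(z, 2, stats::sd)
  if (any(sdv == 0)) {
    rlang::warn("zero-variance latent dimension(s); widening by epsilon")
  }
  low <- mu - k * sdv
  high <- mu + k * sdv
  deg <- high - low < epsilon
  low[deg] <- low[deg] - epsilon / 2
  high[deg] <- high[deg] + epsilon / 2
  structure(list(low = low, high = high), class = "profis_searchbox")
}

#' @export
print.profis_searchbox <- function(x, ...) {
  cat("Latent search box,", length(x$low), "dimensions\n")
  cat("  width:", format(mean(x$high - x$low), digits = 4), "(mean)\n")
  invisible(x)
}

gp_fit <- function(X, y, lengthscales, noise = 1e-6) {
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yn <- (y - ym) / ys
  Xs <- sweep(X, 2, lengthscales, "/")
  d2 <- as.matrix(stats::dist(Xs))^2
  K <- exp(-0.5 * d2) + diag(noise, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yn))
  list(X = X, Xs = Xs, L = L, alpha = alpha, ym = ym, ys = ys,
       ls = lengthscales, noise = noise)
}

gp_predict <- function(fit, Xnew) {
  Xn <- sweep(Xnew, 2, fit$ls, "/")
  # cross-covariances
  d2 <- outer(rowSums(Xn^2), rowSums(fit$Xs^2), "+") - 2 * Xn %*% t(fit$Xs)
  Ks <- exp(-0.5 * pmax(d2, 0))
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu * fit$ys + fit$ym, sd = sqrt(var) * fit$ys)
}

expected_improvement <- function(mu, sd, best, xi = 0) {
  u <- (mu - best - xi) / sd
  (mu - best - xi) * stats::pnorm(u) + sd * stats::dnorm(u)
}

#' Gaussian-process Bayesian maximization over a bounded box
#'
#' `init_points` Latin-hypercube probes seed a Gaussian-process surrogate
#' (squared-exponential kernel, lengthscale proportional to the box width);
#' `n_iter` further probes maximize expected improvement over a random
#' candidate pool. With `domain_reduction`, the box contracts around the
#' incumbent by `dr_factor` whenever `dr_window` consecutive iterations fail
#' to improve, and never re-expands. All probes stay inside the currently
#' active box.
#'
#' @param objective function mapping a latent vector to a finite scalar
#'   (non-finite values discard the probe with a warning).
#' @param box a `profis_searchbox` (or list with `low`, `high`).
#' @param init_points initial quasi-random probes (default 4).
#' @param n_iter acquisition-guided probes (default 20).
#' @param domain_reduction contract the box during the search.
#' @param dr_factor width contraction factor per improvement-less window.
#' @param dr_window iterations without improvement that trigger contraction.
#' @param seed integer seed.
#' @return list of class `profis_bo`: `best_z`, `best_y`, `probes` tibble
#'   (coordinates, objective value, phase, per-probe box bounds).
#' @export
bayesian_maximize <- function(objective, box, init_points = 4, n_iter = 20,
                              domain_reduction = FALSE, dr_factor = 0.9,
                              dr_window = 3, seed = 1) {
  low0 <- box$low; high0 <- box$high
  d <- length(low0)
  with_seed(seed, {
    low <- low0; high <- high0
    X <- matrix(numeric(0), 0, d)
    y <- numeric(0)
    probe_rows <- list()
    add_probe <- function(zv, phase) {
      val <- objective(zv)
      if (!is.finite(val)) {
        rlang::warn("objective returned a non-finite value; probe discarded")
        return(invisible(NULL))
      }
      X <<- rbind(X, zv)
      y <<- c(y, val)
      probe_rows[[length(probe_rows) + 1]] <<- tibble::tibble(
        probe = length(y), phase = phase, y = val,
        z = list(zv), box_low = list(low), box_high = list(high)
      )
      invisible(val)
    }
    init <- lhs::randomLHS(init_points, d)
    for (i in seq_len(init_points)) {
      add_probe(low + init[i, ] * (high - low), "init")
    }
    stall <- 0
    for (it in seq_len(n_iter)) {
      best <- max(y)
      ls <- pmax(0.2 * (high0 - low0), 1e-6)
      fit <- try(gp_fit(X, y, ls), silent = TRUE)
      n_cand <- max(200, 100 * d)
      cand <- matrix(stats::runif(n_cand * d), n_cand, d)
      cand <- sweep(sweep(cand, 2, high - low, "*"), 2, low, "+")
      inc <- X[which.max(y), ]
      local <- matrix(stats::rnorm(50 * d, 0, 1), 50, d)
      local <- sweep(local, 2, (high - low) / 10, "*")
      local <- sweep(local, 2, inc, "+")
      local <- pmin(pmax(local, matrix(low, 50, d, byrow = TRUE)),
                    matrix(high, 50, d, byrow = TRUE))
      cand <- rbind(cand, local)
      pick <- if (inherits(fit, "try-error")) {
        sample.int(nrow(cand), 1)
      } else {
        pr <- gp_predict(fit, cand)
        which.max(expected_improvement(pr$mu, pr$sd, best))
      }
      add_probe(cand[pick, ], "search")
      if (max(y) > best + 1e-12) {
        stall <- 0
      } else {
        stall <- stall + 1
      }
      if (domain_reduction && stall >= dr_window) {
        width <- (high - low) * dr_factor
        center <- X[which.max(y), ]
        low_new <- pmax(center - width / 2, low0)
        high_new <- pmin(center + width / 2, high0)
        # guard against inverted bounds on the clipped edges
        keep <- high_new > low_new
        low[keep] <- low_new[keep]
        high[keep] <- high_new[keep]
        stall <- 0
      }
    }
    best_idx <- which.max(y)
    structure(
      list(best_z = X[best_idx, ], best_y = y[best_idx],
           probes = dplyr::bind_rows(probe_rows)),
      class = "profis_bo"
    )
  })
}

#' @export
print.profis_bo <- function(x, ...) {
  cat("Bayesian search:", nrow(x$probes), "probes, best objective",
      format(x$best_y, digits = 4), "\n")
  invisible(x)
}

#' Generate a candidate library by repeated Bayesian latent search
#'
#' Runs independent seeded searches maximizing the classifier's activity
#' probability, harvests every probe whose predicted activity exceeds
#' `p_floor` (plus the incumbents), greedily decodes the latent vectors,
#' records validity, and deduplicates on canonical SMILES.
#'
#' @param model a trained `profis_model`.
#' @param classifier function mapping a latent matrix to p(active), e.g.
#'   from [train_latent_classifier()].
#' @param box a `profis_searchbox`.
#' @param n_runs number of independent searches.
#' @param init_points,n_iter,domain_reduction search controls per run.
#' @param p_floor minimum predicted activity for harvesting a probe.
#' @param seed integer seed; run r uses `seed + r`.
#' @return tibble: `smiles` (canonical where valid), `raw_output`,
#'   `p_active`, `valid`, `source_seed`, deduplicated on canonical SMILES.
#' @export
generate_library <- function(model, classifier, box, n_runs = 5,
                             init_points = 4, n_iter = 20,
                             domain_reduction = TRUE, p_floor = 0.8,
                             seed = 1) {
  rows <- list()
  for (r in seq_len(n_runs)) {
    bo <- bayesian_maximize(function(z) classifier(z)[1], box,
                            init_points = init_points, n_iter = n_iter,
                            domain_reduction = domain_reduction,
                            seed = seed + r)
    zs <- do.call(rbind, bo$probes$z)
    keep <- bo$probes$y >= p_floor
    keep[which.max(bo$probes$y)] <- TRUE # incumbent always harvested
    if (!any(keep)) next
    zk <- zs[keep, , drop = FALSE]
    dec <- profis_decode(model, zk, mode = "greedy")
    smi <- decode_notation(dec, model$vocab$notation)
    valid <- !is.na(smi) & smiles_valid(smi)
    can <- rep(NA_character_, length(smi))
    if (any(valid)) can[valid] <- ob_canonical(smi[valid])
    valid <- valid & !is.na(can)
    rows[[r]] <- tibble::tibble(
      smiles = ifelse(valid, can, NA_character_),
      raw_output = dec,
      p_active = bo$probes$y[keep],
      valid = valid,
      source_seed = seed + r
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # deduplicate valid molecules on canonical form; invalid rows are kept
  # (they carry the validity accounting)
  dup <- duplicated(out$smiles) & !is.na(out$smiles)
  out[!dup, , drop = FALSE]
}

#' Post-hoc drug-likeness filters for generated libraries
#'
#' Keeps molecules with QED above `qed_min`, computed logP below
#' `clogp_max` and no ring larger than `max_ring` atoms; order is
#' preserved and property columns are attached.
#'
#' @param records tibble with a `smiles` column of valid molecules (rows
#'   with `NA` smiles are dropped).
#' @param qed_min,clogp_max,max_ring filter thresholds.
#' @return the surviving rows with `qed`, `clogp`, `max_ring` columns added.
#' @export
apply_druglikeness_filters <- function(records, qed_min = 0.5,
                                       clogp_max = 8.0, max_ring = 7) {
  recs <- records[!is.na(records$smiles), , drop = FALSE]
  if (nrow(recs) == 0) return(recs)
  props <- property_profile(recs$smiles)
  recs$qed <- props$qed
  recs$clogp <- props$clogp
  recs$max_ring <- props$max_ring
  keep <- props$descriptor_ok & props$qed > qed_min &
    props$clogp < clogp_max & props$max_ring <= max_ring
  recs[keep, , drop = FALSE]
}
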