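# Analog library generation by fingerprint noising, latent-space
# neighborhood sampling and interpolation, and scaffold-novelty scoring.

#' Generate structural analogs by fingerprint bit-flipping
#'
#' Computes the seed molecule's fingerprint, makes `n_copies` independently
#' noised copies (`k_flips` random bits each), passes them through the
#' deterministic encoder path and greedy decoder, and reports the valid,
#' unique outputs with their Tanimoto distance (same fingerprint type) to
#' the seed. Output diversity is attributable purely to the injected
#' fingerprint noise.
#'
#' @param seed_smiles the seed molecule (standardized internally).
#' @param model a trained `profis_model`.
#' @param fp_type,nbits fingerprint settings matching the model input.
#' @param n_copies number of noised fingerprints.
#' @param k_flips bits flipped per copy.
#' @param seed integer seed.
#' @return object of class `profis_analogs`: `seed_smiles`, `k_flips`,
#'   `n_inputs`, `validity`, and `analogs` tibble (`smiles`,
#'   `tanimoto_to_seed`).
#' @export
generate_analogs <- function(seed_smiles, model, fp_type = "ecfp4",
                             nbits = 2048, n_copies = 100, k_flips = 5,
                             seed = 1) {
  std <- standardize(seed_smiles)
  fp <- compute_fingerprints(std$canonical_smiles, fp_type, nbits)[1, ]
  noised <- do.call(rbind, lapply(seq_len(n_copies), function(i) {
    flip_bits(fp, k_flips, seed = seed + i)
  }))
  z <- profis_encode(model, noised, stochastic = FALSE)
  dec <- profis_decode(model, z, mode = "greedy")
  smi <- decode_notation(dec, model$vocab$notation)
  valid <- !is.na(smi) & smiles_valid(smi)
  validity <- mean(valid)
  analogs <- tibble::tibble()
  if (any(valid)) {
    can <- ob_canonical(smi[valid])
    ok <- !is.na(can)
    can <- unique(can[ok])
    if (length(can) > 0) {
      afp <- compute_fingerprints(can, fp_type, nbits)
      analogs <- tibble::tibble(
        smiles = can,
        tanimoto_to_seed = tanimoto_to_set(fp, afp)
      )
    }
  }
  structure(
    list(seed_smiles = std$canonical_smiles, k_flips = k_flips,
         n_inputs = n_copies, validity = validity, analogs = analogs),
    class = "profis_analogs"
  )
}

#' @export
print.profis_analogs <- function(x, ...) {
  cat("Analog report for", x$seed_smiles, "\n")
  cat("  ", x$n_inputs, " noised fingerprints (", x$k_flips, " flips) -> ",
      nrow(x$analogs), " unique valid analogs (validity ",
      format(x$validity, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.profis_analogs <- function(x, ...) x$analogs

#' Scaffold novelty scores against a reference scaffold set
#'
#' For every generated molecule: its Bemis-Murcko scaffold, the smallest
#' Tanimoto distance between that scaffold's fingerprint and any reference
#' scaffold, and a novelty flag (distance at or above the threshold).
#' Acyclic molecules carry the empty-scaffold convention and are flagged.
#'
#' @param smiles generated molecules.
#' @param reference_scaffolds character vector of scaffold SMILES (empty
#'   strings allowed for the acyclic group).
#' @param threshold novelty threshold on the minimum distance (default
#'   0.25).
#' @param fp_type,nbits fingerprint used for scaffold comparison.
#' @return tibble: `smiles`, `scaffold`, `min_distance`, `novel`,
#'   `acyclic`.
#' @export
scaffold_novelty <- function(smiles, reference_scaffolds, threshold = 0.25,
                             fp_type = "ecfp4", nbits = 2048) {
  stopifnot(length(reference_scaffolds) > 0)
  scaf <- murcko_scaffold(smiles)
  ref <- unique(reference_scaffolds[nzchar(reference_scaffolds)])
  ref_fp <- if (length(ref) > 0) compute_fingerprints(ref, fp_type, nbits) else NULL
  has_empty_ref <- any(!nzchar(reference_scaffolds))
  rows <- lapply(seq_along(smiles), function(i) {
    if (!nzchar(scaf[i])) {
      # acyclic: identical to the empty-scaffold group when present,
      # maximally distant otherwise
      d <- if (has_empty_ref) 0 else 1
      return(tibble::tibble(smiles = smiles[i], scaffold = "",
                            min_distance = d, novel = d >= threshold,
                            acyclic = TRUE))
    }
    fp <- compute_fingerprints(scaf[i], fp_type, nbits)[1, ]
    d <- if (is.null(ref_fp)) 1 else min(tanimoto_to_set(fp, ref_fp))
    tibble::tibble(smiles = smiles[i], scaffold = scaf[i],
                   min_distance = d, novel = d >= threshold, acyclic = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Decode the latent neighborhood of a molecule
#'
#' Samples points uniformly on spheres of the given Euclidean radii around
#' the seed's deterministic embedding (normalized Gaussian directions scaled
#' to the radius), greedily decodes them, and reports validity and Tanimoto
#' distance to the seed per radius.
#'
#' @param seed_smiles the center molecule.
#' @param model a trained `profis_model`.
#' @param radii numeric vector of Euclidean radii (0 reproduces the seed's
#'   own decode).
#' @param n_per_radius samples per radius.
#' @param fp_type,nbits fingerprint settings matching the model input.
#' @param seed integer seed.
#' @return tibble: `radius`, `decoded`, `smiles`, `valid`,
#'   `tanimoto_to_seed`.
#' @export
latent_neighborhood <- function(seed_smiles, model, radii = c(0, 1, 2, 4),
                                n_per_radius = 10, fp_type = "ecfp4",
                                nbits = 2048, seed = 1) {
  std <- standardize(seed_smiles)
  fp <- compute_fingerprints(std$canonical_smiles, fp_type, nbits)[1, ]
  z0 <- profis_encode(model, fp, stochastic = FALSE)[1, ]
  d <- length(z0)
  rows <- list()
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    dirs <- with_seed(seed + ri, {
      m <- matrix(stats::rnorm(n_per_radius * d), n_per_radius, d)
      m / sqrt(rowSums(m^2))
    })
    zs <- sweep(dirs * r, 2, z0, "+")
    dec <- profis_decode(model, zs, mode = "greedy")
    smi <- decode_notation(dec, model$vocab$notation)
    valid <- !is.na(smi) & smiles_valid(smi)
    tani <- rep(NA_real_, length(smi))
    if (any(valid)) {
      vfp <- compute_fingerprints(smi[valid], fp_type, nbits)
      tani[valid] <- tanimoto_to_set(fp, vfp)
    }
    rows[[ri]] <- tibble::tibble(
      radius = r, decoded = dec, smiles = ifelse(valid, smi, NA_character_),
      valid = valid, tanimoto_to_seed = tani
    )
  }
  dplyr::bind_rows(rows)
}

#' Interpolate between two molecules in latent space
#'
#' Linear interpolation between the deterministic embeddings of the two
#' endpoint molecules; each interpolation point is greedily decoded. With
#' `steps = 2` the result is exactly the two endpoint reconstructions.
#'
#' @param smiles_a,smiles_b endpoint molecules.
#' @param model a trained `profis_model`.
#' @param steps number of evenly spaced points including endpoints
#'   (>= 2).
#' @param fp_type,nbits fingerprint settings matching the model input.
#' @return tibble: `step`, `alpha`, `z` (list column), `decoded`, `smiles`,
#'   `valid`.
#' @export
interpolate_latent <- function(smiles_a, smiles_b, model, steps = 5,
                               fp_type = "ecfp4", nbits = 2048) {
  stopifnot(steps >= 2)
  can <- c(standardize(smiles_a)$canonical_smiles,
           standardize(smiles_b)$canonical_smiles)
  fps <- compute_fingerprints(can, fp_type, nbits)
  zz <- profis_encode(model, fps, stochastic = FALSE)
  alpha <- seq(0, 1, length.out = steps)
  zs <- do.call(rbind, lapply(alpha, function(a) (1 - a) * zz[1, ] + a * zz[2, ]))
  dec <- profis_decode(model, zs, mode = "greedy")
  smi <- decode_notation(dec, model$vocab$notation)
  valid <- !is.na(smi) & smiles_valid(smi)
  tibble::tibble(
    step = seq_len(steps), alpha = alpha,
    z = lapply(seq_len(steps), function(i) zs[i, ]),
    decoded = dec, smiles = ifelse(valid, smi, NA_character_), valid = valid
  )
}
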