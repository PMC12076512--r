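# Fingerprints: folded circular ECFP4, a 4860-bit substructure-key
# fingerprint in the Klekota-Roth layout, Tanimoto similarity/distance and
# controlled bit-flip noising for analog generation.

.profis_env <- new.env(parent = emptyenv())

#' Substructure key set for the 4860-bit key-based fingerprint
#'
#' The published Klekota-Roth key collection is a fixed list of 4860
#' substructure SMARTS. This package ships a synthetic stand-in: a
#' deterministic, programmatically enumerated set of exactly 4860 SMARTS
#' (linear atom/bond chains over C/N/O/S, aromatic ring motifs and common
#' functional groups), so the fingerprint length contract and all downstream
#' semantics (bit i set iff key i matches) are preserved without shipping
#' third-party data. Key order is fixed across sessions.
#'
#' @return character vector of 4860 SMARTS patterns.
#' @export
krfp_keys <- function() {
  if (!is.null(.profis_env$krfp_keys)) return(.profis_env$krfp_keys)
  atoms <- c("C", "N", "O", "S")
  bonds <- c("-", "=")
  chains <- character(0)
  for (len in 2:5) {
    atom_grid <- do.call(expand.grid, c(rep(list(atoms), len),
                                        stringsAsFactors = FALSE))
    bond_grid <- do.call(expand.grid, c(rep(list(bonds), len - 1),
                                        stringsAsFactors = FALSE))
    for (bi in seq_len(nrow(bond_grid))) {
      bnd <- unlist(bond_grid[bi, ], use.names = FALSE)
      pats <- apply(atom_grid, 1, function(a) {
        s <- a[1]
        for (k in 2:len) s <- paste0(s, bnd[k - 1], a[k])
        s
      })
      chains <- c(chains, pats)
    }
  }
  motifs <- c(
    "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1",
    "c1cncnc1", "c:c", "c:n", "c-C", "c-N", "c-O", "c-S", "c-F",
    "c-Cl", "c-Br", "C(=O)N", "C(=O)O", "C(=O)[OH]", "S(=O)(=O)N",
    "C#N", "C(F)(F)F", "N1CCNCC1", "N1CCCCC1", "N1CCCC1", "C1CCCCC1",
    "[NX3H2]", "[OX2H]", "[#7]", "[#8]", "[#16]", "[F,Cl,Br,I]",
    "N-N", "N=N", "N-O", "N=O", "C=C-C=C", "C#C", "c1ccc2ccccc2c1",
    "O=C-N-C", "N-C=O", "C-O-C", "C-S-C"
  )
  pool <- unique(c(motifs, chains))
  if (length(pool) < 4860) {
    profis_abort("key pool smaller than 4860", "profis_internal")
  }
  .profis_env$krfp_keys <- pool[seq_len(4860)]
  .profis_env$krfp_keys
}

#' Compute binary molecular fingerprints
#'
#' `"ecfp4"` is the radius-2 circular fingerprint folded to `nbits` columns
#' (bitwise OR over the fold); `"krfp"` sets bit i iff substructure key i of
#' [krfp_keys()] occurs in the molecule, and is always exactly 4860 bits.
#'
#' @param smiles character vector of standardized SMILES.
#' @param fp_type `"ecfp4"` or `"krfp"`.
#' @param nbits folded width for ECFP4 (ignored for KRFP).
#' @return a 0/1 integer matrix, one row per molecule, with attributes
#'   `fp_type` and row names set to the input SMILES.
#' @export
compute_fingerprints <- function(smiles, fp_type = c("ecfp4", "krfp"),
                                 nbits = 2048) {
  fp_type <- match.arg(fp_type)
  stopifnot(length(smiles) > 0)
  if (fp_type == "ecfp4") {
    sdf <- ob_quiet(ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles)))))
    fp <- ob_quiet(ChemmineR::fingerprintOB(sdf, "ECFP4"))
    full <- fp@fpma
    wide <- ncol(full)
    if (nbits > wide) {
      profis_abort("nbits exceeds the unfolded ECFP4 width", "profis_bad_config")
    }
    folded <- matrix(0L, nrow(full), nbits)
    for (blk in seq_len(ceiling(wide / nbits))) {
      cols <- ((blk - 1) * nbits + 1):min(blk * nbits, wide)
      folded[, seq_along(cols)] <- folded[, seq_along(cols)] | full[, cols]
    }
    storage.mode(folded) <- "integer"
    out <- folded
  } else {
    keys <- krfp_keys()
    refs <- ob_mol_refs(smiles)
    out <- matrix(0L, length(smiles), length(keys))
    for (k in seq_along(keys)) {
      cnt <- try(ob_smarts_count(refs, keys[k]), silent = TRUE)
      if (inherits(cnt, "try-error")) {
        profis_abort(paste0("unparseable substructure key at index ", k),
                     "profis_bad_smarts")
      }
      out[, k] <- as.integer(cnt > 0)
    }
  }
  rownames(out) <- smiles
  attr(out, "fp_type") <- fp_type
  out
}

check_fp_pair <- function(a, b) {
  ta <- attr(a, "fp_type"); tb <- attr(b, "fp_type")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb)) {
    profis_abort("incompatible fingerprint types", "profis_incompatible_fp")
  }
  if (length(a) != length(b)) {
    profis_abort("incompatible fingerprint lengths", "profis_incompatible_fp")
  }
}

#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`; defined as 0 when both vectors are all-zero
#' (identical empty fingerprints are at distance zero).
#'
#' @param a,b binary vectors of equal length and fingerprint type.
#' @return a number in \[0, 1\].
#' @export
tanimoto_distance <- function(a, b) {
  check_fp_pair(a, b)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  1 - inter / uni
}

#' Tanimoto distances from one fingerprint to the rows of a matrix
#'
#' @param fp a binary vector.
#' @param mat a binary matrix with `ncol(mat) == length(fp)`.
#' @return numeric vector of distances, one per row of `mat`.
#' @export
tanimoto_to_set <- function(fp, mat) {
  stopifnot(ncol(mat) == length(fp))
  inter <- as.numeric(mat %*% fp)
  uni <- rowSums(mat) + sum(fp) - inter
  d <- 1 - ifelse(uni == 0, 1, inter / uni)
  pmin(pmax(d, 0), 1)
}

#' Flip exactly k random bits of a fingerprint
#'
#' Positions are chosen uniformly without replacement, so the Hamming
#' distance between input and output is exactly `k`.
#'
#' @param fp binary vector.
#' @param k number of bits to flip (`0 <= k <= length(fp)`).
#' @param seed integer seed.
#' @return the noised fingerprint, attributes preserved.
#' @export
flip_bits <- function(fp, k, seed = 1) {
  if (k < 0 || k > length(fp)) {
    profis_abort("k must lie in [0, length(fp)]", "profis_invalid_argument")
  }
  out <- fp
  if (k > 0) {
    pos <- with_seed(seed, sample.int(length(fp), k))
    out[pos] <- 1L - out[pos]
  }
  out
}
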