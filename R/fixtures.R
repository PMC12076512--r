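# Deterministic synthetic fixtures: drug-like SMILES corpora assembled from a
# fragment grammar, and activity datasets with a known substructure-driven
# generative rule. Validity is guaranteed by construction (fragments are
# valid linear SMILES pieces; rings are templates with an explicit
# substitution hole), and molecular weight is controlled by rejection.

#' Default fragment inventory for the fixture generator
#'
#' Ring fragments are templates with a `%s` hole marking the backbone
#' continuation point (the hole is dropped for terminal use); `linkers` and
#' `terminals` are linear SMILES pieces that bond head-to-tail on
#' concatenation. `pharmacophore` is the piperazine ring used by the
#' activity rule of [make_activity_dataset()].
#'
#' @return a list with `rings`, `linkers`, `terminals`, `pharmacophore`.
#' @export
fixture_fragments <- function() {
  list(
    rings = c(
      "c1ccc(%s)cc1",       # benzene
      "c1ccc(%s)nc1",       # pyridine
      "c1cnc(%s)cn1",       # pyrimidine
      "c1ccc(%s)s1",        # thiophene
      "c1ccc(%s)o1",        # furan
      "c1cc(%s)c[nH]1",     # pyrrole
      "C1CCN(%s)CC1",       # piperidine (N-linked)
      "C1CCC(%s)CC1",       # cyclohexane
      "C1CCN(%s)C1",        # pyrrolidine (N-linked)
      "c1cc(F)ccc1%s",      # fluorobenzene, ortho continuation
      "c1cc(Cl)ccc1%s"      # chlorobenzene
    ),
    linkers = c(
      "C", "CC", "CCC", "O", "OC", "CO", "N", "NC", "CN",
      "C(=O)", "C(=O)N", "C(=O)O", "CCN", "CCO", "S"
    ),
    terminals = c(
      "C", "CC", "F", "Cl", "OC", "O", "N", "C(F)(F)F", "C#N",
      "N(C)C", "C(C)C", "OCC", "CCC"
    ),
    pharmacophore = "N1CCN(%s)CC1" # piperazine
  )
}

ring_terminal_form <- function(template) {
  out <- sub("(%s)", "", template, fixed = TRUE)
  sub("%s", "", out, fixed = TRUE)
}

assemble_fragments <- function(frags, is_ring) {
  # ring templates are written with digit 1; nested templates are renumbered
  # by depth so an inner ring never closes an outer one
  s <- ""
  level <- sum(is_ring)
  for (k in rev(seq_along(frags))) {
    f <- frags[k]
    if (is_ring[k]) {
      f <- gsub("1", as.character(level), f, fixed = TRUE)
      level <- level - 1
      s <- if (nzchar(s)) sprintf(f, s) else ring_terminal_form(f)
    } else {
      s <- paste0(f, s)
    }
  }
  s
}

sample_fixture_smiles <- function(inv, include_pharmacophore = FALSE) {
  n_rings <- sample(1:3, 1, prob = c(0.25, 0.5, 0.25))
  rings <- sample(inv$rings, n_rings, replace = TRUE)
  if (include_pharmacophore) {
    pos <- sample(n_rings, 1)
    rings[pos] <- inv$pharmacophore
  }
  frags <- character(0)
  is_ring <- logical(0)
  for (k in seq_len(n_rings)) {
    frags <- c(frags, rings[k])
    is_ring <- c(is_ring, TRUE)
    if (k < n_rings) {
      frags <- c(frags, sample(inv$linkers, 1))
      is_ring <- c(is_ring, FALSE)
    }
  }
  if (stats::runif(1) < 0.7) {
    frags <- c(frags, sample(inv$terminals, 1))
    is_ring <- c(is_ring, FALSE)
  }
  assemble_fragments(frags, is_ring)
}

#' Generate a deterministic corpus of drug-like molecules
#'
#' Molecules are assembled from the fragment inventory by seeded composition,
#' canonicalized, deduplicated and filtered to the molecular-weight window.
#' Every returned string is neutral, stereo-free and already canonical, so
#' standardization is the identity on it.
#'
#' @param n number of unique molecules to produce.
#' @param seed integer seed; identical seed and arguments give an identical
#'   corpus.
#' @param inventory fragment inventory, see [fixture_fragments()].
#' @param mw_range allowed molecular weight window (g/mol).
#' @param with_pharmacophore fraction of molecules forced to contain the
#'   pharmacophore ring (0 disables).
#' @param max_rounds sampling rounds before an infeasible inventory is
#'   reported.
#' @return tibble: `canonical_smiles`, `scaffold`, `mw`, `has_pharmacophore`.
#' @export
make_corpus <- function(n, seed = 1, inventory = fixture_fragments(),
                        mw_range = c(200, 450), with_pharmacophore = 0,
                        max_rounds = 60) {
  stopifnot(n >= 1, length(inventory$rings) > 0)
  with_seed(seed, {
    got <- character(0)
    has_ph <- logical(0)
    rounds <- 0
    while (length(got) < n && rounds < max_rounds) {
      rounds <- rounds + 1
      m <- max(2 * (n - length(got)), 50)
      force_ph <- stats::runif(m) < with_pharmacophore
      raw <- vapply(force_ph, function(fp) {
        sample_fixture_smiles(inventory, include_pharmacophore = fp)
      }, character(1))
      raw <- raw[nchar(raw) <= 90]
      can <- ob_canonical(raw, neutralize = TRUE)
      keep <- !is.na(can) & !duplicated(can) & !(can %in% got) & smiles_valid(can)
      can <- can[keep]
      if (length(can) == 0) next
      mw <- graph_descriptors(can)$mw
      ok <- mw >= mw_range[1] & mw <= mw_range[2]
      got <- c(got, can[ok])
      if (length(got) > n) got <- got[seq_len(n)]
    }
    if (length(got) < n) {
      profis_abort(
        "fragment inventory cannot reach the requested size in the MW window",
        "profis_infeasible_spec"
      )
    }
    ph_count <- ob_smarts_count(ob_mol_refs(got), "N1CCNCC1")
    tibble::tibble(
      canonical_smiles = got,
      scaffold = murcko_scaffold(got),
      mw = graph_descriptors(got)$mw,
      has_pharmacophore = ph_count > 0
    )
  })
}

#' Generate a synthetic activity dataset with a known rule
#'
#' pKi = `base_pki` + `effect` * \[contains pharmacophore\] + Gaussian noise;
#' Ki is reported in nM (`10^(9 - pKi)`). With the default 3-log-unit effect
#' and 0.3 noise, the pharmacophore signal dominates and fingerprint-based
#' classifiers can separate the classes almost perfectly; `effect = 0` gives
#' the null dataset where labels are independent of structure.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param effect activity effect size in log10 Ki units.
#' @param noise_sd Gaussian noise on pKi.
#' @param base_pki baseline pKi of molecules without the pharmacophore.
#' @param pharmacophore_frac fraction of molecules assembled around the
#'   pharmacophore ring.
#' @param inventory fragment inventory.
#' @return tibble: corpus columns plus `pki`, `ki_nm`, `activity`
#'   (`active`/`inactive`/`excluded` per the labeling thresholds).
#' @export
make_activity_dataset <- function(n, seed = 1, effect = 3, noise_sd = 0.3,
                                  base_pki = 5.5, pharmacophore_frac = 0.5,
                                  inventory = fixture_fragments()) {
  # stratified assembly keeps the pharmacophore prevalence near the requested
  # fraction despite MW filtering and deduplication
  n_ph <- round(n * pharmacophore_frac)
  ph <- if (n_ph > 0) {
    make_corpus(n_ph, seed = seed, inventory = inventory,
                with_pharmacophore = 1)
  } else NULL
  rest <- if (n - n_ph > 0) {
    make_corpus(n - n_ph, seed = seed + 59, inventory = inventory,
                with_pharmacophore = 0)
  } else NULL
  corpus <- dplyr::bind_rows(ph, rest)
  corpus <- corpus[!duplicated(corpus$canonical_smiles), , drop = FALSE]
  n <- nrow(corpus)
  with_seed(seed + 1000003L, {
    pki <- base_pki + effect * as.numeric(corpus$has_pharmacophore) +
      stats::rnorm(n, 0, noise_sd)
    corpus$pki <- pki
    corpus$ki_nm <- 10^(9 - pki)
    corpus$activity <- label_activity(corpus$ki_nm)
    corpus
  })
}
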