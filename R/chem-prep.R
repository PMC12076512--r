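# Molecule standardization, drug-likeness training filters, Bemis-Murcko
# scaffolds and the scaffold-grouped train/test split.

largest_fragment <- function(canonical) {
  vapply(canonical, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1) return(s)
    # keep the fragment with the most heavy atoms; ties -> lexicographically
    # smallest canonical string
    sizes <- vapply(frags, function(f) {
      g <- try(parse_smiles(f), silent = TRUE)
      if (inherits(g, "try-error")) -1L else nrow(g$atoms)
    }, integer(1))
    cand <- frags[sizes == max(sizes)]
    sort(cand)[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Standardize a single molecule
#'
#' Counterions are removed (the fragment with the most heavy atoms is kept),
#' formal charges are neutralized where chemically possible, stereochemistry
#' descriptors are stripped, and the canonical SMILES is returned. The
#' operation is idempotent: standardizing a standardized string returns it
#' unchanged.
#'
#' @param raw a single SMILES string.
#' @return a list (molecule record) with `raw_input`, `canonical_smiles`,
#'   `scaffold`, `mw`.
#' @export
standardize <- function(raw) {
  df <- standardize_molecules(tibble::tibble(smiles = raw), on_error = "abort")
  as.list(df[1, ])
}

#' Standardize a table of molecules
#'
#' Vectorized standardization pipeline: parse, keep the largest organic
#' fragment, neutralize charges, strip stereochemistry, canonicalize, and
#' attach the Bemis-Murcko scaffold and molecular weight.
#'
#' @param data a data frame with a SMILES column, or a character vector.
#' @param smiles_col name of the SMILES column.
#' @param on_error `"drop"` removes unparseable rows with a warning;
#'   `"abort"` signals `profis_invalid_molecule` naming the offending string.
#' @return a tibble with columns `raw_input`, `canonical_smiles`, `scaffold`,
#'   `mw` plus any other input columns carried through.
#' @export
standardize_molecules <- function(data, smiles_col = "smiles",
                                  on_error = c("drop", "abort")) {
  on_error <- match.arg(on_error)
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  raw <- data[[smiles_col]]
  if (is.null(raw) || any(!nzchar(raw) | is.na(raw))) {
    profis_abort("input contains empty SMILES", "profis_invalid_molecule")
  }
  can0 <- ob_canonical(raw, neutralize = FALSE)
  frag <- largest_fragment(can0)
  can <- ob_canonical(frag, neutralize = TRUE)
  # reject strings OpenBabel mangled into something our validator rejects
  can[!is.na(can) & !smiles_valid(can)] <- NA_character_
  bad <- is.na(can)
  if (any(bad)) {
    if (on_error == "abort") {
      profis_abort(
        paste0("invalid molecule: ", raw[which(bad)[1]]),
        "profis_invalid_molecule"
      )
    }
    rlang::warn(paste0("dropping ", sum(bad), " unparseable molecule(s)"))
  }
  keep <- !bad
  out <- tibble::tibble(
    raw_input = raw[keep],
    canonical_smiles = can[keep]
  )
  extra <- data[keep, setdiff(names(data),
                              c(smiles_col, "raw_input", "canonical_smiles",
                                "scaffold", "mw")), drop = FALSE]
  out <- dplyr::bind_cols(out, extra)
  out$scaffold <- murcko_scaffold(out$canonical_smiles)
  out$mw <- graph_descriptors(out$canonical_smiles)$mw
  out
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus the linkers connecting them, with side chains removed;
#' atoms double- or triple-bonded directly to the framework (e.g. carbonyl
#' oxygens on linkers) are retained. Acyclic molecules yield an empty string.
#'
#' @param smiles character vector of standardized SMILES.
#' @return character vector of canonical scaffold SMILES ("" if acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  raw <- vapply(smiles, function(s) {
    g <- parse_smiles(s)
    ring <- ring_atom_indices(g)
    if (length(ring) == 0) return("")
    n <- nrow(g$atoms)
    keep <- rep(TRUE, n)
    # iteratively prune non-ring terminal atoms
    repeat {
      deg <- numeric(n)
      for (r in seq_len(nrow(g$bonds))) {
        if (keep[g$bonds$i[r]] && keep[g$bonds$j[r]]) {
          deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + 1
          deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + 1
        }
      }
      prune <- which(keep & deg <= 1 & !(seq_len(n) %in% ring))
      if (length(prune) == 0) break
      keep[prune] <- FALSE
    }
    # re-attach atoms multiply-bonded to the framework
    repeat {
      added <- FALSE
      for (r in seq_len(nrow(g$bonds))) {
        if (g$bonds$order[r] >= 2) {
          a <- g$bonds$i[r]; b <- g$bonds$j[r]
          if (keep[a] && !keep[b]) { keep[b] <- TRUE; added <- TRUE }
          if (keep[b] && !keep[a]) { keep[a] <- TRUE; added <- TRUE }
        }
      }
      if (!added) break
    }
    sub <- induced_subgraph_mol(g, which(keep))
    graph_to_smiles(sub)
  }, character(1), USE.NAMES = FALSE)
  out <- raw
  nz <- nzchar(raw)
  if (any(nz)) out[nz] <- ob_canonical(raw[nz])
  out
}

induced_subgraph_mol <- function(g, keep_idx) {
  remap <- integer(nrow(g$atoms))
  remap[keep_idx] <- seq_along(keep_idx)
  b <- g$bonds[g$bonds$i %in% keep_idx & g$bonds$j %in% keep_idx, , drop = FALSE]
  atoms <- g$atoms[keep_idx, , drop = FALSE]
  # pruning can orphan aromatic flags (e.g. a lone exocyclic atom); keep them,
  # the writer and downstream canonicalization handle kekulized orders
  list(
    atoms = atoms,
    bonds = tibble::tibble(
      i = remap[b$i], j = remap[b$j],
      order = b$order, arom = b$arom %||% rep(FALSE, nrow(b))
    )
  )
}

#' Drug-likeness training filter
#'
#' TRUE when the molecular weight lies in \[`mw_min`, `mw_max`\] g/mol and the
#' molecule has zero violations of the classic rule-of-five criteria
#' (MW <= 500, clogP <= 5, hydrogen-bond donors <= 5, acceptors <= 10).
#'
#' @param smiles character vector of standardized SMILES.
#' @param mw_min,mw_max allowed molecular-weight window in g/mol.
#' @return logical vector.
#' @export
passes_training_filters <- function(smiles, mw_min = 200, mw_max = 450) {
  gd <- graph_descriptors(smiles)
  pr <- ob_properties(smiles)
  violations <- (gd$mw > 500) + (pr$clogp > 5) + (gd$hbd > 5) + (gd$hba > 10)
  gd$mw >= mw_min & gd$mw <= mw_max & violations == 0
}

#' Scaffold-grouped train/test split
#'
#' Molecules sharing a Bemis-Murcko scaffold always land in the same
#' partition. Scaffold groups are drawn in seeded random order; a group is
#' appended to the training set only when the resulting training set stays
#' within `train_frac` of the data, otherwise it goes to the test set.
#' Acyclic molecules (empty scaffold) form one shared group.
#'
#' @param data tibble with a `scaffold` column (see
#'   [standardize_molecules()]).
#' @param train_frac target training fraction (default 0.9).
#' @param seed integer seed controlling the group order.
#' @return the input tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
scaffold_split <- function(data, train_frac = 0.9, seed = 1) {
  stopifnot(nrow(data) > 0, train_frac > 0, train_frac < 1)
  if (is.null(data$scaffold)) {
    profis_abort("data needs a `scaffold` column", "profis_missing_column")
  }
  groups <- split(seq_len(nrow(data)), data$scaffold)
  ord <- with_seed(seed, sample.int(length(groups)))
  cap <- train_frac * nrow(data)
  split_lab <- character(nrow(data))
  n_train <- 0
  for (gi in ord) {
    idx <- groups[[gi]]
    if (n_train + length(idx) <= cap) {
      split_lab[idx] <- "train"
      n_train <- n_train + length(idx)
    } else {
      split_lab[idx] <- "test"
    }
  }
  data$split <- split_lab
  data
}

#' Read molecules from a plain-text or CSV file
#'
#' Accepts one-SMILES-per-line text, or CSV with a `smiles` column and an
#' optional `ki_nm` activity column.
#'
#' @param path file path.
#' @return tibble with `smiles` (and `ki_nm` when present).
#' @export
read_molecules <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first) || grepl("^smiles$", trimws(first), ignore.case = TRUE)) {
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) {
      if ("canonical_smiles" %in% names(df)) {
        df$smiles <- df$canonical_smiles
      } else {
        profis_abort("CSV needs a `smiles` column", "profis_bad_input")
      }
    }
    df
  } else {
    tibble::tibble(smiles = readLines(path))
  }
}

#' Write a molecule table to CSV
#'
#' @param data tibble of molecules.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
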