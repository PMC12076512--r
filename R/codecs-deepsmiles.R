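# DeepSMILES-style notation: branches lose their open parenthesis and close
# with one ')' per atom popped from the attachment stack; the two matched
# ring-closure digits of SMILES collapse into a single ring-size token at the
# closing atom (the number of atoms written between and including the two
# ring partners; %nn above 9).

is_atom_token <- function(tok) {
  startsWith(tok, "[") ||
    tok %in% c(ORGANIC_SUBSET, "c", "n", "o", "s", "p", "b")
}

#' Convert valid SMILES to DeepSMILES
#'
#' @param s a single valid SMILES string.
#' @return the DeepSMILES string.
#' @export
smiles_to_deepsmiles <- function(s) {
  toks <- smi_lex(s)
  if (is.null(toks)) {
    profis_abort(paste0("cannot lex SMILES: ", s), "profis_unconvertible")
  }
  out <- character(0)
  atom_ord <- 0L
  stack <- integer(0)      # attachment chain of atom ordinals
  marks <- integer(0)      # stack sizes at '('
  rings <- list()          # digit -> opening atom ordinal
  held_bond <- ""          # bond symbol awaiting its successor token
  for (tok in toks) {
    if (is_atom_token(tok)) {
      atom_ord <- atom_ord + 1L
      stack <- c(stack, atom_ord)
      out <- c(out, held_bond, tok)
      held_bond <- ""
    } else if (tok == "(") {
      marks <- c(marks, length(stack))
    } else if (tok == ")") {
      if (length(marks) == 0) {
        profis_abort("unbalanced parentheses", "profis_unconvertible")
      }
      m <- marks[length(marks)]
      marks <- marks[-length(marks)]
      out <- c(out, rep(")", length(stack) - m))
      stack <- stack[seq_len(m)]
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      key <- sub("^%", "", tok)
      if (is.null(rings[[key]])) {
        # opening digit dropped; a bond symbol written at the opening end
        # is dropped with it (the closure end carries the order)
        rings[[key]] <- atom_ord
        held_bond <- ""
      } else {
        size <- atom_ord - rings[[key]] + 1L
        rings[[key]] <- NULL
        if (size > 99) profis_abort("ring span too large", "profis_unconvertible")
        out <- c(out, held_bond,
                 if (size <= 9) as.character(size) else sprintf("%%%02d", size))
        held_bond <- ""
      }
    } else if (tok == ".") {
      profis_abort("multi-fragment strings are not convertible",
                   "profis_unconvertible")
    } else {
      held_bond <- tok
    }
  }
  paste(out, collapse = "")
}

#' Decode DeepSMILES to SMILES
#'
#' Rebuilds the molecular graph (attachment stack, ring-size closures),
#' checks valences and writes SMILES. Signals `profis_invalid_smiles` for
#' syntactically or chemically broken input.
#'
#' @param s a single DeepSMILES string.
#' @return a SMILES string.
#' @export
deepsmiles_to_smiles <- function(s) {
  toks <- lex_deepsmiles(s)
  if (is.null(toks) || length(toks) == 0) {
    profis_abort("cannot lex DeepSMILES", "profis_invalid_smiles")
  }
  atoms <- list()
  bonds <- list()
  stack <- integer(0)
  pending <- ""
  bond_order <- c("-" = 1, "=" = 2, "#" = 3, "/" = 1, "\\" = 1)
  for (tok in toks) {
    if (is_atom_token(tok)) {
      at <- if (startsWith(tok, "[")) {
        parse_bracket_atom(tok)
      } else if (tok %in% c("c", "n", "o", "s", "p", "b")) {
        list(elem = toupper(tok), arom = TRUE, hcount = NA_integer_,
             charge = 0L, bracket = FALSE)
      } else {
        list(elem = tok, arom = FALSE, hcount = NA_integer_,
             charge = 0L, bracket = FALSE)
      }
      if (is.null(at)) {
        profis_abort(paste0("bad atom token: ", tok), "profis_invalid_smiles")
      }
      atoms[[length(atoms) + 1]] <- at
      idx <- length(atoms)
      if (length(stack) > 0) {
        prev <- stack[length(stack)]
        ord <- if (pending == "") {
          if (atoms[[prev]]$arom && at$arom) -1 else 1
        } else bond_order[[pending]]
        bonds[[length(bonds) + 1]] <- list(i = prev, j = idx, order = ord)
      } else if (pending != "") {
        profis_abort("dangling bond", "profis_invalid_smiles")
      }
      pending <- ""
      stack <- c(stack, idx)
    } else if (tok == ")") {
      if (length(stack) <= 1 || pending != "") {
        profis_abort("cannot pop attachment", "profis_invalid_smiles")
      }
      stack <- stack[-length(stack)]
    } else if (tok %in% names(bond_order)) {
      if (pending != "") profis_abort("double bond symbol", "profis_invalid_smiles")
      pending <- tok
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      size <- as.integer(sub("^%", "", tok))
      cur <- length(atoms)
      if (cur == 0) profis_abort("ring before atom", "profis_invalid_smiles")
      partner <- cur - size + 1L
      if (size < 3 || partner < 1) {
        profis_abort("ring size out of range", "profis_invalid_smiles")
      }
      dup <- any(vapply(bonds, function(b) {
        (b$i == partner && b$j == cur) || (b$i == cur && b$j == partner)
      }, logical(1)))
      if (dup) profis_abort("duplicate ring bond", "profis_invalid_smiles")
      ord <- if (pending != "") {
        bond_order[[pending]]
      } else if (atoms[[cur]]$arom && atoms[[partner]]$arom) -1 else 1
      bonds[[length(bonds) + 1]] <- list(i = partner, j = cur, order = ord)
      pending <- ""
    } else {
      profis_abort(paste0("unsupported token: ", tok), "profis_invalid_smiles")
    }
  }
  if (pending != "") profis_abort("dangling bond", "profis_invalid_smiles")
  if (length(atoms) == 0) profis_abort("no atoms", "profis_invalid_smiles")
  g <- list(
    atoms = tibble::tibble(
      elem = vapply(atoms, `[[`, character(1), "elem"),
      arom = vapply(atoms, `[[`, logical(1), "arom"),
      hcount = vapply(atoms, `[[`, integer(1), "hcount"),
      charge = vapply(atoms, `[[`, integer(1), "charge"),
      bracket = vapply(atoms, `[[`, logical(1), "bracket")
    ),
    bonds = if (length(bonds) == 0) {
      tibble::tibble(i = integer(0), j = integer(0), order = numeric(0))
    } else {
      tibble::tibble(
        i = vapply(bonds, function(b) as.integer(b$i), integer(1)),
        j = vapply(bonds, function(b) as.integer(b$j), integer(1)),
        order = vapply(bonds, function(b) as.numeric(b$order), numeric(1))
      )
    }
  )
  g <- kekulize(g)
  check_valence(g)
  graph_to_smiles(g)
}
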