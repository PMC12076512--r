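# In-package SMILES machinery: lexer, graph parser, kekulization, valence
# checking and a graph-to-SMILES writer.
#
# OpenBabel (the canonicalization backend) is deliberately permissive: it
# repairs unbalanced parentheses and accepts hypervalent atoms as radicals.
# Output-validity accounting for a generative model needs a strict arbiter,
# so parsing and valence/aromaticity checks are done here and OpenBabel is
# only consulted for canonical forms of molecules that pass.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# default valence ladders (neutral atoms); first value that accommodates the
# explicit bond order sum decides the implicit hydrogen count
VALENCE_LADDER <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

smi_lex <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) return(NULL) # unterminated bracket
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = ""))) {
        return(NULL)
      }
      toks <- c(toks, paste(chars[i:(i + 2)], collapse = ""))
      i <- i + 3
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1] %in% c("l", "r")) {
      two <- paste(chars[i:(i + 1)], collapse = "")
      if (two %in% c("Cl", "Br")) {
        toks <- c(toks, two)
        i <- i + 2
      } else {
        toks <- c(toks, ch)
        i <- i + 1
      }
    } else if (grepl("[A-Za-z0-9()=#:./\\\\+-]", ch)) {
      toks <- c(toks, ch)
      i <- i + 1
    } else {
      return(NULL)
    }
  }
  toks
}

parse_bracket_atom <- function(tok) {
  m <- regmatches(
    tok,
    regexec(
      "^\\[([0-9]+)?([A-Z][a-z]?|[bcnops])(@{1,2})?(H([0-9]+)?)?(\\+{1,2}|-{1,2}|[+-][0-9])?\\]$",
      tok
    )
  )[[1]]
  if (length(m) == 0) return(NULL)
  elem_raw <- m[3]
  arom <- elem_raw %in% AROMATIC_ELEMS
  elem <- if (arom) toupper(elem_raw) else elem_raw
  if (!elem %in% names(VALENCE_LADDER)) return(NULL)
  hcount <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
  charge <- 0L
  cg <- m[7]
  if (cg != "") {
    charge <- if (grepl("[0-9]", cg)) {
      as.integer(paste0(substr(cg, 1, 1), substr(cg, 2, 2)))
    } else {
      (nchar(cg)) * (if (substr(cg, 1, 1) == "+") 1L else -1L)
    }
  }
  list(elem = elem, arom = arom, hcount = hcount, charge = charge, bracket = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds an atom/bond table representation with aromatic bonds resolved to a
#' Kekule assignment. Signals a condition of class `profis_invalid_smiles`
#' for syntactic errors (unbalanced parentheses, unmatched ring bonds),
#' failed kekulization or valence violations.
#'
#' @param s a single SMILES string.
#' @return a list with elements `atoms` (tibble: `elem`, `arom`, `charge`,
#'   `hcount`, `bracket`) and `bonds` (tibble: `i`, `j`, `order`, `arom`).
#'   `hcount` is the explicit bracket hydrogen count; implicit hydrogens are
#'   obtained with [implicit_hydrogens()].
#' @seealso [smiles_valid()], [graph_to_smiles()]
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    profis_abort("SMILES must be a non-empty string", "profis_invalid_smiles")
  }
  toks <- smi_lex(s)
  if (is.null(toks)) {
    profis_abort(paste0("cannot lex SMILES: ", s), "profis_invalid_smiles")
  }
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pending <- ""
  stack <- integer(0)
  rings <- list() # digit -> list(atom, bond)
  bond_order <- c("-" = 1, "=" = 2, "#" = 3, "/" = 1, "\\" = 1, ":" = -1)

  add_atom <- function(at) {
    atoms[[length(atoms) + 1]] <<- at
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (pending == "") {
        if (atoms[[prev]]$arom && at$arom) -1 else 1
      } else {
        bond_order[[pending]]
      }
      bonds[[length(bonds) + 1]] <<- list(i = prev, j = idx, order = ord)
    }
    pending <<- ""
    prev <<- idx
  }

  for (tok in toks) {
    if (tok %in% ORGANIC_SUBSET) {
      add_atom(list(elem = tok, arom = FALSE, hcount = NA_integer_,
                    charge = 0L, bracket = FALSE))
    } else if (tok %in% c("c", "n", "o", "s", "p", "b")) {
      add_atom(list(elem = toupper(tok), arom = TRUE, hcount = NA_integer_,
                    charge = 0L, bracket = FALSE))
    } else if (startsWith(tok, "[")) {
      at <- parse_bracket_atom(tok)
      if (is.null(at)) {
        profis_abort(paste0("unsupported bracket atom: ", tok), "profis_invalid_smiles")
      }
      add_atom(at)
    } else if (tok %in% names(bond_order)) {
      if (pending != "" || is.na(prev)) {
        profis_abort("misplaced bond symbol", "profis_invalid_smiles")
      }
      pending <- tok
    } else if (tok == "(") {
      if (is.na(prev) || pending != "") {
        profis_abort("misplaced branch open", "profis_invalid_smiles")
      }
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0 || pending != "") {
        profis_abort("unbalanced parentheses", "profis_invalid_smiles")
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      if (is.na(prev)) {
        profis_abort("ring bond before any atom", "profis_invalid_smiles")
      }
      key <- sub("^%", "", tok)
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        if (op$atom == prev) {
          profis_abort("ring bond to self", "profis_invalid_smiles")
        }
        ord <- if (pending != "") bond_order[[pending]]
          else if (op$bond != "") bond_order[[op$bond]]
          else if (atoms[[op$atom]]$arom && atoms[[prev]]$arom) -1 else 1
        if (pending != "" && op$bond != "" && op$bond != pending) {
          profis_abort("conflicting ring bond orders", "profis_invalid_smiles")
        }
        dup <- any(vapply(bonds, function(b) {
          (b$i == op$atom && b$j == prev) || (b$i == prev && b$j == op$atom)
        }, logical(1)))
        if (dup) profis_abort("duplicate ring bond", "profis_invalid_smiles")
        bonds[[length(bonds) + 1]] <- list(i = op$atom, j = prev, order = ord)
        rings[[key]] <- NULL
        pending <- ""
      } else {
        rings[[key]] <- list(atom = prev, bond = pending)
        pending <- ""
      }
    } else if (tok == ".") {
      if (length(stack) > 0 || pending != "" || is.na(prev)) {
        profis_abort("misplaced fragment separator", "profis_invalid_smiles")
      }
      prev <- NA_integer_
    } else {
      profis_abort(paste0("unsupported SMILES token: ", tok), "profis_invalid_smiles")
    }
  }
  if (length(stack) > 0) profis_abort("unbalanced parentheses", "profis_invalid_smiles")
  if (length(rings) > 0) profis_abort("unmatched ring bond", "profis_invalid_smiles")
  if (pending != "") profis_abort("dangling bond symbol", "profis_invalid_smiles")
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
  g
}

# Resolve aromatic bonds (order -1) to alternating single/double bonds.
# An atom written aromatic must carry >= 2 aromatic bonds (ring membership);
# carbons need exactly one aromatic double bond, bare aromatic N may take one
# or none (pyridine vs pyrrole-type), and o/s/[nH]/charged-n take none.
# Kekulizability is decided by a backtracking matching; no Hueckel electron
# count is applied.
kekulize <- function(g) {
  ar_idx <- which(g$bonds$order == -1)
  ar_atoms <- which(g$atoms$arom)
  if (length(ar_idx) == 0) {
    if (length(ar_atoms) > 0) {
      profis_abort("aromatic atom outside an aromatic ring", "profis_invalid_smiles")
    }
    g$bonds$arom <- rep(FALSE, nrow(g$bonds))
    return(g)
  }
  ab <- g$bonds[ar_idx, ]
  n_ar_bonds <- table(factor(c(ab$i, ab$j), levels = seq_len(nrow(g$atoms))))
  if (any(n_ar_bonds[ar_atoms] < 2)) {
    profis_abort("aromatic atom outside an aromatic ring", "profis_invalid_smiles")
  }
  if (any(n_ar_bonds > 3)) {
    profis_abort("too many aromatic bonds at one atom", "profis_invalid_smiles")
  }

  needs <- function(k) { # 2 = must match, 1 = may match, 0 = must not
    a <- g$atoms[k, ]
    if (!a$arom) return(0)
    exo_double <- any(g$bonds$order == 2 &
      (g$bonds$i == k | g$bonds$j == k))
    if (a$elem == "C") {
      if (exo_double) 0 else 2
    } else if (a$elem == "N" || a$elem == "P") {
      if (a$charge > 0) 2
      else if (!is.na(a$hcount) && a$hcount > 0) 0
      else if (a$bracket) 0 # [n-] style
      else 1
    } else {
      0 # O, S
    }
  }
  req <- vapply(seq_len(nrow(g$atoms)), needs, numeric(1))

  adj <- lapply(seq_len(nrow(g$atoms)), function(k) integer(0))
  for (r in seq_len(nrow(ab))) {
    adj[[ab$i[r]]] <- c(adj[[ab$i[r]]], r)
    adj[[ab$j[r]]] <- c(adj[[ab$j[r]]], r)
  }
  matched <- integer(nrow(g$atoms)) # 0 = free, else bond row in ab
  must <- which(req == 2)
  assign_match <- function(pos) {
    if (pos > length(must)) return(TRUE)
    a <- must[pos]
    if (matched[a] > 0) return(assign_match(pos + 1))
    for (r in adj[[a]]) {
      b <- if (ab$i[r] == a) ab$j[r] else ab$i[r]
      if (matched[b] == 0 && req[b] >= 1) {
        matched[a] <<- r
        matched[b] <<- r
        if (assign_match(pos + 1)) return(TRUE)
        matched[a] <<- 0L
        matched[b] <<- 0L
      }
    }
    FALSE
  }
  if (!assign_match(1)) {
    profis_abort("aromatic system cannot be kekulized", "profis_invalid_smiles")
  }
  double_rows <- unique(matched[matched > 0])
  ord <- rep(1, nrow(ab))
  ord[double_rows] <- 2
  g$bonds$order[ar_idx] <- ord
  g$bonds$arom <- rep(FALSE, nrow(g$bonds))
  g$bonds$arom[ar_idx] <- TRUE
  g
}

bond_order_sums <- function(g) {
  s <- numeric(nrow(g$atoms))
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      s[g$bonds$i[r]] <- s[g$bonds$i[r]] + g$bonds$order[r]
      s[g$bonds$j[r]] <- s[g$bonds$j[r]] + g$bonds$order[r]
    }
  }
  s
}

max_allowed_valence <- function(elem, charge) {
  base <- max(VALENCE_LADDER[[elem]])
  if (elem == "N" && charge == 1) return(4)
  if (elem == "N" && charge == -1) return(2)
  if (elem == "O" && charge == 1) return(3)
  if (elem == "O" && charge == -1) return(1)
  if (elem == "C" && charge != 0) return(3)
  if (elem %in% c("F", "Cl", "Br", "I") && charge == -1) return(0)
  if (elem == "S" && charge == 1) return(5)
  base
}

check_valence <- function(g) {
  used <- bond_order_sums(g)
  for (k in seq_len(nrow(g$atoms))) {
    a <- g$atoms[k, ]
    tot <- used[k] + ifelse(is.na(a$hcount), 0, a$hcount)
    if (abs(a$charge) > 2) {
      profis_abort("unsupported formal charge", "profis_invalid_smiles")
    }
    if (tot > max_allowed_valence(a$elem, a$charge)) {
      profis_abort(
        paste0("valence violation at atom ", k, " (", a$elem, ")"),
        "profis_invalid_smiles"
      )
    }
  }
  invisible(g)
}

#' Implicit hydrogen counts for a parsed molecular graph
#'
#' Organic-subset atoms are filled to the smallest standard valence that
#' accommodates their explicit bonds; bracket atoms carry only their explicit
#' hydrogen count.
#'
#' @param g a graph from [parse_smiles()].
#' @return integer vector, one count per atom.
#' @export
implicit_hydrogens <- function(g) {
  used <- bond_order_sums(g)
  vapply(seq_len(nrow(g$atoms)), function(k) {
    a <- g$atoms[k, ]
    if (a$bracket) return(as.integer(a$hcount))
    ladder <- VALENCE_LADDER[[a$elem]]
    if (a$charge != 0) ladder <- max_allowed_valence(a$elem, a$charge)
    # aromatic atoms in a kekulized graph are handled like their Kekule form
    fit <- ladder[ladder >= used[k]]
    if (length(fit) == 0) return(0L)
    as.integer(round(fit[1] - used[k]))
  }, integer(1))
}

#' Strict SMILES validity check
#'
#' A string is valid when it lexes, parses to a connected-or-multifragment
#' graph with balanced parentheses and matched ring bonds, its aromatic
#' systems kekulize, and no atom exceeds its allowed valence. This is the
#' arbiter used for all output-validity accounting in the package.
#'
#' @param s character vector of SMILES strings.
#' @return logical vector.
#' @export
smiles_valid <- function(s) {
  vapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(FALSE)
    !inherits(try(parse_smiles(x), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

# ---- graph utilities ------------------------------------------------------

graph_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      adj[[g$bonds$i[r]]] <- c(adj[[g$bonds$i[r]]], r)
      adj[[g$bonds$j[r]]] <- c(adj[[g$bonds$j[r]]], r)
    }
  }
  adj
}

# rows of g$bonds that lie on a cycle (non-bridge edges)
ring_bond_rows <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ig <- igraph_from_graph(g)
  br <- igraph::bridges(ig)
  setdiff(seq_len(nrow(g$bonds)), as.integer(br))
}

igraph_from_graph <- function(g) {
  igraph::graph_from_edgelist(
    cbind(g$bonds$i, g$bonds$j),
    directed = FALSE
  ) + igraph::vertices(setdiff(seq_len(nrow(g$atoms)), c(g$bonds$i, g$bonds$j)))
}

ring_atom_indices <- function(g) {
  rr <- ring_bond_rows(g)
  sort(unique(c(g$bonds$i[rr], g$bonds$j[rr])))
}

#' Size of the largest smallest-ring in a molecule
#'
#' For every ring bond, the shortest cycle through that bond is found by a
#' breadth-first search with the bond removed; the maximum over ring bonds is
#' returned (0 for acyclic molecules). This matches the chemist's notion of
#' "maximum ring size" over the smallest set of smallest rings.
#'
#' @param smiles a single SMILES string.
#' @return integer ring size, 0 if acyclic.
#' @export
max_ring_size <- function(smiles) {
  g <- parse_smiles(smiles)
  rr <- ring_bond_rows(g)
  if (length(rr) == 0) return(0L)
  ig <- igraph_from_graph(g)
  sizes <- vapply(rr, function(r) {
    ig2 <- igraph::delete_edges(ig, r)
    d <- igraph::distances(ig2, v = g$bonds$i[r], to = g$bonds$j[r])
    if (is.infinite(d[1, 1])) return(NA_integer_)
    as.integer(d[1, 1] + 1)
  }, integer(1))
  max(sizes, na.rm = TRUE)
}

# number of aromatic rings = cycle rank of the aromatic-bond subgraph
aromatic_ring_count <- function(g) {
  ar <- which(g$bonds$arom %||% rep(FALSE, nrow(g$bonds)))
  if (length(ar) == 0) return(0L)
  sub <- igraph::graph_from_edgelist(
    cbind(g$bonds$i[ar], g$bonds$j[ar]), directed = FALSE
  )
  deg <- igraph::degree(sub)
  memb <- igraph::components(sub)$membership
  v_used <- sum(deg > 0)
  c_used <- length(unique(memb[deg > 0]))
  as.integer(length(ar) - v_used + c_used)
}

# ---- graph -> SMILES writer ----------------------------------------------

#' Write a molecular graph back to SMILES
#'
#' Depth-first traversal with ring-closure digits; aromatic atoms are written
#' lowercase and aromatic-aromatic bond symbols omitted, other bonds use
#' `=`/`#`. The output is not canonical; pass it through
#' [standardize_molecules()] or OpenBabel for a canonical form.
#'
#' @param g graph from [parse_smiles()] (or built programmatically with the
#'   same shape).
#' @return a SMILES string.
#' @export
graph_to_smiles <- function(g) {
  n <- nrow(g$atoms)
  adj <- graph_adjacency(g)
  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, max(1, nrow(g$bonds)))
  next_digit <- 1
  free_digits <- integer(0)

  alloc_digit <- function() {
    if (length(free_digits) > 0) {
      d <- free_digits[1]
      free_digits <<- free_digits[-1]
      d
    } else {
      d <- next_digit
      next_digit <<- next_digit + 1
      d
    }
  }
  digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)

  arom_flags <- g$bonds$arom %||% rep(FALSE, nrow(g$bonds))

  bond_char <- function(r) {
    if (nrow(g$bonds) == 0) return("")
    if (arom_flags[r]) return("")
    # non-aromatic bond between two aromatic atoms must be written explicitly
    o <- g$bonds$order[r]
    both_ar <- g$atoms$arom[g$bonds$i[r]] && g$atoms$arom[g$bonds$j[r]]
    if (o == 2) "=" else if (o == 3) "#" else if (both_ar) "-" else ""
  }

  atom_str <- function(k) {
    a <- g$atoms[k, ]
    sym <- if (a$arom) tolower(a$elem) else a$elem
    plain_ok <- !a$bracket && a$charge == 0 && a$elem %in% ORGANIC_SUBSET
    if (plain_ok) return(sym)
    h <- if (is.na(a$hcount)) 0L else a$hcount
    hs <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    cs <- if (a$charge == 0) "" else if (a$charge == 1) "+"
      else if (a$charge == -1) "-"
      else if (a$charge > 0) paste0("+", a$charge) else paste0("-", -a$charge)
    paste0("[", sym, hs, cs, "]")
  }

  # ring closure digits must be planned before writing: a first DFS discovers
  # back edges, a second emits the string.
  back_edges <- integer(0)
  visited2 <- rep(FALSE, n)
  plan <- function(k) {
    visited2[k] <<- TRUE
    for (r in adj[[k]]) {
      other <- if (g$bonds$i[r] == k) g$bonds$j[r] else g$bonds$i[r]
      if (!visited2[other]) {
        bond_used[r] <<- TRUE
        plan(other)
      } else if (!bond_used[r]) {
        bond_used[r] <<- TRUE
        back_edges <- c(back_edges, r)
        back_edges <<- back_edges
      }
    }
  }
  roots <- integer(0)
  for (k in seq_len(n)) {
    if (!visited2[k]) {
      roots <- c(roots, k)
      plan(k)
    }
  }

  # assign digits: each back edge opens at the earlier-visited endpoint in the
  # second (emitting) DFS. We emit digits at both endpoints as encountered.
  pending_digits <- vector("list", n)
  for (r in back_edges) {
    d <- alloc_digit()
    bc <- bond_char(r)
    for (k in c(g$bonds$i[r], g$bonds$j[r])) {
      pending_digits[[k]] <- c(pending_digits[[k]], list(list(digit = d, bond = bc)))
    }
  }
  # digits are preassigned (no reuse) to keep the writer simple
  next_digit <- 1
  free_digits <- integer(0)

  bond_used <- rep(FALSE, max(1, nrow(g$bonds)))
  visited <- rep(FALSE, n)
  emit2 <- character(0)
  dfs2 <- function(k) {
    visited[k] <<- TRUE
    s <- atom_str(k)
    for (pd in pending_digits[[k]]) {
      s <- paste0(s, pd$bond, digit_str(pd$digit))
    }
    children <- list()
    for (r in adj[[k]]) {
      if (bond_used[r]) next
      other <- if (g$bonds$i[r] == k) g$bonds$j[r] else g$bonds$i[r]
      if (visited[other]) next
      if (r %in% back_edges) next
      bond_used[r] <<- TRUE
      children[[length(children) + 1]] <- list(r = r, atom = other)
    }
    parts <- character(0)
    if (length(children) > 0) {
      for (idx in seq_along(children)) {
        ch <- children[[idx]]
        if (visited[ch$atom]) next
        sub <- paste0(bond_char(ch$r), dfs2(ch$atom))
        parts <- c(parts, sub)
      }
    }
    if (length(parts) == 0) return(s)
    if (length(parts) == 1) return(paste0(s, parts[1]))
    paste0(
      s,
      paste0(vapply(parts[-length(parts)], function(p) paste0("(", p, ")"),
                    character(1)), collapse = ""),
      parts[length(parts)]
    )
  }
  frags <- vapply(roots, function(rt) dfs2(rt), character(1))
  paste(frags, collapse = ".")
}

# ---- descriptors from the graph ------------------------------------------

#' Molecular descriptors computed from the bond graph
#'
#' Classic Lipinski-style counts: molecular weight (with implicit hydrogens),
#' hydrogen-bond donors (N/O bearing at least one H), acceptors (all N/O),
#' rotatable bonds (non-ring single bonds between non-terminal heavy atoms,
#' triple-bond-adjacent bonds excluded) and aromatic ring count.
#'
#' @param smiles character vector of SMILES.
#' @return tibble with one row per molecule: `smiles`, `mw`, `hbd`, `hba`,
#'   `rotb`, `arom_rings`, `heavy_atoms`, `max_ring`.
#' @export
graph_descriptors <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    g <- parse_smiles(s)
    hh <- implicit_hydrogens(g)
    mw <- sum(ATOMIC_MASS[g$atoms$elem]) + sum(hh) * ATOMIC_MASS[["H"]]
    is_no <- g$atoms$elem %in% c("N", "O")
    hbd <- sum(is_no & hh > 0)
    hba <- sum(is_no)
    rr <- ring_bond_rows(g)
    deg <- numeric(nrow(g$atoms))
    if (nrow(g$bonds) > 0) {
      for (r in seq_len(nrow(g$bonds))) {
        deg[g$bonds$i[r]] <- deg[g$bonds$i[r]] + 1
        deg[g$bonds$j[r]] <- deg[g$bonds$j[r]] + 1
      }
    }
    triple_atoms <- unique(c(
      g$bonds$i[g$bonds$order == 3], g$bonds$j[g$bonds$order == 3]
    ))
    rotb <- 0L
    if (nrow(g$bonds) > 0) {
      for (r in seq_len(nrow(g$bonds))) {
        if (r %in% rr) next
        if (g$bonds$order[r] != 1) next
        a <- g$bonds$i[r]; b <- g$bonds$j[r]
        if (deg[a] < 2 || deg[b] < 2) next
        if (a %in% triple_atoms || b %in% triple_atoms) next
        rotb <- rotb + 1L
      }
    }
    mr <- if (length(rr) == 0) 0L else max_ring_size(s)
    tibble::tibble(
      smiles = s, mw = mw, hbd = hbd, hba = hba, rotb = rotb,
      arom_rings = aromatic_ring_count(g),
      heavy_atoms = nrow(g$atoms), max_ring = mr
    )
  })
  dplyr::bind_rows(rows)
}
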