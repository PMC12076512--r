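# SELFIES-style notation: a self-referencing token stream whose derivation
# rules enforce valence constraints, so every token sequence decodes to a
# valid molecule (totality). Ring and branch sizes are carried by operand
# tokens overloaded as base-16 digits. Aromatic rings are represented in
# their Kekule form (alternating single/double bonds), as this dialect has
# no aromatic tokens.

SELFIES_MAXVAL <- c(C = 4, N = 3, O = 2, S = 6, P = 5,
                    F = 1, Cl = 1, Br = 1, I = 1)

# fixed overload order: operand tokens are read as hexadecimal digits via
# their position in this list (absent tokens read as 0)
SELFIES_OVERLOAD <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]",
  "[=C]", "[#C]", "[S]", "[P]"
)

selfies_token_info <- function(tok) {
  body <- sub("^\\[", "", sub("\\]$", "", tok))
  prefix <- 1L
  if (startsWith(body, "=")) { prefix <- 2L; body <- substring(body, 2) }
  if (startsWith(body, "#")) { prefix <- 3L; body <- substring(body, 2) }
  if (body %in% names(SELFIES_MAXVAL)) {
    return(list(kind = "atom", elem = body, order = prefix))
  }
  if (body %in% c("Branch1", "Branch2")) {
    return(list(kind = "branch", n_operands = as.integer(substring(body, 7)),
                order = prefix))
  }
  if (body %in% c("Ring1", "Ring2")) {
    return(list(kind = "ring", n_operands = as.integer(substring(body, 5)),
                order = prefix))
  }
  list(kind = "nop")
}

selfies_operand_value <- function(toks) {
  vals <- match(toks, SELFIES_OVERLOAD) - 1L
  vals[is.na(vals)] <- 0L
  v <- 0L
  for (x in vals) v <- v * 16L + x
  v
}

# derivation machine shared by the main chain and branches; st is an
# environment holding atoms/bonds/caps
selfies_derive <- function(st, toks, attach_from = NA_integer_,
                           attach_order = 1L) {
  cur <- attach_from
  pending_attach <- !is.na(attach_from)
  i <- 1
  n <- length(toks)
  while (i <= n) {
    info <- selfies_token_info(toks[i])
    if (info$kind == "atom") {
      if (length(st$caps) > 0 && !is.na(cur) && st$caps[cur] == 0) break
      new_idx <- length(st$elems) + 1L
      maxv <- SELFIES_MAXVAL[[info$elem]]
      if (is.na(cur)) {
        st$elems <- c(st$elems, info$elem)
        st$caps <- c(st$caps, maxv)
      } else {
        want <- if (pending_attach) max(attach_order, info$order) else info$order
        o <- min(want, st$caps[cur], maxv)
        if (o < 1) break
        st$elems <- c(st$elems, info$elem)
        st$caps <- c(st$caps, maxv - o)
        st$caps[cur] <- st$caps[cur] - o
        st$bonds[[length(st$bonds) + 1]] <- c(cur, new_idx, o)
      }
      pending_attach <- FALSE
      cur <- new_idx
      i <- i + 1
    } else if (info$kind == "branch") {
      ops <- i + seq_len(info$n_operands)
      if (max(ops, i) > n) break
      q <- selfies_operand_value(toks[ops])
      len <- q + 1L
      body <- ops[length(ops)] + seq_len(len)
      body <- body[body <= n]
      i <- ops[length(ops)] + len + 1
      if (is.na(cur) || st$caps[cur] <= 1 || length(body) == 0) next
      selfies_derive(st, toks[body], attach_from = cur,
                     attach_order = info$order)
    } else if (info$kind == "ring") {
      ops <- i + seq_len(info$n_operands)
      i <- if (length(ops) > 0) ops[length(ops)] + 1 else i + 1
      if (max(ops, 0) > n) break
      q <- selfies_operand_value(toks[ops])
      if (is.na(cur)) next
      partner <- cur - (q + 1L)
      if (partner < 1) next
      o <- min(info$order, st$caps[cur], st$caps[partner])
      if (o < 1) next
      dup <- any(vapply(st$bonds, function(b) {
        (b[1] == partner && b[2] == cur) || (b[1] == cur && b[2] == partner)
      }, logical(1)))
      if (dup) next
      st$bonds[[length(st$bonds) + 1]] <- c(partner, cur, o)
      st$caps[cur] <- st$caps[cur] - o
      st$caps[partner] <- st$caps[partner] - o
    } else {
      i <- i + 1
    }
  }
  invisible(st)
}

#' Decode a SELFIES-style token string to SMILES
#'
#' Decoding is total: bonds are capped to the remaining valence of both
#' partners, impossible branch/ring instructions are skipped, and the empty
#' derivation falls back to methane (`"C"`), so every token sequence yields
#' a valid molecule.
#'
#' @param s a single string of `[...]` tokens.
#' @return a SMILES string (Kekule form for rings).
#' @export
selfies_to_smiles <- function(s) {
  toks <- lex_selfies(s)
  if (is.null(toks)) {
    profis_abort("not a SELFIES token string", "profis_invalid_smiles")
  }
  st <- new.env(parent = emptyenv())
  st$elems <- character(0)
  st$caps <- numeric(0)
  st$bonds <- list()
  selfies_derive(st, toks)
  if (length(st$elems) == 0) return("C")
  g <- list(
    atoms = tibble::tibble(
      elem = st$elems, arom = FALSE, hcount = NA_integer_,
      charge = 0L, bracket = FALSE
    ),
    bonds = if (length(st$bonds) == 0) {
      tibble::tibble(i = integer(0), j = integer(0), order = numeric(0),
                     arom = logical(0))
    } else {
      m <- do.call(rbind, st$bonds)
      tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     order = as.numeric(m[, 3]), arom = FALSE)
    }
  )
  graph_to_smiles(g)
}

selfies_atom_token <- function(elem, order) {
  prefix <- c("", "=", "#")[order]
  paste0("[", prefix, elem, "]")
}

selfies_size_tokens <- function(q, n_operands) {
  digits <- integer(n_operands)
  for (k in rev(seq_len(n_operands))) {
    digits[k] <- q %% 16L
    q <- q %/% 16L
  }
  SELFIES_OVERLOAD[digits + 1L]
}

#' Encode valid SMILES as SELFIES-style tokens
#'
#' The kekulized molecular graph is walked depth-first; side branches become
#' `[BranchL]` blocks sized in tokens, ring-closure bonds become `[RingL]`
#' tokens referring back along the atom derivation order. Charged or
#' isotope-labeled molecules are not expressible in this dialect and signal
#' `profis_unconvertible`.
#'
#' @param s a single valid SMILES string.
#' @return the SELFIES token string.
#' @export
smiles_to_selfies <- function(s) {
  g <- parse_smiles(s)
  if (any(g$atoms$charge != 0)) {
    profis_abort("charged molecules are not expressible", "profis_unconvertible")
  }
  if (!all(g$atoms$elem %in% names(SELFIES_MAXVAL))) {
    profis_abort("element outside the SELFIES alphabet", "profis_unconvertible")
  }
  n <- nrow(g$atoms)
  adj <- graph_adjacency(g)
  # DFS order and tree/back classification
  visited <- rep(FALSE, n)
  dfs_pos <- integer(n)
  counter <- 0L
  back_edges <- integer(0)
  bond_seen <- rep(FALSE, max(1, nrow(g$bonds)))

  encode_atom <- function(k, incoming_order, via_branch) {
    visited[k] <<- TRUE
    counter <<- counter + 1L
    dfs_pos[k] <<- counter
    toks <- selfies_atom_token(
      g$atoms$elem[k],
      if (via_branch) 1L else incoming_order
    )
    # ring closures terminating at this atom (to already-visited atoms)
    for (r in adj[[k]]) {
      if (bond_seen[r]) next
      other <- if (g$bonds$i[r] == k) g$bonds$j[r] else g$bonds$i[r]
      if (visited[other]) {
        bond_seen[r] <<- TRUE
        q <- dfs_pos[k] - dfs_pos[other] - 1L
        if (q < 0) profis_abort("ring order error", "profis_internal")
        n_ops <- if (q < 16) 1L else if (q < 256) 2L else
          profis_abort("ring span too large", "profis_unconvertible")
        ring_tok <- paste0("[", c("", "=", "#")[g$bonds$order[r]],
                           "Ring", n_ops, "]")
        toks <- c(toks, ring_tok, selfies_size_tokens(q, n_ops))
      }
    }
    # children: discovered lazily, because recursing into one child can turn
    # a sibling bond into a ring closure (handled inside the subtree). The
    # branch-vs-chain decision is made after the fact: all but the last
    # subtree are wrapped in sized Branch blocks, the last continues the
    # chain with its bond prefix patched onto its first atom token.
    subs <- list()
    repeat {
      r_next <- NA_integer_
      for (r in adj[[k]]) {
        if (bond_seen[r]) next
        other <- if (g$bonds$i[r] == k) g$bonds$j[r] else g$bonds$i[r]
        if (!visited[other]) { r_next <- r; break }
      }
      if (is.na(r_next)) break
      bond_seen[r_next] <<- TRUE
      other <- if (g$bonds$i[r_next] == k) g$bonds$j[r_next] else g$bonds$i[r_next]
      ord <- as.integer(g$bonds$order[r_next])
      sub <- encode_atom(other, ord, TRUE)
      subs[[length(subs) + 1]] <- list(sub = sub, order = ord, elem = g$atoms$elem[other])
    }
    if (length(subs) > 0) {
      for (si in seq_along(subs)) {
        x <- subs[[si]]
        if (si < length(subs)) {
          q <- length(x$sub) - 1L
          n_ops <- if (q < 16) 1L else if (q < 256) 2L else
            profis_abort("branch too large", "profis_unconvertible")
          br <- paste0("[", c("", "=", "#")[x$order], "Branch", n_ops, "]")
          toks <- c(toks, br, selfies_size_tokens(q, n_ops), x$sub)
        } else {
          chain <- x$sub
          chain[1] <- selfies_atom_token(x$elem, x$order)
          toks <- c(toks, chain)
        }
      }
    }
    toks
  }

  roots <- integer(0)
  out <- character(0)
  for (k in seq_len(n)) {
    if (!visited[k]) {
      if (length(roots) > 0) {
        profis_abort("multi-fragment strings are not convertible",
                     "profis_unconvertible")
      }
      roots <- c(roots, k)
      out <- c(out, encode_atom(k, 1L, FALSE))
    }
  }
  paste(out, collapse = "")
}
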