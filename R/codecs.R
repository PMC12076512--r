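# Token vocabularies, fixed-length integer encoding of molecular notations,
# notation conversion dispatch and output-validity accounting.

#' Construct a token vocabulary
#'
#' Structure tokens are kept in the given order; the special tokens
#' `<pad>`, `<start>`, `<end>` occupy the first three indices so models can
#' rely on `pad = 1L`.
#'
#' @param tokens character vector of unique structure tokens.
#' @param notation `"smiles"`, `"deepsmiles"` or `"selfies"`.
#' @return an object of class `profis_vocab`.
#' @export
new_vocabulary <- function(tokens, notation) {
  notation <- match.arg(notation, c("smiles", "deepsmiles", "selfies"))
  if (anyDuplicated(tokens)) {
    profis_abort("vocabulary tokens must be unique", "profis_bad_vocab")
  }
  specials <- c(pad = "<pad>", start = "<start>", end = "<end>")
  full <- c(unname(specials), tokens)
  structure(
    list(
      notation = notation, tokens = tokens, specials = specials,
      full = full, index = setNames(seq_along(full), full),
      pad = 1L, start = 2L, end = 3L
    ),
    class = "profis_vocab"
  )
}

#' @export
print.profis_vocab <- function(x, ...) {
  cat("Token vocabulary (", x$notation, "): ", length(x$tokens),
      " structure tokens + ", length(x$specials), " specials\n", sep = "")
  invisible(x)
}

#' Load one of the packaged reference vocabularies
#'
#' The reference inventories hold 29 (SMILES), 46 (DeepSMILES) and
#' 28 (SELFIES) structure tokens; the three special tokens are recorded
#' separately in the file header.
#'
#' @param notation `"smiles"`, `"deepsmiles"` or `"selfies"`.
#' @return a `profis_vocab`.
#' @export
profis_vocabulary <- function(notation = c("smiles", "deepsmiles", "selfies")) {
  notation <- match.arg(notation)
  path <- system.file("extdata", paste0("vocab_", notation, ".txt"),
                      package = "profis", mustWork = TRUE)
  read_vocabulary(path)
}

#' Read a vocabulary file
#'
#' Format: `# notation: <name>` and `# specials: ...` header lines followed
#' by one structure token per line.
#'
#' @param path file path.
#' @return a `profis_vocab`.
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  # header lines are "# key: value"; a bare "#" line is the triple-bond token
  is_hdr <- grepl("^#\\s", lines)
  hdr <- lines[is_hdr]
  notation <- trimws(sub("^#\\s*notation:", "", hdr[grepl("notation:", hdr)]))
  toks <- lines[!is_hdr & nzchar(lines)]
  new_vocabulary(toks, notation)
}

#' Write a vocabulary file
#'
#' @param vocab a `profis_vocab`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c(
    paste0("# notation: ", vocab$notation),
    paste0("# specials: ", paste(vocab$specials, collapse = " ")),
    vocab$tokens
  ), path)
  invisible(path)
}

# notation-specific lexers ---------------------------------------------------

lex_deepsmiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars); toks <- character(0); i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) return(NULL)
      toks <- c(toks, paste(chars[i:j], collapse = "")); i <- j + 1
    } else if (ch == "%") {
      if (i + 2 > n) return(NULL)
      toks <- c(toks, paste(chars[i:(i + 2)], collapse = "")); i <- i + 3
    } else if (ch %in% c("C", "B") && i < n &&
               paste(chars[i:(i + 1)], collapse = "") %in% c("Cl", "Br")) {
      toks <- c(toks, paste(chars[i:(i + 1)], collapse = "")); i <- i + 2
    } else {
      toks <- c(toks, ch); i <- i + 1
    }
  }
  toks
}

lex_selfies <- function(s) {
  m <- gregexpr("\\[[^][]*\\]", s)[[1]]
  if (m[1] == -1) return(if (nzchar(s)) NULL else character(0))
  covered <- sum(attr(m, "match.length"))
  if (covered != nchar(s)) return(NULL)
  regmatches(s, gregexpr("\\[[^][]*\\]", s))[[1]]
}

notation_lexer <- function(notation) {
  switch(notation,
    smiles = smi_lex,
    deepsmiles = lex_deepsmiles,
    selfies = lex_selfies
  )
}

#' Build a vocabulary from a training corpus
#'
#' Lexes every string in its notation (two-character halogens and bracket
#' atoms are atomic tokens) and collects the unique tokens in order of first
#' appearance; by construction the corpus then tokenizes without
#' out-of-vocabulary errors.
#'
#' @param strings character vector in the given notation.
#' @param notation `"smiles"`, `"deepsmiles"` or `"selfies"`.
#' @return a `profis_vocab`.
#' @export
build_vocabulary <- function(strings, notation = "smiles") {
  lexer <- notation_lexer(notation)
  toks <- character(0)
  for (s in strings) {
    tk <- lexer(s)
    if (is.null(tk)) {
      profis_abort(paste0("cannot lex string in ", notation, ": ", s),
                   "profis_out_of_vocabulary")
    }
    toks <- c(toks, setdiff(tk, toks))
  }
  new_vocabulary(toks, notation)
}

#' Encode strings as fixed-length integer token sequences
#'
#' Greedy longest-match tokenization against the vocabulary, terminated by
#' the end marker and padded to `seq_len` positions. The start token is not
#' stored: the decoder prepends it internally for conditioning.
#'
#' @param strings character vector.
#' @param vocab a `profis_vocab`.
#' @param seq_len fixed sequence length (default 100).
#' @return integer matrix (`length(strings)` x `seq_len`), padded with the
#'   pad index after the end marker.
#' @export
tokenize_sequences <- function(strings, vocab, seq_len = 100) {
  lexer <- notation_lexer(vocab$notation)
  out <- matrix(vocab$pad, length(strings), seq_len)
  for (r in seq_along(strings)) {
    tk <- lexer(strings[r])
    if (is.null(tk)) {
      profis_abort(paste0("cannot lex: ", strings[r]), "profis_out_of_vocabulary")
    }
    idx <- vocab$index[tk]
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      profis_abort(
        paste0("out-of-vocabulary token '", tk[bad], "' at position ", bad,
               " in: ", strings[r]),
        "profis_out_of_vocabulary"
      )
    }
    if (length(idx) + 1 > seq_len) {
      profis_abort(paste0("string needs more than ", seq_len, " positions: ",
                          strings[r]), "profis_too_long")
    }
    out[r, seq_len(length(idx) + 1)] <- c(as.integer(idx), vocab$end)
  }
  out
}

#' Decode integer token sequences back to strings
#'
#' Reading stops at the end marker; start/pad tokens are dropped.
#'
#' @param indices integer matrix or vector of token indices.
#' @param vocab a `profis_vocab`.
#' @return character vector.
#' @export
detokenize_sequences <- function(indices, vocab) {
  if (is.null(dim(indices))) indices <- matrix(indices, nrow = 1)
  apply(indices, 1, function(row) {
    row <- row[row != vocab$pad & row != vocab$start]
    stop_at <- which(row == vocab$end)
    if (length(stop_at) > 0) row <- row[seq_len(stop_at[1] - 1)]
    paste(vocab$full[row], collapse = "")
  })
}

#' Convert a canonical SMILES string to another notation
#'
#' @param smiles character vector of valid SMILES.
#' @param target `"smiles"` (identity), `"deepsmiles"` or `"selfies"`.
#' @return character vector in the target notation.
#' @seealso [decode_notation()] for the inverse direction.
#' @export
convert_notation <- function(smiles, target = c("smiles", "deepsmiles", "selfies")) {
  target <- match.arg(target)
  switch(target,
    smiles = smiles,
    deepsmiles = vapply(smiles, smiles_to_deepsmiles, character(1), USE.NAMES = FALSE),
    selfies = vapply(smiles, smiles_to_selfies, character(1), USE.NAMES = FALSE)
  )
}

#' Decode a string in any supported notation to SMILES
#'
#' @param strings character vector.
#' @param notation the strings' notation.
#' @return character vector of SMILES; `NA` where decoding fails (SELFIES
#'   decoding is total and never fails).
#' @export
decode_notation <- function(strings, notation = c("smiles", "deepsmiles", "selfies")) {
  notation <- match.arg(notation)
  switch(notation,
    smiles = strings,
    deepsmiles = vapply(strings, function(s) {
      out <- try(deepsmiles_to_smiles(s), silent = TRUE)
      if (inherits(out, "try-error")) NA_character_ else out
    }, character(1), USE.NAMES = FALSE),
    selfies = vapply(strings, selfies_to_smiles, character(1), USE.NAMES = FALSE)
  )
}

#' Fraction of generated strings that are valid molecules
#'
#' Strings are first decoded from their notation to SMILES (failures count
#' as invalid) and then checked with the strict in-package validator
#' ([smiles_valid()]): parseable, kekulizable, valence-correct.
#'
#' @param strings character vector of model outputs.
#' @param notation their notation.
#' @return proportion in \[0, 1\].
#' @export
validity_rate <- function(strings, notation = "smiles") {
  if (length(strings) == 0) {
    profis_abort("validity of an empty set is undefined", "profis_empty_input")
  }
  smi <- decode_notation(strings, notation)
  mean(!is.na(smi) & smiles_valid(smi))
}
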