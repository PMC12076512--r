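# OpenBabel-backed operations (via ChemmineR/ChemmineOB): canonicalization,
# charge neutralization, physicochemical properties and SMARTS matching.
# Batched wherever possible; per-molecule titles keep input/output rows
# aligned even when OpenBabel drops unparseable lines.

ob_quiet <- function(expr) {
  # OpenBabel chatters on stderr for odd molecules; keep test output clean
  msg <- utils::capture.output(res <- suppressWarnings(suppressMessages(expr)),
                               type = "message")
  res
}

# canonical SMILES for a vector of inputs; NA where OpenBabel cannot parse.
# neutralize uses OpenBabel's charge-neutralization transformation; stereo is
# always stripped afterwards via the stereo-free canonical form.
ob_canonical <- function(smiles, neutralize = FALSE) {
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("m", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  opts <- if (neutralize) {
    data.frame(names = "neutralize", args = "")
  } else {
    data.frame(names = character(0), args = character(0))
  }
  out <- try(ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", src, options = opts)),
             silent = TRUE)
  res <- rep(NA_character_, length(smiles))
  if (inherits(out, "try-error")) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) >= 2) {
      k <- match(parts[2], ids)
      if (!is.na(k)) res[k] <- parts[1]
    }
  }
  # stereo stripping: reparse the canonical form without stereo markers
  has_stereo <- !is.na(res) & grepl("[@/\\\\]", res)
  if (any(has_stereo)) {
    stripped <- gsub("/|\\\\", "", res[has_stereo])
    stripped <- gsub("@{1,2}", "", stripped)
    res[has_stereo] <- ob_canonical(stripped, neutralize = FALSE)
  }
  res
}

# OBMol references for fast repeated SMARTS matching
ob_mol_refs <- function(smiles) {
  ob_quiet(ChemmineOB::forEachMol("SMI", paste(smiles, collapse = "\n"), identity))
}

# count of unique SMARTS matches per molecule (prebuilt refs)
ob_smarts_count <- function(mol_refs, smarts) {
  out <- try(ob_quiet(ChemmineOB::smartsSearch_OB(mol_refs, smarts)), silent = TRUE)
  if (inherits(out, "try-error")) {
    profis_abort(paste0("cannot parse SMARTS: ", smarts), "profis_bad_smarts")
  }
  as.numeric(out)
}

# MW / logP / TPSA via OpenBabel descriptors, one row per input SMILES
ob_properties <- function(smiles) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0), mw = numeric(0),
                          clogp = numeric(0), tpsa = numeric(0)))
  }
  sdf <- ob_quiet(ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles)))))
  pr <- ob_quiet(ChemmineR::propOB(sdf))
  tibble::tibble(
    smiles = smiles,
    mw = as.numeric(pr$MW),
    clogp = as.numeric(pr$logP),
    tpsa = as.numeric(pr$TPSA)
  )
}
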