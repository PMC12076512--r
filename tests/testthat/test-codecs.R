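test_that("reference vocabularies carry the expected structure-token counts", {
  expect_length(profis_vocabulary("smiles")$tokens, 29)
  expect_length(profis_vocabulary("selfies")$tokens, 28)
  expect_length(profis_vocabulary("deepsmiles")$tokens, 46)
  v <- profis_vocabulary("smiles")
  expect_identical(unname(v$specials), c("<pad>", "<start>", "<end>"))
  expect_equal(v$pad, 1L)
})

test_that("tokenization is a lossless round trip with correct padding", {
  v <- profis_vocabulary("smiles")
  s <- c("CCO", "ClCCl", "c1ccccc1CC(=O)O")
  m <- tokenize_sequences(s, v, 40)
  expect_equal(dim(m), c(3, 40))
  expect_identical(detokenize_sequences(m, v), s)
  # two-character halogens are atomic: Cl C Cl + end = 4 non-pad positions
  expect_equal(sum(m[2, ] != v$pad), 4)
  # everything after the end marker is pad
  for (r in 1:3) {
    e <- which(m[r, ] == v$end)
    expect_true(all(m[r, seq(e + 1, 40)] == v$pad))
  }
  expect_error(tokenize_sequences("CxQ", v), class = "profis_out_of_vocabulary")
  expect_error(tokenize_sequences(strrep("C", 50), v, seq_len = 20),
               class = "profis_too_long")
})

test_that("corpus-built vocabularies tokenize their corpus without OOV", {
  corp <- test_corpus()
  v <- build_vocabulary(corp$canonical_smiles, "smiles")
  m <- tokenize_sequences(corp$canonical_smiles, v, 100)
  expect_identical(detokenize_sequences(m, v), corp$canonical_smiles)
})

test_that("notation conversion round-trips through canonical SMILES", {
  corp <- test_corpus()
  smis <- corp$canonical_smiles
  for (target in c("deepsmiles", "selfies")) {
    conv <- convert_notation(smis, target)
    back <- decode_notation(conv, target)
    expect_identical(
      standardize_molecules(back)$canonical_smiles, smis,
      info = target
    )
  }
  expect_identical(convert_notation(smis, "smiles"), smis)
})

test_that("DeepSMILES conversion matches the known branch/ring rewrite", {
  expect_identical(smiles_to_deepsmiles("c1ccccc1"), "cccccc6")
  expect_identical(smiles_to_deepsmiles("CC(=O)Oc1ccccc1C(=O)O"),
                   "CC=O)Occcccc6C=O)O")
  expect_identical(smiles_to_deepsmiles("C(Br)(OC)F"), "CBr)OC))F")
  expect_error(deepsmiles_to_smiles("ccc6"), class = "profis_invalid_smiles")
})

test_that("random SELFIES token soup always decodes to valid molecules", {
  v <- profis_vocabulary("selfies")
  withr::with_seed(99, {
    rnd <- replicate(400, paste(
      sample(v$tokens, sample(3:80, 1), replace = TRUE), collapse = ""
    ))
  })
  smi <- decode_notation(rnd, "selfies")
  expect_false(anyNA(smi))
  expect_true(all(smiles_valid(smi)))
})

test_that("validity accounting counts broken strings in the denominator", {
  expect_equal(validity_rate(c("C((", "CCO"), "smiles"), 0.5)
  expect_equal(validity_rate(c("CCO", "c1ccccc1"), "smiles"), 1)
  expect_error(validity_rate(character(0)), class = "profis_empty_input")
})
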