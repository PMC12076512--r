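test_that("standardization strips stereo, neutralizes and keeps the largest fragment", {
  r <- standardize("C[C@H](N)C(=O)O")
  expect_false(grepl("@", r$canonical_smiles, fixed = TRUE))

  r2 <- standardize("[NH3+]CC(=O)[O-]")
  g <- parse_smiles(r2$canonical_smiles)
  expect_equal(sum(g$atoms$charge), 0)

  salt <- standardize("CC(=O)O.[Na+]")
  acid <- standardize("CC(=O)O")
  expect_identical(salt$canonical_smiles, acid$canonical_smiles)

  expect_error(standardize("not_a_molecule((("),
               class = "profis_invalid_molecule")
})

test_that("standardization is idempotent on a fixture corpus", {
  corp <- test_corpus()
  std <- standardize_molecules(corp$canonical_smiles)
  expect_identical(std$canonical_smiles, corp$canonical_smiles)
})

test_that("training filters enforce the MW window and rule-of-five", {
  # aspirin: MW ~180 < 200 forces rejection even with zero violations
  expect_false(passes_training_filters("CC(=O)Oc1ccccc1C(=O)O"))
  halo <- standardize("O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1")
  # MW 375.9, clogP ~4, HBD 1, HBA 3: inside the window, no violations
  expect_true(passes_training_filters(halo$canonical_smiles))
  # a long alkane ether chain in the MW window but clogP > 5 must fail
  expect_false(passes_training_filters("CCCCCCCCCCCCCCCCCCCC"))
})

test_that("Murcko scaffolds keep rings, linkers and multiply-bonded attachments", {
  expect_identical(murcko_scaffold("CCc1ccccc1"), "c1ccccc1")
  expect_identical(murcko_scaffold("CCCCO"), "")
  scaf <- murcko_scaffold("O=C(CCCN1CCCC1)c1ccccc1")
  # both rings, the three-carbon linker and the carbonyl oxygen survive
  g <- parse_smiles(scaf)
  expect_equal(nrow(g$atoms), 16)
  expect_true(any(g$atoms$elem == "O"))
  # scaffold of a scaffold is itself
  expect_identical(murcko_scaffold(scaf), scaf)
})

test_that("scaffold split keeps groups intact and honors the cap", {
  # 1000 singleton scaffolds: exactly 900/100
  df <- tibble::tibble(id = 1:1000, scaffold = paste0("s", 1:1000))
  sp <- scaffold_split(df, train_frac = 0.9, seed = 3)
  expect_equal(sum(sp$split == "train"), 900)
  expect_equal(sum(sp$split == "test"), 100)

  # one group holding everything overflows the cap and goes to test
  df1 <- tibble::tibble(id = 1:50, scaffold = "only")
  sp1 <- scaffold_split(df1, train_frac = 0.9, seed = 1)
  expect_true(all(sp1$split == "test"))

  # determinism and no scaffold leakage on a real corpus
  corp <- test_corpus()
  s1 <- scaffold_split(corp, train_frac = 0.8, seed = 7)
  s2 <- scaffold_split(corp, train_frac = 0.8, seed = 7)
  expect_identical(s1$split, s2$split)
  leak <- intersect(s1$scaffold[s1$split == "train"],
                    s1$scaffold[s1$split == "test"])
  expect_length(leak, 0)
  expect_lte(sum(s1$split == "train"), 0.8 * nrow(corp))
})

test_that("molecule files round-trip through the readers", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1"), tmp)
  df <- read_molecules(tmp)
  expect_identical(df$smiles, c("CCO", "c1ccccc1"))

  tmpc <- withr::local_tempfile(fileext = ".csv")
  write_molecules(tibble::tibble(smiles = "CCO", ki_nm = 50), tmpc)
  back <- read_molecules(tmpc)
  expect_equal(back$ki_nm, 50)
})
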