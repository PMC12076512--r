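test_that("the strict validator accepts correct SMILES and rejects broken ones", {
  good <- c(
    "CCO", "c1ccccc1", "C1CC1", "N#Cc1ccccc1", "c1cc2ccccc2[nH]1",
    "S(=O)(=O)(N)c1ccccc1", "[O-]C(=O)C[NH3+]", "CC(=O)Oc1ccccc1C(=O)O"
  )
  expect_true(all(smiles_valid(good)))

  bad <- c(
    "C((",          # unbalanced parenthesis
    "C1CC",         # unmatched ring bond
    "C(C)(C)(C)(C)C", # pentavalent carbon
    "CC)C", "C==C", "9CC", "[Xx]", "c1ccccc1c", "", "C..C"
  )
  expect_false(any(smiles_valid(bad)))
})

test_that("kekulization resolves aromatic rings and flags impossible ones", {
  g <- parse_smiles("c1ccccc1")
  expect_setequal(sort(g$bonds$order), c(1, 1, 1, 2, 2, 2))
  # pyridine and pyrrole kekulize; an aromatic atom off-ring does not
  expect_true(smiles_valid("c1ccncc1"))
  expect_true(smiles_valid("c1cc[nH]c1"))
  expect_false(smiles_valid("cC"))
})

test_that("the graph writer round-trips through canonicalization", {
  corp <- test_corpus()
  for (s in head(corp$canonical_smiles, 25)) {
    w <- graph_to_smiles(parse_smiles(s))
    expect_true(smiles_valid(w))
    expect_identical(standardize(w)$canonical_smiles, s)
  }
})

test_that("graph descriptors match hand-computed values", {
  d <- graph_descriptors(c("CCO", "c1ccccc1", "CCCCCC"))
  expect_equal(d$mw, c(46.069, 78.114, 86.178), tolerance = 1e-3)
  expect_equal(d$hbd, c(1, 0, 0))
  expect_equal(d$hba, c(1, 0, 0))
  expect_equal(d$arom_rings, c(0, 1, 0))
  expect_equal(max_ring_size("C1CCCCCCC1"), 8L)
  expect_equal(max_ring_size("c1ccc2ccccc2c1"), 6L)
  expect_equal(max_ring_size("CCO"), 0L)
})
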