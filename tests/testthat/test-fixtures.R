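test_that("the corpus generator emits valid, unique, standardized molecules", {
  corp <- make_corpus(80, seed = 7)
  expect_equal(nrow(corp), 80)
  expect_false(anyDuplicated(corp$canonical_smiles) > 0)
  expect_true(all(smiles_valid(corp$canonical_smiles)))
  expect_true(all(corp$mw >= 200 & corp$mw <= 450))
  # already standardized: neutral, stereo-free, canonical
  std <- standardize_molecules(corp$canonical_smiles)
  expect_identical(std$canonical_smiles, corp$canonical_smiles)
  # scaffold diversity
  expect_gt(length(unique(corp$scaffold)), 20)
  # every string tokenizes within the reference sequence length
  v <- build_vocabulary(corp$canonical_smiles, "smiles")
  expect_no_error(tokenize_sequences(corp$canonical_smiles, v, 100))
})

test_that("the corpus generator is deterministic in its seed", {
  a <- make_corpus(40, seed = 13)
  b <- make_corpus(40, seed = 13)
  expect_identical(a, b)
  c <- make_corpus(40, seed = 14)
  expect_false(identical(a$canonical_smiles, c$canonical_smiles))
})

test_that("an infeasible inventory is reported", {
  inv <- fixture_fragments()
  expect_error(
    make_corpus(10, seed = 1, inventory = inv, mw_range = c(5000, 6000),
                max_rounds = 3),
    class = "profis_infeasible_spec"
  )
})

test_that("the activity rule creates fingerprint-detectable signal", {
  act <- make_activity_dataset(120, seed = 3)
  expect_identical(act, make_activity_dataset(120, seed = 3))
  # labels track the pharmacophore under the default 3-log-unit effect
  tab <- table(act$activity, act$has_pharmacophore)
  expect_gt(sum(diag(tab[1:2, 2:1])) / sum(tab), 0.95)
  # a substructure-lookup oracle classifier separates held-out data
  oracle_p <- as.numeric(act$has_pharmacophore)
  y01 <- as.integer(act$activity == "active")
  auc <- suppressMessages(pROC::auc(pROC::roc(y01, oracle_p, quiet = TRUE)))
  expect_gte(as.numeric(auc), 0.95)
})

test_that("a zero effect size makes labels independent of the pharmacophore", {
  act <- make_activity_dataset(150, seed = 9, effect = 0, noise_sd = 1.5,
                               base_pki = 7)
  tab <- table(act$has_pharmacophore, act$activity == "active")
  # association no better than chance (chi-squared on the 2x2 table)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})
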