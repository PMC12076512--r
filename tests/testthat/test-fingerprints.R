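test_that("fingerprints have the contracted shapes and are deterministic", {
  smis <- head(test_corpus()$canonical_smiles, 5)
  fp <- compute_fingerprints(smis, "ecfp4", 512)
  expect_equal(dim(fp), c(5, 512))
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, compute_fingerprints(smis, "ecfp4", 512))

  kr <- compute_fingerprints(smis[1:2], "krfp")
  expect_equal(ncol(kr), 4860)
  # methane matches (almost) none of the substructure keys
  expect_lte(sum(compute_fingerprints("C", "krfp")), 5)
})

test_that("the substructure key set is fixed and well-formed", {
  keys <- krfp_keys()
  expect_length(keys, 4860)
  expect_false(anyDuplicated(keys) > 0)
})

test_that("Tanimoto distance is a bounded semimetric with the stated conventions", {
  a <- c(0L, 1L, 1L, 1L, 0L)
  b <- c(0L, 0L, 1L, 1L, 1L)
  expect_equal(tanimoto_distance(a, b), 0.5) # |and|=2, |or|=4
  expect_equal(tanimoto_distance(a, a), 0)
  expect_equal(tanimoto_distance(c(1L, 0L), c(0L, 1L)), 1)
  expect_equal(tanimoto_distance(integer(4), integer(4)), 0) # all-zero pair

  withr::with_seed(42, {
    for (i in 1:20) {
      x <- sample(0:1, 64, replace = TRUE)
      y <- sample(0:1, 64, replace = TRUE)
      d <- tanimoto_distance(x, y)
      expect_gte(d, 0); expect_lte(d, 1)
      expect_equal(d, tanimoto_distance(y, x))
      if (any(x != y)) expect_gt(tanimoto_distance(x, y), 0)
    }
  })

  expect_error(tanimoto_distance(c(1L, 0L), c(1L, 0L, 1L)),
               class = "profis_incompatible_fp")
})

test_that("bit flipping changes exactly k positions, reproducibly", {
  fp <- compute_fingerprints("CCO", "ecfp4", 256)[1, ]
  expect_identical(flip_bits(fp, 0, 1), fp)
  withr::with_seed(9, {
    for (k in c(1, 5, 17, 256)) {
      out <- flip_bits(fp, k, seed = k)
      expect_equal(sum(out != fp), k)
    }
  })
  expect_identical(flip_bits(fp, 256, 3), 1L - fp) # full complement
  expect_identical(flip_bits(fp, 5, 11), flip_bits(fp, 5, 11))
  expect_error(flip_bits(fp, 257, 1), class = "profis_invalid_argument")
})
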