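test_that("property profile matches closed-form descriptor cases", {
  p <- property_profile(c("CCO", "c1ccccc1", "CCCCCC"))
  expect_equal(p$hbd, c(1, 0, 0))
  expect_equal(p$hba, c(1, 0, 0))
  expect_equal(p$tpsa[2], 0)
  expect_equal(p$tpsa[3], 0)
  expect_true(all(p$qed >= 0 & p$qed <= 1))
  expect_true(all(p$descriptor_ok))
  summ <- attr(p, "summary")
  expect_true(all(c("property", "median") %in% names(summ)))
})

test_that("descriptor failures are flagged, not dropped", {
  p <- property_profile(c("CCO", "C(("))
  expect_equal(nrow(p), 2)
  expect_identical(p$descriptor_ok, c(TRUE, FALSE))
  expect_true(is.na(p$qed[2]))
})

test_that("QED rewards drug-like molecules over fragments and greases", {
  halo <- standardize("O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1")
  p <- property_profile(c(halo$canonical_smiles, "CCO",
                          "CCCCCCCCCCCCCCCCCCCCCCCCCC"))
  expect_gt(p$qed[1], 0.6)
  expect_gt(p$qed[1], p$qed[2])
  expect_gt(p$qed[1], p$qed[3])
})

test_that("scaffold novelty scores match a brute-force pairwise scan", {
  corp <- test_corpus()
  gen <- head(corp$canonical_smiles, 8)
  ref <- unique(corp$scaffold[40:60])
  ns <- scaffold_novelty(gen, ref, threshold = 0.25, nbits = 512)
  expect_equal(nrow(ns), 8)
  # brute force over the full reference set
  ref_nz <- unique(ref[nzchar(ref)])
  ref_fp <- compute_fingerprints(ref_nz, "ecfp4", 512)
  for (i in seq_len(8)) {
    if (ns$acyclic[i]) next
    fp <- compute_fingerprints(ns$scaffold[i], "ecfp4", 512)[1, ]
    brute <- min(vapply(seq_len(nrow(ref_fp)), function(j) {
      tanimoto_distance(fp, ref_fp[j, ])
    }, numeric(1)))
    expect_equal(ns$min_distance[i], brute, tolerance = 1e-12)
  }
  expect_identical(ns$novel, ns$min_distance >= 0.25)
})

test_that("a scaffold present in the reference set scores distance zero", {
  corp <- test_corpus()
  s <- corp$canonical_smiles[nzchar(corp$scaffold)][1]
  ns <- scaffold_novelty(s, corp$scaffold, nbits = 512)
  expect_equal(ns$min_distance, 0)
  expect_false(ns$novel)
})
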