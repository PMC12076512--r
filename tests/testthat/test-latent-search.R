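test_that("search bounds are mu +/- k*sigma with epsilon widening", {
  withr::with_seed(8, {
    z <- matrix(rnorm(10000 * 2), 10000, 2)
  })
  box <- compute_bounds(z, k = 2)
  expect_true(all(abs(box$low - (-2)) < 0.1))
  expect_true(all(abs(box$high - 2) < 0.1))

  # k = 0 collapses to the mean before widening
  box0 <- compute_bounds(z, k = 0, epsilon = 1e-3)
  expect_true(all(box0$high - box0$low <= 1e-3 + 1e-12))

  expect_warning(bc <- compute_bounds(matrix(1, 5, 2), k = 2))
  expect_true(all(bc$high > bc$low))
})

test_that("the Bayesian optimizer approaches the grid optimum on 2-D quadratics", {
  cc <- c(0.7, -0.5)
  obj <- function(z) -sum((z - cc)^2)
  box <- list(low = c(-2, -2), high = c(2, 2))
  # dense-grid oracle
  gr <- expand.grid(x = seq(-2, 2, length.out = 101),
                    y = seq(-2, 2, length.out = 101))
  gopt <- gr[which.max(-(gr$x - cc[1])^2 - (gr$y - cc[2])^2), ]
  for (s in 1:5) {
    bo <- bayesian_maximize(obj, box, init_points = 4, n_iter = 20, seed = s)
    expect_lt(sqrt(sum((bo$best_z - c(gopt$x, gopt$y))^2)), 0.5)
  }
})

test_that("probes stay inside the active box and its volume never grows", {
  obj <- function(z) -sum(z^2)
  box <- list(low = c(-3, -3), high = c(3, 3))
  bo <- bayesian_maximize(obj, box, init_points = 4, n_iter = 15,
                          domain_reduction = TRUE, seed = 2)
  for (i in seq_len(nrow(bo$probes))) {
    z <- bo$probes$z[[i]]
    expect_true(all(z >= bo$probes$box_low[[i]] - 1e-9))
    expect_true(all(z <= bo$probes$box_high[[i]] + 1e-9))
  }
  vols <- vapply(seq_len(nrow(bo$probes)), function(i) {
    prod(bo$probes$box_high[[i]] - bo$probes$box_low[[i]])
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
})

test_that("probe bookkeeping: counts, determinism, non-finite discard", {
  box <- list(low = -1, high = 1)
  bo <- bayesian_maximize(function(z) 1, box, init_points = 4, n_iter = 10,
                          seed = 1)
  expect_equal(nrow(bo$probes), 14)

  b1 <- bayesian_maximize(function(z) sum(z), box, seed = 5)
  b2 <- bayesian_maximize(function(z) sum(z), box, seed = 5)
  expect_identical(b1$probes$y, b2$probes$y)

  flaky <- function(z) if (z[1] > 0) NaN else -z[1]
  ws <- testthat::capture_warnings(
    bf <- bayesian_maximize(flaky, box, init_points = 4, n_iter = 5, seed = 3)
  )
  expect_true(any(grepl("non-finite", ws)))
  expect_lt(nrow(bf$probes), 9)
  expect_true(all(is.finite(bf$probes$y)))
})

test_that("drug-likeness filters apply the three predicates in order", {
  recs <- tibble::tibble(smiles = c(
    "C1CCCCCCC1",                  # 8-ring: rejected on ring size
    "CCCCCCCCCCCCCCCCCCCCCC",     # long alkane: QED fails
    standardize("O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1")$canonical_smiles
  ))
  out <- apply_druglikeness_filters(recs)
  expect_equal(out$smiles, recs$smiles[3])
  expect_true(all(c("qed", "clogp", "max_ring") %in% names(out)))
  # thresholds configurable: lax settings keep the 8-ring out, ring <= 8 lets it in
  out2 <- apply_druglikeness_filters(recs[1, ], qed_min = 0, max_ring = 8)
  expect_equal(nrow(out2), 1)
})
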