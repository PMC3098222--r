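test_that("mu_out = 0 yields a block-diagonal adjacency", {
  g <- generate_planted(planted_spec(c(4, 4), 3, 0, seed = 2))
  A <- g$network$A
  truth <- g$truth[rownames(A)]
  cross <- outer(truth, truth, "!=")
  expect_true(all(A[cross] == 0))
  expect_gt(sum(A[!cross]), 0)
})

test_that("the generator is a pure function of its spec", {
  spec <- planted_spec(c(6, 6), 2, 0.3, seed = 99, pair_fraction = 0.5)
  g1 <- generate_planted(spec)
  g2 <- generate_planted(spec)
  expect_identical(g1$network$A, g2$network$A)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$pairing, g2$pairing)
})

test_that("intra-cluster dyad weights have the requested mean", {
  spec <- planted_spec(c(10, 10), 2.0, 0.1, seed = 7)
  g <- generate_planted(spec)
  A <- g$network$A
  truth <- g$truth[rownames(A)]
  same <- outer(truth, truth, "==") & !diag(TRUE, nrow(A))
  x <- A[same]
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 2.0), 3 * se)
})

test_that("power-law weights respect the cap and skew heavy", {
  spec <- planted_spec(c(12, 12), 1.5, 0.1, weight_model = "powerlaw",
                       alpha = 2.2, cap = 20, seed = 5)
  g <- generate_planted(spec)
  A <- g$network$A
  expect_lte(max(A), 20 + 1 + 50)  # pair edges may add a Poisson bump
  nz <- A[A > 0]
  expect_gt(mean(nz == 1), mean(nz == 2))  # heavier mass at 1 than at 2
})

test_that("planted pairs share a cluster and satisfy pairing invariants", {
  g <- generate_planted(planted_spec(c(9, 9, 9), 3, 0.2, seed = 13,
                                     pair_fraction = 0.6))
  pr <- g$pairing
  expect_gt(nrow(pr), 0)
  expect_false(anyDuplicated(c(pr$a, pr$b)) > 0)
  expect_true(all(g$truth[pr$a] == g$truth[pr$b]))
  # reciprocal edge of weight >= 1 in both directions
  A <- g$network$A
  expect_true(all(A[cbind(pr$b, pr$a)] >= 1))
  expect_true(all(A[cbind(pr$a, pr$b)] >= 1))
  # names follow the L/R convention so inference recovers the pairing
  inferred <- infer_bilateral_pairs(g$network)
  expect_equal(nrow(inferred), nrow(pr))
})

test_that("impossible pairing specs error", {
  expect_error(generate_planted(planted_spec(c(1, 1), 2, 0, seed = 1,
                                             pair_fraction = 0.4)),
               "pair")
})

test_that("generated metadata covers positions, ganglia and types", {
  g <- generate_planted(planted_spec(c(10, 10), 2, 0.2, seed = 21))
  m <- g$network$meta
  expect_true(all(m$position >= 0 & m$position <= 1))
  expect_true(all(grepl("^G", m$ganglion)))
  expect_true(all(m$ntype %in% c("sensory", "inter", "motor", "poly")))
  # positions cluster around the planted centers
  mean1 <- mean(m$position[g$truth[m$name] == 1])
  mean2 <- mean(m$position[g$truth[m$name] == 2])
  expect_lt(mean1, mean2)
})

test_that("functional grouping interpolates from refinement to noise", {
  g <- generate_planted(planted_spec(c(20, 20, 20), 3, 0.2, seed = 4))
  sub <- names(g$truth)[1:40]
  g0 <- generate_functional_grouping(g$truth, 6, scramble = 0, seed = 1,
                                     subset = sub)
  g1 <- generate_functional_grouping(g$truth, 6, scramble = 1, seed = 1,
                                     subset = sub)
  v0 <- variation_of_information(g$truth[sub], g0)
  v1 <- variation_of_information(g$truth[sub], g1)
  expect_lt(v0, v1)
  # scramble = 0 is a refinement: knowing the grouping determines the
  # truth cluster, so H(truth | grouping) = 0 and VI = H(grouping | truth)
  tab <- table(g0, g$truth[sub])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("scrambled grouping approaches the random-pairing expectation", {
  g <- generate_planted(planted_spec(c(30, 30), 2, 0.3, seed = 6))
  sub <- names(g$truth)
  v_scr <- variation_of_information(
    g$truth[sub],
    generate_functional_grouping(g$truth, 4, scramble = 1, seed = 2,
                                 subset = sub))
  # Monte-Carlo oracle: VI of truly uniform labelings of the subset
  set.seed(33)
  v_mc <- replicate(200, {
    rnd <- stats::setNames(sample.int(4, length(sub), replace = TRUE), sub)
    variation_of_information(g$truth[sub], rnd)
  })
  expect_lt(abs(v_scr - mean(v_mc)), 4 * stats::sd(v_mc))
})

test_that("empty subset yields an empty grouping", {
  g <- generate_planted(planted_spec(c(5, 5), 2, 0.2, seed = 1))
  out <- generate_functional_grouping(g$truth, 3, scramble = 0.5,
                                      subset = character(0))
  expect_length(out, 0)
})
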