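test_that("within-module weight z-scores match the hand example", {
  # 3-node module with kappa = (4, 2, 0): chain a<->b (2 each way), b--c none
  conn <- tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                         type = "chemical", count = c(2, 2))
  meta <- tibble::tibble(name = c("a", "b", "c"))
  net <- as_connectome(conn, meta, quiet = TRUE)
  z <- within_module_weight(net, c(a = 1, b = 1, c = 1))
  expect_equal(z$kappa, c(4, 4, 0))
  # degenerate variant with distinct kappas: a->b 2, b->c 1
  conn2 <- tibble::tibble(source = c("a", "a"), target = c("b", "c"),
                          type = "chemical", count = c(3, 1))
  net2 <- as_connectome(conn2, meta, quiet = TRUE)
  z2 <- within_module_weight(net2, c(a = 1, b = 1, c = 1))
  expect_equal(z2$kappa, c(4, 3, 1))
  mu <- mean(c(4, 3, 1)); sdp <- sqrt(mean((c(4, 3, 1) - mu)^2))
  expect_equal(z2$z, (c(4, 3, 1) - mu) / sdp, tolerance = 1e-12)
})

test_that("Z is the population z-score of (4, 2, 0)", {
  kappa <- c(4, 2, 0)
  mu <- mean(kappa); sdp <- sqrt(mean((kappa - mu)^2))
  expect_equal(sdp, 1.632993, tolerance = 1e-6)
  expect_equal((kappa - mu) / sdp, c(1.224745, 0, -1.224745),
               tolerance = 1e-6)
})

test_that("uniform modules and singletons get Z = 0", {
  net <- four_node_net()
  z <- within_module_weight(net, c(a = 1, b = 1, c = 2, d = 2))
  expect_equal(z$z, rep(0, 4))  # equal kappas in each module
  zs <- within_module_weight(net, c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(zs$z, rep(0, 4))  # singleton modules
})

test_that("module Z vectors have mean 0 and population sd 1", {
  g <- generate_planted(planted_spec(c(10, 10), 3, 0.5, seed = 9))
  r <- anneal(g$network, seed = 1, schedule = fast_schedule())
  z <- within_module_weight(g$network, r$partition)
  for (cl in unique(z$cluster)) {
    v <- z$z[z$cluster == cl]
    if (stats::sd(v) > 0) {
      expect_equal(mean(v), 0, tolerance = 1e-10)
      expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-10)
    }
  }
})

test_that("participation coefficient matches the direct formula", {
  # node a sends 3 into cluster 2 and 1 into cluster 3
  conn <- tibble::tibble(source = c("a", "a"), target = c("b", "c"),
                         type = "chemical", count = c(3, 1))
  net <- as_connectome(conn, quiet = TRUE)
  p <- participation_coefficient(net, c(a = 1, b = 2, c = 3))
  expect_equal(p$p[p$name == "a"], 1 - (9 / 16 + 1 / 16), tolerance = 1e-12)

  # all weight inside one's own cluster -> P = 0
  net2 <- four_node_net()
  p2 <- participation_coefficient(net2, c(a = 1, b = 1, c = 2, d = 2))
  expect_equal(p2$p, rep(0, 4))

  # weight split equally across two clusters -> P = 0.5
  conn3 <- tibble::tibble(source = c("a", "a"), target = c("b", "c"),
                          type = "chemical", count = c(2, 2))
  net3 <- as_connectome(conn3, quiet = TRUE)
  p3 <- participation_coefficient(net3, c(a = 1, b = 2, c = 3))
  expect_equal(p3$p[p3$name == "a"], 0.5, tolerance = 1e-12)
})

test_that("P is bounded by 1 - 1/k and isolated nodes get 0", {
  g <- generate_planted(planted_spec(c(8, 8, 8), 3, 0.5, seed = 3))
  r <- anneal(g$network, seed = 2, schedule = fast_schedule())
  k <- length(unique(r$partition))
  p <- participation_coefficient(g$network, r$partition)
  expect_true(all(p$p >= 0 & p$p <= 1 - 1 / k + 1e-12))
})

test_that("role classification respects thresholds and boundaries", {
  expect_equal(classify_roles(0, 0), "R1")
  expect_equal(classify_roles(0.7, 0), "R3")
  expect_equal(classify_roles(0.5, 3), "R6")
  expect_equal(classify_roles(0.9, 0), "R4")
  expect_equal(classify_roles(0.1, 2.5), "R5")
  expect_equal(classify_roles(0.8, 3), "R7")
  # boundary values fall to the lower class
  expect_equal(classify_roles(0.05, 0), "R1")
  expect_equal(classify_roles(0.62, 0), "R2")
  expect_equal(classify_roles(0.30, 2.5), "R5")
  # every node gets exactly one role
  set.seed(5)
  roles <- classify_roles(runif(100), rnorm(100, 0, 2))
  expect_true(all(roles %in% paste0("R", 1:7)))
})

test_that("IQV matches its closed form and bounds", {
  expect_equal(iqv(rep("a", 10), levels = c("a", "b", "c")), 0)
  expect_equal(iqv(rep(c("a", "b", "c"), 4)), 1, tolerance = 1e-12)
  x <- c(rep("a", 18), "b", "c")  # proportions (0.9, 0.05, 0.05)
  expect_equal(iqv(x), 1.5 * (1 - (0.81 + 0.0025 + 0.0025)),
               tolerance = 1e-12)
  expect_equal(round(iqv(x), 4), 0.2775)
  expect_error(iqv(rep("a", 3)), "at least 2")
})

test_that("cluster composition uses the global category domain", {
  p <- c(a = 1, b = 1, c = 2, d = 2)
  attr_ <- c(a = "x", b = "x", c = "x", d = "y")
  cc <- cluster_composition(p, attr_)
  # cluster 1 is pure x but scored over domain {x, y} -> IQV 0
  expect_equal(cc$iqv$iqv[cc$iqv$cluster == 1], 0)
  expect_gt(cc$iqv$iqv[cc$iqv$cluster == 2], 0)
  expect_equal(sum(cc$composition$prop[cc$composition$cluster == 1]), 1)
  # missing values become "unknown"
  cc2 <- cluster_composition(p, c(a = "x", b = NA, c = "x", d = "y"))
  expect_true("unknown" %in% cc2$composition$category)
})

test_that("cartography joins Z, P and roles per node", {
  g <- generate_planted(planted_spec(c(10, 10), 3, 0.4, seed = 19))
  r <- anneal(g$network, seed = 3, schedule = fast_schedule())
  ct <- cartography(g$network, r$partition)
  expect_named(ct, c("name", "cluster", "kappa", "z", "p", "role"))
  expect_equal(nrow(ct), 20)
  expect_true(all(ct$role %in% paste0("R", 1:7)))
  expect_s3_class(plot_cartography(ct), "ggplot")
})
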