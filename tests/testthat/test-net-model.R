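test_that("single-edge bookkeeping follows the direction convention", {
  conn <- tibble::tibble(source = "a", target = "b",
                         type = "chemical", count = 3)
  net <- as_connectome(conn, quiet = TRUE)
  expect_equal(net$A["b", "a"], 3)
  expect_equal(net$A["a", "b"], 0)
  expect_equal(total_weight(net), 3)
  st <- strengths(net)
  expect_equal(st$s_out[st$name == "a"], 3)
  expect_equal(st$s_in[st$name == "b"], 3)
})

test_that("electrical junctions are symmetric and double the weight", {
  conn <- tibble::tibble(source = "a", target = "b",
                         type = "electrical", count = 2)
  net <- as_connectome(conn, quiet = TRUE)
  expect_equal(net$A["b", "a"], 2)
  expect_equal(net$A["a", "b"], 2)
  expect_equal(total_weight(net), 4)
})

test_that("total weight is chemical count plus twice electrical count", {
  conn <- tibble::tibble(
    source = c("a", "b", "a", "c"), target = c("b", "c", "c", "a"),
    type = c("chemical", "chemical", "electrical", "electrical"),
    count = c(5, 2, 3, 1))
  net <- as_connectome(conn, quiet = TRUE)
  expect_equal(total_weight(net), (5 + 2) + 2 * (3 + 1))
  expect_equal(net$n_chemical, 7)
  expect_equal(net$n_electrical, 4)
  expect_equal(sum(net$s_in), total_weight(net))
  expect_equal(sum(net$s_out), total_weight(net))
})

test_that("loader rejects bad rows and sums duplicates with a warning", {
  meta <- tibble::tibble(name = c("a", "b"))
  expect_error(
    as_connectome(tibble::tibble(source = "a", target = "z",
                                 type = "chemical", count = 1),
                  meta, quiet = TRUE),
    "absent from metadata")
  expect_error(
    as_connectome(tibble::tibble(source = "a", target = "b",
                                 type = "chemical", count = 0),
                  meta, quiet = TRUE),
    "non-positive count")
  expect_warning(
    net <- as_connectome(
      tibble::tibble(source = c("a", "a"), target = c("b", "b"),
                     type = "chemical", count = c(1, 2)),
      meta, quiet = TRUE),
    "summed")
  expect_equal(net$A["b", "a"], 3)
})

test_that("zero-strength nodes are retained and flagged isolated", {
  conn <- tibble::tibble(source = "a", target = "b",
                         type = "chemical", count = 1)
  meta <- tibble::tibble(name = c("a", "b", "c"))
  net <- as_connectome(conn, meta, quiet = TRUE)
  expect_equal(nrow(net$A), 3)
  expect_equal(net$meta$isolated, c(FALSE, FALSE, TRUE))
})

test_that("canonical TSV round trip reproduces the adjacency exactly", {
  g <- generate_planted(planted_spec(c(6, 5), 3, 0.5, seed = 11,
                                     pair_fraction = 0.4))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_wiring_tsv(g$network, cpath, mpath)
  back <- read_wiring_tsv(cpath, mpath, quiet = TRUE)
  expect_identical(back$A, g$network$A)
  expect_equal(total_weight(back), total_weight(g$network))
})

test_that("bilateral pair inference follows the terminal L/R rule", {
  p <- infer_bilateral_pairs(c("ALML", "ALMR", "AVM"))
  expect_equal(nrow(p), 1)
  expect_setequal(c(p$a, p$b), c("ALML", "ALMR"))

  p2 <- infer_bilateral_pairs(c("AVAL", "AVAR", "AVBL", "AVBR"))
  expect_equal(nrow(p2), 2)

  # involution-stable: inferring from the same names twice is identical
  nms <- c("AVAL", "AVAR", "RID", "PVML", "PVMR", "AQR")
  expect_identical(infer_bilateral_pairs(nms), infer_bilateral_pairs(nms))
})

test_that("pair overrides apply and unknown names are rejected", {
  nms <- c("XXL", "XXR", "YYL", "YYR")
  exc <- tibble::tibble(a = "XXL", b = "XXR", action = "unpair")
  p <- infer_bilateral_pairs(nms, exc)
  expect_equal(nrow(p), 1)
  expect_setequal(c(p$a, p$b), c("YYL", "YYR"))
  expect_error(
    infer_bilateral_pairs(nms, tibble::tibble(a = "ZZL", b = "ZZR",
                                              action = "pair")),
    "unknown")
})

test_that("pairing constructor enforces disjointness", {
  expect_error(bilateral_pairing(c("a", "a"), c("b", "c")), "disjoint")
  expect_error(bilateral_pairing("a", "a"), "twice")
})

test_that("wormatlas-style codes normalize to canonical rows", {
  raw <- tibble::tibble(
    Neuron1 = c("A", "B", "A", "B", "A", "C"),
    Neuron2 = c("B", "A", "B", "A", "M1", "A"),
    Type    = c("S", "R", "EJ", "EJ", "NMJ", "Sp"),
    Nbr     = c(4, 4, 2, 2, 7, 1))
  conv <- convert_neuron_connect(raw, drop = character())
  # R row dropped (reciprocal record), EJ kept once, NMJ excluded
  expect_equal(nrow(conv), 3)
  chem_ab <- conv[conv$type == "chemical" & conv$source == "A", ]
  expect_equal(chem_ab$count, 4)
  ej <- conv[conv$type == "electrical", ]
  expect_equal(nrow(ej), 1)
  expect_equal(ej$count, 2)
  net <- as_connectome(conv, quiet = TRUE)
  expect_equal(total_weight(net), 4 + 1 + 2 * 2)
})

test_that("the configurable drop-list removes neurons everywhere", {
  raw <- tibble::tibble(
    Neuron1 = c("A", "CANL"), Neuron2 = c("CANL", "A"),
    Type = c("S", "S"), Nbr = c(1, 1))
  conv <- convert_neuron_connect(raw)
  expect_equal(nrow(conv), 0)
})

test_that("strengths conserve the total on random networks", {
  for (s in 1:5) {
    net <- random_network(7, seed = s)
    st <- strengths(net)
    expect_equal(sum(st$s_in), total_weight(net))
    expect_equal(sum(st$s_out), total_weight(net))
  }
})
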