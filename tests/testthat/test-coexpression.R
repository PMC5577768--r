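test_that("seed correlations hit the closed-form anchors", {
  m <- rbind(seed = c(1, 2, 3, 4),
             same = c(1, 2, 3, 4),
             anti = -c(1, 2, 3, 4),
             bent = c(1, 2, 3, 10))
  colnames(m) <- paste0("e", 1:4)
  co <- correlateWithSeeds(m, "seed", minOverlap = 3)
  r <- setNames(co$r, co$partner_id)
  expect_equal(unname(r["seed"]), 1)
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["anti"]), -1)
  # direct formula, computed by hand arithmetic rather than cor()
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 10)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r["bent"]), hand)

  expect_error(correlateWithSeeds(m, "nosuch"), "nosuch")
  expect_error(correlateWithSeeds(m, "seed", minOverlap = 2), ">= 3")
})

test_that("pairwise-complete correlations match the naive double-loop oracle", {
  for (case in 1:200) {
    nr <- sample(3:10, 1)
    nc <- sample(4:10, 1)
    m <- random_fc_matrix(nr, nc, missing = runif(1, 0, 0.3), seed = case)
    co <- correlateWithSeeds(m, rownames(m)[1], minOverlap = 3)
    for (i in seq_len(nrow(co))) {
      oracle <- naive_pairwise_pearson(m[co$seed_id[i], ],
                                       m[co$partner_id[i], ])
      expect_equal(co$r[i], oracle, tolerance = 1e-12)
    }
  }
})

test_that("correlation is symmetric in the pair and bounded", {
  m <- random_fc_matrix(8, 9, missing = 0.2, seed = 42)
  co_ab <- correlateWithSeeds(m, "t01", minOverlap = 3)
  co_ba <- correlateWithSeeds(m, "t05", minOverlap = 3)
  r1 <- co_ab$r[co_ab$partner_id == "t05"]
  r2 <- co_ba$r[co_ba$partner_id == "t01"]
  expect_equal(r1, r2)
  expect_true(all(abs(co_ab$r) <= 1 + 1e-12))
})

test_that("low-overlap pairs are omitted and counted", {
  m <- random_fc_matrix(5, 8, seed = 3)
  m["t03", 1:6] <- NA   # only 2 co-observed with anything
  co <- correlateWithSeeds(m, "t01", minOverlap = 5)
  expect_false("t03" %in% co$partner_id)
  expect_equal(unname(attr(co, "skipped")["t01"]), 1L)
})

test_that("network thresholding follows the mode and stays deterministic", {
  co <- data.frame(seed_id = "s",
                   partner_id = c("a", "b", "c", "s"),
                   r = c(0.85, -0.85, 0.5, 1), n_pairs = 27L)
  signed <- buildNetwork(co, 0.8, "signed")
  expect_equal(nrow(networkEdges(signed)), 2L)
  positive <- buildNetwork(co, 0.8, "positive")
  expect_equal(networkEdges(positive)$partner_id, "a")
  # self-edge excluded in both
  expect_false("s" %in% networkEdges(signed)$partner_id)
  # deterministic ordering: by seed, then decreasing |r|, then partner
  co2 <- data.frame(seed_id = "s", partner_id = c("z", "y", "x"),
                    r = c(0.9, 0.9, 0.95), n_pairs = 27L)
  expect_equal(networkEdges(buildNetwork(co2))$partner_id, c("x", "y", "z"))
})

test_that("raising the threshold never adds edges", {
  m <- random_fc_matrix(40, 10, seed = 8)
  co <- correlateWithSeeds(m, c("t01", "t02"), minOverlap = 3)
  taus <- seq(0.3, 1, by = 0.1)
  sizes <- vapply(taus, function(t) nrow(networkEdges(buildNetwork(co, t))),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  edge_key <- function(t) {
    e <- networkEdges(buildNetwork(co, t))
    paste(e$seed_id, e$partner_id)
  }
  for (i in seq_len(length(taus) - 1))
    expect_true(all(edge_key(taus[i + 1]) %in% edge_key(taus[i])))
})

test_that("network exports round-trip across SIF, TSV and GraphML", {
  co <- data.frame(seed_id = "s", partner_id = c("a", "b"),
                   r = c(0.9, -0.82), n_pairs = c(25L, 20L))
  net <- buildNetwork(co)
  sif <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(lines, c("s\tcoexpressed\ta", "s\tcoexpressed\tb"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(back$r, networkEdges(net)$r)
  expect_equal(back$n_pairs, networkEdges(net)$n_pairs)

  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  ed <- igraph::as_data_frame(g, "edges")
  expect_setequal(round(ed$r, 6), round(networkEdges(net)$r, 6))

  # empty network -> empty SIF
  empty <- buildNetwork(co, threshold = 0.99)
  exportNetwork(empty, sif, "sif")
  expect_length(readLines(sif), 0)
})

test_that("hypergeometric enrichment agrees with exhaustive subset enumeration", {
  # spec'd anchor: universe 10, category 5, list 4, k = 4
  universe <- paste0("g", 1:10)
  annot <- list(cat = paste0("g", 1:5))
  members <- paste0("g", 1:4)
  res <- hypergeometricEnrichment(members, annot, universe)
  manual <- (choose(5, 4) * choose(5, 0)) / choose(10, 4)
  expect_equal(res$p, manual)
  expect_equal(res$p, enum_hyper_tail(10, 5, 4, 4))

  # random instances with N <= 12
  for (case in 1:25) {
    set.seed(case)
    N <- sample(5:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    universe <- paste0("g", 1:N)
    annot <- list(c1 = paste0("g", 1:K))
    members <- sample(universe, n)
    res <- hypergeometricEnrichment(members, annot, universe)
    k <- sum(members %in% annot$c1)
    expect_equal(res$p, enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment degenerate cases and BH behave", {
  universe <- paste0("g", 1:8)
  annot <- list(all = universe, half = universe[1:4], none = "g999")
  # members = universe: every tested category has p = 1 (all draws taken)
  res <- hypergeometricEnrichment(universe, annot[1:2], universe)
  expect_true(all(res$p == 1))
  # k = 0 -> upper tail P(X >= 0) = 1
  res0 <- hypergeometricEnrichment(c("g5", "g6"), list(c1 = c("g1", "g2")),
                                   universe)
  expect_equal(res0$p, 1)
  # q-values monotone in p-rank and never below p
  set.seed(5)
  annot_many <- lapply(1:6, function(i) sample(universe, sample(2:5, 1)))
  names(annot_many) <- paste0("c", 1:6)
  res2 <- hypergeometricEnrichment(c("g1", "g2", "g3"), annot_many, universe)
  expect_true(all(diff(res2$q) >= -1e-15))
  expect_true(all(res2$q >= res2$p - 1e-15))

  expect_error(hypergeometricEnrichment("g999", annot, universe), "g999")
})
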