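test_that("the majority rule is strict on both count and score", {
  expect_true(labelCombinationSynergistic(c(25, 30, 5)))
  expect_false(labelCombinationSynergistic(c(25, 5)))          # tie
  expect_false(labelCombinationSynergistic(c(19.9, 20.0, 20.1)))
  expect_error(labelCombinationSynergistic(numeric()), "without scores")
})

test_that("network construction matches per-combination labeling", {
  exps <- data.frame(
    combination = rep(c("C1", "C2"), each = 3),
    drugA = rep(c("DA", "DA"), each = 3),
    drugB = rep(c("DB", "DC"), each = 3),
    cellLine = rep(paste0("CL", 1:3), 2),
    synergy = c(25, 30, 5, 1, 2, 50))
  net <- buildSynergyNetwork(exps)
  expect_setequal(net@nodes, c("DA", "DB", "DC"))
  expect_equal(nrow(net@edges), 1L)
  expect_equal(unname(net@edges[1, ]), c("DA", "DB"))

  co <- smallCohort()
  net2 <- buildSynergyNetwork(co$experiments)
  byCombo <- split(co$experiments$synergy,
                   paste(co$experiments$drugA, co$experiments$drugB))
  expected <- sum(vapply(byCombo, function(s) sum(s > 20) > length(s) / 2,
                         logical(1)))
  expect_equal(nrow(net2@edges), expected)
})

test_that("proximity features reproduce the toy-graph values", {
  net <- toyNetwork()
  expect_equal(commonNeighbors(net, "A", "D"), 1)
  expect_equal(commonNeighbors(net, "A", "B"), 1)
  expect_equal(jaccardCoefficient(net, "A", "D"), 0.5)
  expect_equal(jaccardCoefficient(net, "A", "B"), 1 / 3)
  expect_equal(adamicAdar(net, "A", "D"), 1 / log(3), tolerance = 1e-12)
  expect_equal(adamicAdar(net, "B", "D"), 1 / log(3), tolerance = 1e-12)
  # isolated / unknown nodes
  empty <- new("SynergyNetwork", nodes = c("X", "Y"),
               edges = matrix(character(), 0, 2))
  expect_equal(commonNeighbors(empty, "X", "Y"), 0)
  expect_equal(jaccardCoefficient(empty, "X", "Y"), 0)
  expect_equal(adamicAdar(net, "A", "Z_unknown"), 0)
})

test_that("star-graph leaf pairs score 1/log(hub degree)", {
  for (k in c(3, 5, 8)) {
    leaves <- paste0("L", seq_len(k))
    net <- new("SynergyNetwork", nodes = c("H", leaves),
               edges = cbind(rep("H", k), leaves))  # "H" < "L*"
    expect_equal(adamicAdar(net, "L1", "L2"), 1 / log(k), tolerance = 1e-12)
    expect_equal(commonNeighbors(net, "L1", "L2"), 1)
  }
})

test_that("random 8-node networks match the brute-force oracle", {
  set.seed(99)
  nodes <- paste0("N", 1:8)
  allPairs <- t(combn(nodes, 2))
  for (rep in 1:100) {
    sel <- runif(nrow(allPairs)) < 0.3
    edges <- allPairs[sel, , drop = FALSE]
    net <- new("SynergyNetwork", nodes = nodes, edges = edges)
    idx <- sample(nrow(allPairs), 6)
    for (i in idx) {
      x <- allPairs[i, 1]; y <- allPairs[i, 2]
      expect_equal(commonNeighbors(net, x, y), bfCommonNeighbors(edges, x, y))
      expect_equal(jaccardCoefficient(net, x, y), bfJaccard(edges, x, y))
      expect_equal(adamicAdar(net, x, y), bfAdamicAdar(edges, x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("features are symmetric, bounded and monotone under edge addition", {
  set.seed(7)
  nodes <- paste0("N", 1:7)
  allPairs <- t(combn(nodes, 2))
  for (rep in 1:25) {
    edges <- allPairs[runif(21) < 0.35, , drop = FALSE]
    net <- new("SynergyNetwork", nodes = nodes, edges = edges)
    i <- sample(21, 1)
    x <- allPairs[i, 1]; y <- allPairs[i, 2]
    expect_equal(commonNeighbors(net, x, y), commonNeighbors(net, y, x))
    expect_equal(jaccardCoefficient(net, x, y),
                 jaccardCoefficient(net, y, x))
    expect_equal(adamicAdar(net, x, y), adamicAdar(net, y, x))
    expect_lte(jaccardCoefficient(net, x, y), 1)
    expect_lte(commonNeighbors(net, x, y),
               min(length(networkNeighbors(net, x)),
                   length(networkNeighbors(net, y))))
    # adding an edge from x to a new node never decreases common neighbors
    z <- setdiff(nodes, c(x, y))[1]
    pz <- synergyScreen:::canonicalPair(x, z)
    if (!any(edges[, 1] == pz[1] & edges[, 2] == pz[2])) {
      net2 <- new("SynergyNetwork", nodes = nodes,
                  edges = rbind(edges, pz))
      expect_gte(commonNeighbors(net2, x, y), commonNeighbors(net, x, y))
    }
  }
})

test_that("the leakage guard removes only the queried pair's own edge", {
  exps <- data.frame(
    combination = rep(c("C1", "C2", "C3"), each = 3),
    drugA = rep(c("DA", "DA", "DB"), each = 3),
    drugB = rep(c("DB", "DC", "DC"), each = 3),
    cellLine = rep(paste0("CL", 1:3), 3),
    synergy = rep(30, 9))  # every combination majority-synergistic
  guarded <- pairNetworkFeatures(exps, cbind("DA", "DB"))
  # with edge DA-DB removed, DC remains the only neighbor of both
  expect_equal(guarded$commonNeighbors, 1)
  expect_equal(guarded$jaccard, 1)
  whole <- pairNetworkFeatures(exps, cbind("DA", "DB"), wholeNetwork = TRUE)
  # on the full triangle the pair itself enters the neighbor union
  expect_equal(whole$commonNeighbors, 1)
  expect_equal(whole$jaccard, 1 / 3)
  # drugs unseen in training are isolated
  unseen <- pairNetworkFeatures(exps, cbind("DX", "DY"))
  expect_equal(unlist(unseen[, 3:5]), c(commonNeighbors = 0, jaccard = 0,
                                        adamicAdar = 0))
})
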