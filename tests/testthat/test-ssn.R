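test_that("buildSSN symmetrises, collapses to max bitscore and keeps isolates", {
  copies <- makeCopies(data.frame(genome_id = "g1",
                                  family = c("F1", "F1", "F1", "F2"),
                                  n = 1L, len = 600L))
  ids <- copies$copy_id
  hits <- rbind(makeHits(ids[1], ids[2], 200),
                makeHits(ids[2], ids[1], 180),   # reverse direction, lower
                makeHits(ids[1], ids[3], 50),
                makeHits(ids[1], ids[3], 90),    # repeated local alignment
                makeHits(ids[1], ids[3], 70))
  net <- buildSSN(hits, copies)
  g <- asIgraph(net)
  expect_equal(nodeCount(net), 4L)           # isolate retained
  expect_equal(edgeCount(net), 2L)
  w <- setNames(igraph::E(g)$weight,
                apply(igraph::ends(g, igraph::E(g)), 1,
                      function(e) paste(sort(e), collapse = "|")))
  expect_equal(unname(w[paste(sort(ids[1:2]), collapse = "|")]), 200)
  expect_equal(unname(w[paste(sort(ids[c(1, 3)]), collapse = "|")]), 90)
  expect_equal(igraph::degree(g)[ids[4]], c(setNames(0, ids[4])))

  # edge count never exceeds distinct unordered hit pairs
  expect_lte(edgeCount(net), 2L)
})

test_that("buildSSN applies length and e-value presets and rejects unknown ids", {
  copies <- makeCopies(data.frame(genome_id = "g1", family = c("L1a", "L1b"),
                                  n = 2L, len = c(400L, 600L)))
  ids <- copies$copy_id
  hits <- rbind(makeHits(ids[1], ids[2], 100, evalue = 1e-50),
                makeHits(ids[3], ids[4], 100, evalue = 1e-10))
  # L1-style preset: min length 500 bp, e-value ceiling 1e-30
  expect_message(net <- buildSSN(hits, copies, minCopyLength = 500,
                                 maxEvalue = 1e-30), "excluded")
  expect_equal(sort(igraph::V(asIgraph(net))$name), sort(ids[3:4]))
  expect_equal(edgeCount(net), 0L)  # surviving hit fails e-value ceiling

  expect_error(buildSSN(makeHits("ghost", ids[1], 50), copies),
               "unknown copy_id")
})

test_that("Louvain recovers planted cliques and is seed-deterministic", {
  # two 10-node cliques joined by one weak edge
  copies <- makeCopies(data.frame(genome_id = "g1", family = c("A", "B"),
                                  n = 10L, len = 500L))
  byFam <- split(copies$copy_id, copies$family)
  clique <- function(ids) {
    pr <- t(combn(ids, 2))
    makeHits(pr[, 1], pr[, 2], 100)
  }
  hits <- rbind(clique(byFam$A), clique(byFam$B),
                makeHits(byFam$A[1], byFam$B[1], 1))
  net <- buildSSN(hits, copies)
  part <- louvainPartition(net, seed = 0)
  memb <- clusterAssignments(part)
  expect_equal(nClusters(part), 2L)
  expect_equal(length(unique(memb[byFam$A])), 1L)
  expect_equal(length(unique(memb[byFam$B])), 1L)

  # the recovered bipartition beats the merged partition on modularity,
  # and no other bipartition of the nodes does better (exhaustive check
  # over the clique-respecting alternatives plus random bipartitions)
  g <- asIgraph(net)
  w <- igraph::E(g)$weight
  qRecovered <- igraph::modularity(g, memb, weights = w)
  qMerged <- igraph::modularity(g, setNames(rep(1, 20), names(memb))[
    igraph::V(g)$name], weights = w)
  expect_gt(qRecovered, qMerged)
  set.seed(5)
  for (r in 1:50) {
    alt <- setNames(sample(1:2, 20, replace = TRUE), igraph::V(g)$name)
    expect_gte(qRecovered, igraph::modularity(g, alt, weights = w) - 1e-12)
  }

  # determinism: same seed, same partition; runs are reproducible
  p2 <- louvainPartition(net, seed = 0)
  expect_identical(clusterAssignments(p2), memb)

  # edgeless network -> all singletons
  lone <- buildSSN(makeHits(character(), character(), numeric()),
                   makeCopies(data.frame(genome_id = "g1",
                                         family = paste0("s", 1:5),
                                         n = 1L, len = 500L)))
  pLone <- louvainPartition(lone, seed = 1)
  expect_equal(nClusters(pLone), 5L)
})

test_that("component partition matches the transitive-closure oracle", {
  set.seed(8)
  for (r in 1:5) {
    n <- 30
    copies <- makeCopies(data.frame(genome_id = "g1",
                                    family = paste0("f", seq_len(n)),
                                    n = 1L, len = 500L))
    ids <- copies$copy_id
    m <- sample(10:40, 1)
    edges <- data.frame(from = sample(ids, m, replace = TRUE),
                        to = sample(ids, m, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, ]
    net <- buildSSN(makeHits(edges$from, edges$to, 50), copies)
    part <- componentPartition(net)
    oracle <- componentsBrute(edges, ids)
    expect_equal(randIndex(clusterAssignments(part), oracle), 1)
    # every edge's endpoints share a cluster
    memb <- clusterAssignments(part)
    expect_true(all(memb[edges$from] == memb[edges$to]))
  }

  # two disjoint triangles / one path
  copies <- makeCopies(data.frame(genome_id = "g1",
                                  family = paste0("f", 1:6), n = 1L,
                                  len = 500L))
  ids <- copies$copy_id
  tri <- function(v) makeHits(v[c(1, 2, 3)], v[c(2, 3, 1)], 10)
  net <- buildSSN(rbind(tri(ids[1:3]), tri(ids[4:6])), copies)
  expect_equal(nClusters(componentPartition(net)), 2L)
  path <- buildSSN(makeHits(ids[1:2], ids[2:3], 10), copies[1:3, ])
  expect_equal(nClusters(componentPartition(path)), 1L)
})

test_that("every Louvain cluster nests within one connected component", {
  sim <- plantedSSN(k = 6, m = 6, seed = 13, withinDensity = 0.6)
  net <- buildSSN(sim$hits, sim$copies)
  lv <- clusterAssignments(louvainPartition(net, seed = 0))
  cc <- clusterAssignments(componentPartition(net))
  for (cl in unique(lv))
    expect_equal(length(unique(cc[names(lv)[lv == cl]])), 1L)
})

test_that("connectivity comparison by flag detects planted degree contrast", {
  # flagged nodes form a clique of 20; unflagged are isolated
  copies <- makeCopies(data.frame(genome_id = "g1", family = c("hot", "cold"),
                                  n = c(20L, 10L), len = 500L))
  byFam <- split(copies$copy_id, copies$family)
  pr <- t(combn(byFam$hot, 2))
  net <- buildSSN(makeHits(pr[, 1], pr[, 2], 80), copies)
  net <- setNodeFlag(net, "has_dde3", byFam$hot)
  res <- connectivityByFlag(net, "has_dde3")
  expect_true(all(res$flagged == 19))
  expect_true(all(res$unflagged == 0))
  expect_lt(pValue(res$test), 0.05)

  # weighted variant uses strength
  resW <- connectivityByFlag(net, "has_dde3", weighted = TRUE)
  expect_true(all(resW$flagged == 19 * 80))

  # one empty group -> error
  netAll <- setNodeFlag(net, "has_dde3", copies$copy_id)
  expect_error(connectivityByFlag(netAll, "has_dde3"), "non-empty")
})

test_that("DDE3-boosted families show significantly higher connectivity", {
  sim <- plantedSSN(k = 6, m = 8, seed = 17, withinDensity = 0.35,
                    dde3Families = c("fam01", "fam02"))
  net <- buildSSN(sim$hits, sim$copies)
  net <- setNodeFlag(net, "has_dde3", sim$domains$copy_id)
  res <- connectivityByFlag(net, "has_dde3")
  expect_lt(pValue(res$test), 0.01)
  expect_gt(mean(res$flagged), mean(res$unflagged))
})

test_that("cluster composition tallies subfamilies and flags mixtures", {
  copies <- makeCopies(data.frame(genome_id = c("cele", "cbre", "cele"),
                                  family = c("Tc1", "Fot1", "Mar2"),
                                  n = c(30L, 33L, 5L), len = 500L))
  byFam <- split(copies$copy_id, copies$family)
  memb <- setNames(c(rep(1L, 63), rep(2L, 5)),
                   c(byFam$Tc1, byFam$Fot1, byFam$Mar2))
  net <- buildSSN(makeHits(character(), character(), numeric()), copies)
  part <- new("Partition", membership = memb, method = "louvain",
              modularity = NA_real_)
  comp <- clusterComposition(net, part)
  expect_equal(comp$n_nodes, c(63L, 5L))          # sorted by size
  expect_equal(comp$n_subfamilies, c(2L, 1L))
  expect_equal(comp$mixed, c(TRUE, FALSE))
  expect_equal(comp$subfamilies[1], "Fot1=33;Tc1=30")
  expect_equal(comp$n_genomes, c(2L, 1L))

  # histogram of clusters by subfamily count matches brute-force recount
  fam <- setNames(copies$family, copies$copy_id)
  recount <- vapply(split(names(memb), memb),
                    function(v) length(unique(fam[v])), integer(1))
  expect_equal(sort(comp$n_subfamilies), sort(unname(recount)))
})

test_that("cryptic-hit enrichment reproduces proportions and Fisher p", {
  copies <- makeCopies(data.frame(genome_id = "cele",
                                  family = c("Tc1", "Other"),
                                  n = c(63L, 40L), len = 500L))
  byFam <- split(copies$copy_id, copies$family)
  net <- buildSSN(makeHits(character(), character(), numeric()), copies)
  flagged <- c(byFam$Tc1[1:53], byFam$Other[1:2])
  net <- setNodeFlag(net, "cryptic_hit", flagged)
  memb <- setNames(c(rep(1L, 63), rep(2L, 40)),
                   c(byFam$Tc1, byFam$Other))
  part <- new("Partition", membership = memb, method = "louvain",
              modularity = NA_real_)
  res <- crypticHitEnrichment(net, part, 1L)
  expect_equal(res$inCluster, 53 / 63)
  expect_equal(res$outside, 2 / 40)
  expect_equal(pValue(res$test), fisherBrute(res$table), tolerance = 1e-9)
  expect_lt(pValue(res$test), 0.001)
  expect_error(crypticHitEnrichment(net, part, 99L), "not in partition")

  # all nodes flagged -> both proportions 1, p = 1
  netAll <- setNodeFlag(net, "cryptic_hit", copies$copy_id)
  resAll <- crypticHitEnrichment(netAll, part, 1L)
  expect_equal(resAll$inCluster, 1)
  expect_equal(resAll$outside, 1)
  expect_equal(pValue(resAll$test), 1)
})

test_that("cluster persistence reports the best Jaccard overlap", {
  before <- new("Partition", membership = setNames(rep(1:2, each = 8),
                                                   sprintf("n%02d", 1:16)),
                method = "louvain", modularity = NA_real_)
  expect_equal(clusterPersistence(before, before, 1L)$overlap, 1)

  # split exactly in half -> best overlap 0.5
  halves <- setNames(c(rep(3L, 4), rep(4L, 4), rep(5L, 8)),
                     sprintf("n%02d", 1:16))
  after <- new("Partition", membership = halves, method = "louvain",
               modularity = NA_real_)
  res <- clusterPersistence(before, after, 1L)
  expect_equal(res$overlap, 0.5)
  expect_true(res$persists)

  # overlap equals brute-force maximum over candidate clusters
  members <- names(clusterAssignments(before))[
    clusterAssignments(before) == 1L]
  jac <- vapply(split(names(halves), halves), function(cand)
    length(intersect(members, cand)) / length(union(members, cand)),
    numeric(1))
  expect_equal(res$overlap, max(jac))
})

test_that("masking the convergent segment leaves the mixed cluster intact", {
  # with the convergent segment on, the two families co-cluster; removing
  # those hits (the masking analogue) splits them, but each family's own
  # cluster persists at Jaccard >= 0.5 of the original mixed cluster
  sim <- plantedSSN(k = 8, m = 8, seed = 23, withinDensity = 1,
                    convergentPair = c("fam01", "fam02"),
                    convergentDensity = 0.6)
  net <- buildSSN(sim$hits, sim$copies)
  pBefore <- louvainPartition(net, seed = 0)
  memb <- clusterAssignments(pBefore)
  fam <- setNames(sim$copies$family, sim$copies$copy_id)
  mixedId <- unique(memb[names(fam)[fam == "fam01"]])
  expect_length(mixedId, 1)

  simOff <- plantedSSN(k = 8, m = 8, seed = 23, withinDensity = 1)
  netOff <- buildSSN(simOff$hits, simOff$copies)
  pAfter <- louvainPartition(netOff, seed = 0)
  res <- clusterPersistence(pBefore, pAfter, mixedId)
  expect_true(res$persists)
  expect_equal(res$overlap, 0.5, tolerance = 1e-9)
})
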