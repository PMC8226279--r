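orthoFixture <- function() {
  spec <- data.frame(
    genome_id = c("g1", "g1", "g2", "g2", "g3"),
    family = c("FA", "FB", "FA", "FB", "FC"),
    n = c(2L, 1L, 1L, 1L, 1L),
    len = c(500L, 100L, 1000L, 100L, 100L))
  ot <- orthoTableFromPairs(data.frame(
    genome_a = c("g1", "g1", "g2"), genome_b = c("g2", "g3", "g3"),
    shared_orthogroups = c(8000, 4000, 2000)))
  list(copies = makeCopies(spec),
       annotations = makeAnnotations(c("g1", "g2", "g3")),
       ortho = ot)
}

test_that("orthonetwork weights implement the log-adjusted content metric", {
  fx <- orthoFixture()
  net <- buildOrthoNetwork(fx$copies, fx$ortho, fx$annotations,
                           threshold = 4500)
  g <- asIgraph(net)
  w <- function(a, b) igraph::E(g)$weight[igraph::get_edge_ids(g, c(a, b))]
  # totals: g1-FA 1000, g1-FB 100, g2-FA 1000, g2-FB 100, g3-FC 100
  # global max total = 1000 -> weight(g1,FA) = 1
  expect_equal(w("g1", "FA"), 1)
  expect_equal(w("g1", "FB"), log(100) / log(1000))
  # log-base invariance of the ratio
  expect_equal(log2(100) / log2(1000), log10(100) / log10(1000))
  expect_equal(w("g2", "FB"), log(100, base = 2) / log(1000, base = 2))

  # genome-genome edges: only the 8000 pair passes tau = 4500; weight 1
  expect_equal(w("g1", "g2"), 1)
  expect_equal(igraph::get_edge_ids(g, c("g1", "g3")), 0)
  ec <- igraph::E(g)$edgeClass
  expect_equal(sum(ec == "genome_genome"), 1L)
  # all normalised weights in (0, 1], max attained
  expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))
  expect_equal(max(igraph::E(g)$weight), 1)
})

test_that("raising the threshold never adds genome-genome edges", {
  land <- simulateLandscape(landscapeConfig(nSpecies = 16, nClades = 4,
                                            seed = 303))
  taus <- c(0, 2000, 4500, 8000, 1e9)
  counts <- vapply(taus, function(tau) {
    g <- asIgraph(buildOrthoNetwork(land$copies, land$orthoTable,
                                    land$annotations, threshold = tau))
    sum(igraph::E(g)$edgeClass == "genome_genome")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("orthonetwork rejects sub-log totals and missing pairs", {
  fx <- orthoFixture()
  tiny <- fx$copies
  tiny$end[5] <- tiny$start[5] + 1L
  tiny$length_bp[5] <- 1L
  expect_error(buildOrthoNetwork(tiny, fx$ortho, fx$annotations),
               "exceed 1 bp")

  ot <- orthoTableFromPairs(data.frame(
    genome_a = "g1", genome_b = "g2", shared_orthogroups = 8000))
  expect_error(buildOrthoNetwork(fx$copies, ot, fx$annotations),
               "no count|lacks genome")
})

test_that("per-family max scope normalises within families", {
  fx <- orthoFixture()
  net <- buildOrthoNetwork(fx$copies, fx$ortho, fx$annotations,
                           maxScope = "family")
  g <- asIgraph(net)
  w <- function(a, b) igraph::E(g)$weight[igraph::get_edge_ids(g, c(a, b))]
  # FB max total is 100 -> both FB edges get weight 1 under family scope
  expect_equal(w("g1", "FB"), 1)
  expect_equal(w("g2", "FB"), 1)
})

test_that("collapsing recovers planted clades and their group statistics", {
  land <- simulateLandscape(landscapeConfig(nSpecies = 20, nClades = 4,
                                            seed = 404))
  net <- buildOrthoNetwork(land$copies, land$orthoTable, land$annotations)
  groups <- collapseToGroups(net, seed = 0)
  # the four planted clades come back as four genome groups
  expect_equal(nrow(groups), 4L)
  truth <- land$truth$cladeOf
  recovered <- integer()
  for (i in seq_len(nrow(groups))) {
    members <- strsplit(groups$members[i], ";")[[1]]
    recovered[members] <- i
    expect_equal(groups$clade_agreement[i], 1)
  }
  expect_gte(randIndex(setNames(as.integer(factor(truth)), names(truth)),
                       recovered[names(truth)]), 0.95)

  # group degree / singletons recompute from the bipartite side
  cnet <- buildContentNetwork(land$copies, land$annotations, "total_bp")
  st <- genomeStatistics(cnet)
  for (i in seq_len(nrow(groups))) {
    members <- strsplit(groups$members[i], ";")[[1]]
    fams <- unique(land$copies$family[land$copies$genome_id %in% members])
    expect_equal(groups$degree[i], length(fams))
    onlyHere <- vapply(fams, function(f) {
      all(land$copies$genome_id[land$copies$family == f] %in% members)
    }, logical(1))
    expect_equal(groups$n_singletons[i], sum(onlyHere))
  }
})

test_that("a single-genome group reproduces that genome's bipartite statistics", {
  fx <- orthoFixture()
  # threshold excluding every pair -> Louvain keeps genomes with their own
  # TE families; g3 shares no family, so it forms a one-genome group
  net <- buildOrthoNetwork(fx$copies, fx$ortho, fx$annotations,
                           threshold = 1e9)
  groups <- collapseToGroups(net, seed = 0)
  g3row <- groups[groups$members == "g3", ]
  expect_equal(nrow(g3row), 1L)
  cnet <- buildContentNetwork(fx$copies, fx$annotations, "total_bp")
  st <- genomeStatistics(cnet)
  expect_equal(g3row$degree, st$degree[st$genome_id == "g3"])
  expect_equal(g3row$n_singletons, st$n_singletons[st$genome_id == "g3"])
})

test_that("group-level silencing comparison detects a clade-planted effect", {
  # clade-uniform piwi regime, strong richness contrast: the effect must
  # survive collapsing to one observation per clade group
  land <- simulateLandscape(landscapeConfig(
    nSpecies = 48, nClades = 12, famRatioPiwi = 3, copyRatioPiwi = 1 / 3,
    regimeByClade = TRUE, seed = 505))
  net <- buildOrthoNetwork(land$copies, land$orthoTable, land$annotations)
  groups <- collapseToGroups(net, seed = 0)
  expect_gte(nrow(groups), 8L)
  expect_true(all(groups$piwi_agreement == 1))
  res <- groupComparison(groups, "has_piwi", "degree")
  expect_lt(pValue(res$test), 0.05)
  expect_gt(mean(res$inGroup), mean(res$outGroup))

  # permuted labels give a calibrated null: no excess of small p-values
  set.seed(1)
  pNull <- replicate(40, {
    shuf <- groups
    shuf$has_piwi <- sample(shuf$has_piwi)
    pValue(groupComparison(shuf, "has_piwi", "degree")$test)
  })
  expect_lt(mean(pNull < 0.05), 0.25)

  # identical statistic values -> p = 1
  same <- data.frame(has_piwi = rep(c(TRUE, FALSE), each = 3),
                     degree = rep(7, 6))
  expect_equal(pValue(groupComparison(same, "has_piwi", "degree")$test), 1)
})
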