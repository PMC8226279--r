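contentFixture <- function() {
  # 3 genomes x 4 families with known abundances
  spec <- data.frame(
    genome_id = c("g1", "g1", "g1", "g2", "g2", "g3"),
    family = c("FA", "FB", "FC", "FA", "FB", "FA"),
    n = c(3L, 2L, 1L, 1L, 4L, 2L),
    len = c(100L, 50L, 200L, 300L, 100L, 150L))
  list(copies = makeCopies(spec),
       annotations = makeAnnotations(c("g1", "g2", "g3"),
                                     sizes = c(1e5L, 2e5L, 3e5L)))
}

test_that("content network edge weights implement the four abundance metrics", {
  fx <- contentFixture()
  w <- function(net, g, f) {
    gr <- asIgraph(net)
    e <- igraph::get_edge_ids(gr, c(g, f))
    if (e == 0) return(NA_real_)
    igraph::E(gr)$weight[e]
  }
  nc <- buildContentNetwork(fx$copies, fx$annotations, "count")
  expect_equal(w(nc, "g1", "FA"), 3)
  expect_equal(w(nc, "g2", "FB"), 4)

  nb <- buildContentNetwork(fx$copies, fx$annotations, "total_bp")
  expect_equal(w(nb, "g1", "FA"), 300)      # 3 x 100
  expect_equal(w(nb, "g1", "FB"), 100)      # 2 x 50
  expect_equal(w(nb, "g3", "FA"), 300)

  npg <- buildContentNetwork(fx$copies, fx$annotations, "pct_genome")
  expect_equal(w(npg, "g1", "FA"), 100 * 300 / 1e5)

  npt <- buildContentNetwork(fx$copies, fx$annotations, "pct_of_te")
  expect_equal(w(npt, "g1", "FC"), 100 * 200 / 600)
  # normalisation identity: per-genome pct_of_te weights sum to 100
  gr <- asIgraph(npt)
  for (g in c("g1", "g2", "g3"))
    expect_equal(sum(igraph::strength(gr)[g]), 100, tolerance = 1e-9)

  # families absent from a genome have no edge; network strictly bipartite
  expect_true(is.na(w(nb, "g3", "FB")))
  expect_error(buildContentNetwork(fx$copies, NULL, "pct_genome"),
               "genome_size")

  # changing only the metric never changes the node sets
  expect_setequal(igraph::V(asIgraph(nc))$name,
                  igraph::V(asIgraph(npt))$name)
})

test_that("genome statistics match a hand enumeration of the toy network", {
  fx <- contentFixture()
  net <- buildContentNetwork(fx$copies, fx$annotations, "total_bp")
  st <- genomeStatistics(net, fx$annotations)
  st <- st[order(st$genome_id), ]
  # degrees: g1 has FA,FB,FC; g2 has FA,FB; g3 has FA
  expect_equal(st$degree, c(3, 2, 1))
  # weighted degrees: sums of total_bp weights
  expect_equal(st$weighted_degree, c(300 + 100 + 200, 300 + 400, 300))
  # singletons: FC is only in g1; FA in all, FB in two
  expect_equal(st$n_singletons, c(1, 0, 0))
  # singleton conservation: sum over genomes = degree-1 TE nodes
  deg <- igraph::degree(asIgraph(net))
  teDeg <- deg[igraph::V(asIgraph(net))$nodeClass == "te"]
  expect_equal(sum(st$n_singletons), sum(teDeg == 1))
})

test_that("family summary equals a brute-force recount", {
  fx <- contentFixture()
  fs <- familySummary(fx$copies)
  # FA and FB both have 6 copies; the tie breaks alphabetically
  expect_equal(fs$family[1:2], c("FA", "FB"))
  expect_equal(fs$n_copies[1:2], c(6L, 6L))
  for (i in seq_len(nrow(fs))) {
    sel <- fx$copies[fx$copies$family == fs$family[i], ]
    expect_equal(fs$n_copies[i], nrow(sel))
    expect_equal(fs$total_bp[i], sum(sel$length_bp))
    expect_equal(fs$n_genomes[i], length(unique(sel$genome_id)))
  }
  expect_equal(nrow(familySummary(fx$copies[0, ])), 0L)
})

test_that("metric concordance is 1 for identical metrics and high for planted clades", {
  land <- simulateLandscape(landscapeConfig(nSpecies = 24, nClades = 3,
                                            seed = 101))
  expect_equal(metricConcordance(land$copies, land$annotations,
                                 "total_bp", "total_bp"), 1)
  ri <- metricConcordance(land$copies, land$annotations,
                          "total_bp", "pct_of_te")
  expect_gte(ri, 0.8)

  # degenerate two-genome case: rand index is a valid pair fraction
  two <- land$copies[land$copies$genome_id %in%
                     land$annotations$genome_id[1:2], ]
  ri2 <- metricConcordance(two, land$annotations, "count", "total_bp")
  expect_true(ri2 >= 0 && ri2 <= 1)
})

test_that("family knockout removes exactly the target's nodes", {
  fx <- contentFixture()
  net <- buildContentNetwork(fx$copies, fx$annotations, "total_bp")
  prof <- familyKnockout(net, "FA")
  d <- perturbationDelta(prof)
  expect_equal(unname(d["nodes"]), -1)        # one TE node named FA
  expect_equal(unname(d["edges"]), -3)        # FA present in all 3 genomes
  expect_error(familyKnockout(net, "nope"), "no TE node")

  # knockout equals the set-difference network rebuilt from filtered copies
  kept <- fx$copies[fx$copies$family != "FA", ]
  rebuilt <- buildContentNetwork(kept, fx$annotations, "total_bp")
  gAfter <- igraph::delete_vertices(asIgraph(net), "FA")
  expect_setequal(
    igraph::V(rebuilt@graph)$name,
    setdiff(igraph::V(gAfter)$name, "g3"))  # g3 loses its only family
  # edge sets and weights agree on the shared nodes
  eb <- igraph::as_data_frame(rebuilt@graph, what = "edges")
  ea <- igraph::as_data_frame(gAfter, what = "edges")
  key <- function(d) sprintf("%s|%s|%g", pmin(d$from, d$to),
                             pmax(d$from, d$to), d$weight)
  expect_setequal(key(eb), key(ea))
})

test_that("superfamily knockout and random partial knockout behave as planted", {
  # landscape with a pronounced node-count imbalance for one superfamily
  land <- simulateLandscape(landscapeConfig(nSpecies = 16, nClades = 2,
                                            dominantWeight = 8, seed = 202))
  net <- buildContentNetwork(land$copies, land$annotations, "total_bp")
  g <- asIgraph(net)
  sup <- igraph::V(g)$superfamily[igraph::V(g)$nodeClass == "te"]
  tab <- sort(table(sup), decreasing = TRUE)
  expect_equal(names(tab)[1], "Gypsy")       # planted dominant superfamily

  profiles <- lapply(names(tab), function(s) familyKnockout(net, s))
  dn <- vapply(profiles, function(p) -perturbationDelta(p)["nodes"],
               numeric(1))
  de <- vapply(profiles, function(p) -perturbationDelta(p)["edges"],
               numeric(1))
  # the dominant superfamily removes the most TE nodes and edges, and
  # perturbs the genome partition at least as much as a typical superfamily
  expect_equal(which.max(dn), 1L)
  expect_equal(which.max(de), 1L)
  rands <- vapply(profiles, function(p) p@genomeRand, numeric(1))
  expect_lte(rands[1], stats::median(rands) + 1e-9)

  # random 10% knockout: exact removal count per rep, gentler than full
  rk <- randomSubsetKnockout(net, "Gypsy", fraction = 0.10, reps = 5,
                             seed = 1)
  nG <- sum(sup == "Gypsy")
  for (p in rk$profiles)
    expect_equal(unname(perturbationDelta(p)["nodes"]), -floor(0.1 * nG))
  expect_lt(abs(rk$summary$mean[rk$summary$statistic == "nodes"]),
            abs(perturbationDelta(profiles[[1]])["nodes"]))
  expect_error(randomSubsetKnockout(net, "Gypsy", fraction = 1.0),
               "between 0 and 1")
})
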