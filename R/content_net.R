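## Bipartite genome-TE content network: genome nodes vs TE-family
## (consensus) nodes, edge weight = per-genome abundance of the family
## under one of four metrics. TE-family identity is the consensus/library
## name shared across genomes.

contentMetrics <- c("count", "total_bp", "pct_genome", "pct_of_te")

#' Build the bipartite genome-TE content network
#'
#' One genome node per species, one TE node per family; a genome-family
#' edge exists iff the family has at least one copy in that genome. The
#' edge weight is the chosen abundance metric:
#' \describe{
#'   \item{count}{number of copies of the family in the genome}
#'   \item{total_bp}{total length of those copies in bp (the "TE length"
#'     network, the default focus of the analyses)}
#'   \item{pct_genome}{total bp as a percentage of genome size}
#'   \item{pct_of_te}{total bp as a percentage of all TE bp in the genome}
#' }
#'
#' @param copies TE copy table.
#' @param annotations species annotation table; required for `pct_genome`
#'   (genome sizes) and to attach silencing-pathway attributes to genome
#'   nodes. May be `NULL` for the other metrics.
#' @param metric one of `"count"`, `"total_bp"`, `"pct_genome"`,
#'   `"pct_of_te"`.
#' @return a [ContentNetwork-class].
#' @export
buildContentNetwork <- function(copies, annotations = NULL,
                                metric = "total_bp") {
  metric <- match.arg(metric, contentMetrics)
  validateCopies(copies)
  if (metric == "pct_genome") {
    if (is.null(annotations))
      stop("pct_genome requires an annotation table with genome_size_bp")
    validateAnnotations(annotations, requireSize = TRUE)
  } else if (!is.null(annotations)) {
    validateAnnotations(annotations)
  }

  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(copies)), bp = copies$length_bp),
    by = list(genome_id = copies$genome_id, family = copies$family),
    FUN = sum)
  weight <- switch(metric,
    count = agg$n,
    total_bp = agg$bp,
    pct_genome = {
      sizes <- setNames(annotations$genome_size_bp, annotations$genome_id)
      miss <- setdiff(agg$genome_id, names(sizes))
      if (length(miss))
        stop("no genome size for: ", paste(miss, collapse = ", "))
      100 * agg$bp / sizes[agg$genome_id]
    },
    pct_of_te = {
      tot <- tapply(agg$bp, agg$genome_id, sum)
      100 * agg$bp / tot[agg$genome_id]
    })
  agg$weight <- as.numeric(weight)

  genomes <- sort(unique(copies$genome_id))
  famSuper <- vapply(split(copies$superfamily, copies$family),
                     function(x) names(sort(table(x), decreasing = TRUE))[1],
                     character(1))
  families <- sort(unique(copies$family))
  vertices <- data.frame(
    name = c(genomes, families),
    nodeClass = rep(c("genome", "te"), c(length(genomes), length(families))),
    type = rep(c(FALSE, TRUE), c(length(genomes), length(families))),
    superfamily = c(rep(NA_character_, length(genomes)),
                    unname(famSuper[families])),
    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(vertices$name, annotations$genome_id)
    vertices$clade_label <- annotations$clade_label[idx]
    vertices$has_dnmt <- annotations$has_dnmt[idx]
    vertices$has_piwi <- annotations$has_piwi[idx]
  }
  edges <- data.frame(from = agg$genome_id, to = agg$family,
                      weight = agg$weight, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  new("ContentNetwork", graph = g, metric = metric)
}

#' Concordance of two abundance metrics
#'
#' Builds the content network under two metrics from the same copies (node
#' sets are identical by construction; only weights differ), clusters each,
#' and returns the rand index between the genome-node partitions — the
#' check that the choice of abundance metric does not change the inferred
#' genome grouping.
#'
#' @param copies TE copy table.
#' @param annotations species annotation table (may be `NULL` unless a
#'   percentage metric is requested).
#' @param metricA,metricB metric tags.
#' @param method `"louvain"` (default) or `"components"`.
#' @param resolution,seed passed to [louvainPartition()].
#' @return rand index of the genome partitions, in \[0, 1\].
#' @export
metricConcordance <- function(copies, annotations = NULL,
                              metricA = "total_bp", metricB = "pct_of_te",
                              method = "louvain", resolution = 1, seed = 0) {
  netA <- buildContentNetwork(copies, annotations, metricA)
  netB <- buildContentNetwork(copies, annotations, metricB)
  stopifnot(setequal(igraph::V(asIgraph(netA))$name,
                     igraph::V(asIgraph(netB))$name))
  part <- function(net) {
    if (method == "louvain") louvainPartition(net, resolution, seed)
    else componentPartition(net)
  }
  genomes <- genomeNodeIds(netA)
  pA <- clusterAssignments(part(netA))[genomes]
  pB <- clusterAssignments(part(netB))[genomes]
  randIndex(pA, pB)
}

genomeNodeIds <- function(net) {
  g <- asIgraph(net)
  igraph::V(g)$name[igraph::V(g)$nodeClass == "genome"]
}

teNodeIds <- function(net) {
  g <- asIgraph(net)
  igraph::V(g)$name[igraph::V(g)$nodeClass == "te"]
}

#' Per-genome degree, weighted degree and singleton count
#'
#' Degree counts the distinct TE families present in the genome; weighted
#' degree sums the incident edge weights under the network's metric;
#' `n_singletons` counts incident family nodes of total degree 1 — families
#' found in this genome and nowhere else.
#'
#' @param net a [ContentNetwork-class].
#' @param annotations optional annotation table merged onto the result (for
#'   [groupComparison()]).
#' @return data.frame with one row per genome: `genome_id`, `degree`,
#'   `weighted_degree`, `n_singletons` (+ annotation columns if given).
#' @export
genomeStatistics <- function(net, annotations = NULL) {
  g <- asIgraph(net)
  genomes <- genomeNodeIds(net)
  deg <- igraph::degree(g)
  stren <- igraph::strength(g)
  out <- data.frame(genome_id = genomes,
                    degree = unname(deg[genomes]),
                    weighted_degree = unname(stren[genomes]),
                    stringsAsFactors = FALSE)
  out$n_singletons <- vapply(genomes, function(v) {
    nb <- igraph::neighbors(g, v)
    sum(deg[nb$name] == 1)
  }, numeric(1))
  if (!is.null(annotations)) {
    validateAnnotations(annotations)
    idx <- match(out$genome_id, annotations$genome_id)
    if (anyNA(idx))
      stop("annotations missing for: ",
           paste(out$genome_id[is.na(idx)], collapse = ", "))
    out <- cbind(out, annotations[idx, setdiff(names(annotations),
                                               "genome_id"), drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Per-family summary across the network
#'
#' @param copies TE copy table.
#' @return data.frame sorted by decreasing copy count: `family`,
#'   `superfamily`, `n_copies`, `total_bp`, `n_genomes`.
#' @export
familySummary <- function(copies) {
  validateCopies(copies)
  if (!nrow(copies))
    return(data.frame(family = character(), superfamily = character(),
                      n_copies = integer(), total_bp = integer(),
                      n_genomes = integer(), stringsAsFactors = FALSE))
  sp <- split(seq_len(nrow(copies)), copies$family)
  out <- do.call(rbind, lapply(names(sp), function(f) {
    i <- sp[[f]]
    data.frame(family = f,
               superfamily = names(sort(table(copies$superfamily[i]),
                                        decreasing = TRUE))[1],
               n_copies = length(i),
               total_bp = sum(copies$length_bp[i]),
               n_genomes = length(unique(copies$genome_id[i])),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_copies, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

networkProfile <- function(g, resolution = 1, seed = 0) {
  part <- louvainPartition(g, resolution, seed)
  c(nodes = igraph::gorder(g), edges = igraph::gsize(g),
    n_clusters = nClusters(part),
    modularity = if (is.na(part@modularity)) 0 else part@modularity,
    n_components = igraph::components(g)$no)
}

knockoutProfile <- function(net, teVictims, target, clusterSeed, resolution) {
  g <- asIgraph(net)
  gAfter <- igraph::delete_vertices(g, teVictims)
  before <- networkProfile(g, resolution, clusterSeed)
  after <- networkProfile(gAfter, resolution, clusterSeed)
  genomes <- genomeNodeIds(net)
  pB <- clusterAssignments(louvainPartition(g, resolution, clusterSeed))
  pA <- clusterAssignments(louvainPartition(gAfter, resolution, clusterSeed))
  new("PerturbationProfile", target = target, before = before,
      after = after, genomeRand = randIndex(pB[genomes], pA[genomes]))
}

#' Remove a TE family (or superfamily) from the network
#'
#' Deletes every TE node whose family name or superfamily matches the
#' target, recomputes the network statistics with identical clustering
#' parameters and seed, and reports before/after values together with the
#' rand index between the genome partitions of the baseline and perturbed
#' networks — the perturbation experiment used to rank the contribution of
#' each family to network structure.
#'
#' @param net a [ContentNetwork-class].
#' @param target family name or superfamily label.
#' @param clusterSeed,resolution Louvain parameters, applied identically
#'   before and after.
#' @return a [PerturbationProfile-class].
#' @export
familyKnockout <- function(net, target, clusterSeed = 0, resolution = 1) {
  g <- asIgraph(net)
  te <- igraph::V(g)$nodeClass == "te"
  victims <- igraph::V(g)$name[te & (igraph::V(g)$name == target |
                                     igraph::V(g)$superfamily %in% target)]
  if (!length(victims))
    stop("no TE node matches family or superfamily '", target, "'")
  knockoutProfile(net, victims, target, clusterSeed, resolution)
}

#' Repeated random partial knockout of a family
#'
#' Removes a random fraction (default 10%) of the target's TE nodes in each
#' of `reps` independent draws and profiles each perturbed network — the
#' control showing whether a family's influence comes from its node count
#' rather than its identity.
#'
#' @param net a [ContentNetwork-class].
#' @param target family or superfamily label.
#' @param fraction fraction of the target's nodes removed per rep, in (0,1).
#' @param reps number of independent draws.
#' @param seed RNG seed for the draws.
#' @param clusterSeed,resolution Louvain parameters.
#' @return list with `profiles` (list of [PerturbationProfile-class]) and
#'   `summary` (mean and sd of each delta statistic across reps).
#' @export
randomSubsetKnockout <- function(net, target, fraction = 0.10, reps = 10,
                                 seed = 0, clusterSeed = 0, resolution = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  g <- asIgraph(net)
  te <- igraph::V(g)$nodeClass == "te"
  pool <- igraph::V(g)$name[te & (igraph::V(g)$name == target |
                                  igraph::V(g)$superfamily %in% target)]
  k <- floor(fraction * length(pool))
  if (k < 1)
    stop("target has ", length(pool), " nodes; fraction ", fraction,
         " removes none")
  profiles <- withSeed(seed, lapply(seq_len(reps), function(r) {
    victims <- sample(pool, k)
    knockoutProfile(net, victims,
                    sprintf("%s (random %d/%d)", target, k, length(pool)),
                    clusterSeed, resolution)
  }))
  deltas <- do.call(rbind, lapply(profiles, perturbationDelta))
  list(profiles = profiles,
       summary = data.frame(statistic = colnames(deltas),
                            mean = colMeans(deltas),
                            sd = apply(deltas, 2, stats::sd),
                            row.names = NULL))
}
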