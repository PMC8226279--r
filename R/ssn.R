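## Monopartite TE sequence-similarity network: one node per annotated TE
## copy, one undirected edge per aligned copy pair, weighted by the best
## alignment bitscore over both directions and all local alignments.

#' Build a TE sequence-similarity network
#'
#' Nodes are TE copies; edges connect aligned pairs with weight equal to the
#' maximum bitscore over both hit directions and all local alignments of the
#' pair. Copies with no hits are retained as degree-0 nodes. Two optional
#' filters reproduce the retrotransposon preset used for dense superfamilies
#' such as human L1: a minimum copy length (500 bp there) and an e-value
#' ceiling (1e-30 there).
#'
#' @param hits alignment hit table (see [readAlignmentHits()]).
#' @param copies TE copy table (see [readRepeatMasker()]).
#' @param minCopyLength drop copies shorter than this many bp (default 0).
#' @param maxEvalue drop hits with larger e-value (default `NULL`, no filter).
#' @return a [SimilarityNetwork-class].
#' @export
buildSSN <- function(hits, copies, minCopyLength = 0, maxEvalue = NULL) {
  validateCopies(copies)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     copies$copy_id)
  if (length(unknown))
    stop("hits reference unknown copy_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) sprintf(" (and %d more)", length(unknown) - 5))

  keep <- copies$length_bp >= minCopyLength
  if (any(!keep))
    message("excluded ", sum(!keep), " copies shorter than ", minCopyLength,
            " bp")
  copies <- copies[keep, , drop = FALSE]

  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!is.null(maxEvalue)) {
    drop <- hits$evalue > maxEvalue
    if (any(drop))
      message("excluded ", sum(drop), " hits above e-value ", maxEvalue)
    hits <- hits[!drop, , drop = FALSE]
  }
  hits <- hits[hits$query_id %in% copies$copy_id &
               hits$subject_id %in% copies$copy_id, , drop = FALSE]

  if (nrow(hits)) {
    a <- pmin(hits$query_id, hits$subject_id)
    b <- pmax(hits$query_id, hits$subject_id)
    w <- tapply(hits$bitscore, paste(a, b, sep = "\r"), max)
    key <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(key, `[`, "", 1),
                        to = vapply(key, `[`, "", 2),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  vertices <- data.frame(name = copies$copy_id,
                         genome_id = copies$genome_id,
                         family = copies$family,
                         superfamily = copies$superfamily,
                         length_bp = copies$length_bp,
                         has_dde3 = FALSE, cryptic_hit = FALSE,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  new("SimilarityNetwork", graph = g)
}

#' Set a logical node flag on a network
#'
#' Marks the listed nodes `TRUE` for `flag` (e.g. `has_dde3` from a domain
#' search, or `cryptic_hit` from a protein-level search) and all others
#' `FALSE`.
#'
#' @param net a [SimilarityNetwork-class].
#' @param flag attribute name.
#' @param ids copy ids to flag.
#' @return the updated network.
#' @export
setNodeFlag <- function(net, flag, ids) {
  g <- asIgraph(net)
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing))
    warning(length(missing), " flagged id(s) not present in the network")
  val <- igraph::V(g)$name %in% ids
  g <- igraph::set_vertex_attr(g, flag, value = val)
  initialize(net, graph = g)
}

#' Louvain community detection
#'
#' Weighted modularity maximisation by the Louvain method at the given
#' resolution (the analyses here all use resolution 1, matching the
#' modularity statistic as usually run with edge weights and randomisation).
#' The algorithm visits nodes in random order; the `seed` pins that order so
#' a fixed seed gives an identical partition on identical input.
#'
#' @param net a network object (any of the three network classes) or igraph.
#' @param resolution modularity resolution parameter (default 1).
#' @param seed RNG seed (default 0).
#' @return a [Partition-class] with method `"louvain"` and the weighted
#'   modularity of the partition.
#' @export
louvainPartition <- function(net, resolution = 1, seed = 0) {
  g <- if (is(net, "TENetwork")) asIgraph(net) else net
  if (igraph::gorder(g) == 0)
    return(new("Partition", membership = setNames(integer(), character()),
               method = "louvain", modularity = NA_real_))
  w <- igraph::E(g)$weight
  comm <- withSeed(seed, igraph::cluster_louvain(g, weights = w,
                                                 resolution = resolution))
  memb <- igraph::membership(comm)
  mod <- igraph::modularity(g, memb, weights = w, resolution = resolution)
  new("Partition",
      membership = setNames(as.integer(memb), igraph::V(g)$name),
      method = "louvain", modularity = mod)
}

#' Connected-component clustering
#'
#' Clusters are the connected components of the network (depth-first
#' search), the second clustering statistic compared against Louvain.
#'
#' @param net a network object or igraph.
#' @return a [Partition-class] with method `"connected_components"`.
#' @export
componentPartition <- function(net) {
  g <- if (is(net, "TENetwork")) asIgraph(net) else net
  comp <- igraph::components(g)
  new("Partition",
      membership = setNames(as.integer(comp$membership), igraph::V(g)$name),
      method = "connected_components", modularity = NA_real_)
}

#' Degree comparison between flagged and unflagged nodes
#'
#' Splits nodes by a logical attribute (e.g. presence of the DDE3
#' transposase domain) and compares their connectivity with a two-sided
#' Wilcoxon rank-sum test. Connectivity is the unweighted degree by default;
#' `weighted = TRUE` uses the sum of incident bitscores instead.
#'
#' @param net a [SimilarityNetwork-class].
#' @param flag name of a logical node attribute.
#' @param weighted use weighted degree (strength)?
#' @return list with `flagged` and `unflagged` degree vectors and `test`,
#'   a [TestResult-class].
#' @export
connectivityByFlag <- function(net, flag, weighted = FALSE) {
  g <- asIgraph(net)
  val <- igraph::vertex_attr(g, flag)
  if (is.null(val) || anyNA(val))
    stop("flag '", flag, "' must be set on every node")
  val <- as.logical(val)
  if (!any(val) || all(val))
    stop("both flagged and unflagged groups must be non-empty")
  deg <- if (weighted) igraph::strength(g) else igraph::degree(g)
  flagged <- unname(deg[val]); unflagged <- unname(deg[!val])
  list(flagged = flagged, unflagged = unflagged,
       test = wilcoxonRankSum(flagged, unflagged))
}

#' Per-cluster composition table
#'
#' For each cluster of a partition: size, number of distinct subfamilies and
#' genomes, the subfamily breakdown, and a `mixed` flag marking clusters
#' that contain two or more subfamilies (candidate convergent-similarity or
#' misclassification events).
#'
#' @param net a [SimilarityNetwork-class].
#' @param partition a [Partition-class] over its nodes.
#' @return data.frame sorted by decreasing cluster size with columns
#'   `cluster_id`, `n_nodes`, `n_subfamilies`, `n_genomes`, `mixed`,
#'   `subfamilies` (e.g. `"Tc1=30;Fot1=33"`, by decreasing count).
#' @export
clusterComposition <- function(net, partition) {
  g <- asIgraph(net)
  memb <- clusterAssignments(partition)
  if (!setequal(names(memb), igraph::V(g)$name))
    stop("partition does not cover the network's node set")
  fam <- setNames(igraph::V(g)$family, igraph::V(g)$name)
  gen <- setNames(igraph::V(g)$genome_id, igraph::V(g)$name)
  ids <- names(memb)
  rows <- lapply(split(ids, memb), function(members) {
    tab <- sort(table(fam[members]), decreasing = TRUE)
    data.frame(n_nodes = length(members), n_subfamilies = length(tab),
               n_genomes = length(unique(gen[members])),
               mixed = length(tab) >= 2,
               subfamilies = paste(names(tab), as.integer(tab), sep = "=",
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(cluster_id = as.integer(names(rows)), out)
  out <- out[order(-out$n_nodes, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of a node flag within one cluster
#'
#' Compares the proportion of flagged nodes (e.g. copies whose best protein
#' hit is a cryptic host-gene sequence) inside a cluster against the rest of
#' the network, with a two-sided Fisher exact test.
#'
#' @param net a [SimilarityNetwork-class].
#' @param partition a [Partition-class].
#' @param clusterId cluster to test.
#' @param flag logical node attribute name (default `"cryptic_hit"`).
#' @return list with `inCluster` and `outside` proportions, the 2x2 `table`,
#'   and `test`, a [TestResult-class].
#' @export
crypticHitEnrichment <- function(net, partition, clusterId,
                                 flag = "cryptic_hit") {
  g <- asIgraph(net)
  memb <- clusterAssignments(partition)
  if (!clusterId %in% memb) stop("cluster ", clusterId, " not in partition")
  hit <- as.logical(igraph::vertex_attr(g, flag))
  if (is.null(hit) || anyNA(hit))
    stop("flag '", flag, "' must be set on every node")
  names(hit) <- igraph::V(g)$name
  inCl <- names(memb)[memb == clusterId]
  outCl <- setdiff(names(hit), inCl)
  tab <- matrix(c(sum(hit[inCl]), sum(!hit[inCl]),
                  sum(hit[outCl]), sum(!hit[outCl])), 2, 2,
                dimnames = list(c("hit", "no_hit"),
                                c("in_cluster", "outside")))
  list(inCluster = sum(hit[inCl]) / length(inCl),
       outside = if (length(outCl)) sum(hit[outCl]) / length(outCl) else NaN,
       table = tab,
       test = fisherExact2x2(tab))
}

#' Persistence of a cluster after a network rebuild
#'
#' After perturbing the input (e.g. masking the cryptic similarity segment)
#' and re-clustering, measures how well a named cluster survives: the best
#' Jaccard overlap between its original member set and any cluster of the
#' new partition. The cluster is reported as persisting when the best
#' overlap reaches `threshold` (default 0.5).
#'
#' @param partitionBefore,partitionAfter [Partition-class] objects; the two
#'   node sets need not be identical but must share the cluster's members.
#' @param clusterId cluster id in `partitionBefore`.
#' @param threshold Jaccard overlap above which the cluster is declared
#'   persistent.
#' @return list with `overlap` (best Jaccard), `bestMatch` (cluster id in
#'   the new partition) and `persists` (logical).
#' @export
clusterPersistence <- function(partitionBefore, partitionAfter, clusterId,
                               threshold = 0.5) {
  before <- clusterAssignments(partitionBefore)
  after <- clusterAssignments(partitionAfter)
  members <- names(before)[before == clusterId]
  if (!length(members)) stop("cluster ", clusterId, " not in partition")
  overlaps <- vapply(split(names(after), after), function(cand) {
    length(intersect(members, cand)) / length(union(members, cand))
  }, numeric(1))
  best <- which.max(overlaps)
  list(overlap = unname(overlaps[best]),
       bestMatch = as.integer(names(overlaps)[best]),
       persists = unname(overlaps[best]) >= threshold)
}
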