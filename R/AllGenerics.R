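#' Extract the underlying igraph object
#' @param x a `SimilarityNetwork`, `ContentNetwork` or `OrthoNetwork`.
#' @return an igraph object (a reference to the stored graph).
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Number of nodes in a network
#' @param x a network object.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' Number of edges in a network
#' @param x a network object.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Cluster assignments of a partition
#' @param x a `Partition`.
#' @return named integer vector mapping node id to cluster id.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' Number of clusters in a partition
#' @param x a `Partition`.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Method tag of a partition
#' @param x a `Partition`.
#' @export
setGeneric("partitionMethod", function(x) standardGeneric("partitionMethod"))

#' p-value of a test result
#' @param x a `TestResult`.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Shared orthogroup count for a genome pair
#' @param x an `OrthoTable`.
#' @param a,b genome ids.
#' @export
setGeneric("sharedOrthogroups", function(x, a, b) standardGeneric("sharedOrthogroups"))

#' Change in network statistics caused by a perturbation
#' @param x a `PerturbationProfile`.
#' @return named numeric vector `after - before`.
#' @export
setGeneric("perturbationDelta", function(x) standardGeneric("perturbationDelta"))

setMethod("asIgraph", "TENetwork", function(x) x@graph)
setMethod("nodeCount", "TENetwork", function(x) igraph::gorder(x@graph))
setMethod("edgeCount", "TENetwork", function(x) igraph::gsize(x@graph))

setMethod("clusterAssignments", "Partition", function(x) x@membership)
setMethod("nClusters", "Partition",
          function(x) length(unique(x@membership)))
setMethod("partitionMethod", "Partition", function(x) x@method)

setMethod("pValue", "TestResult", function(x) x@pValue)

setMethod("sharedOrthogroups", "OrthoTable", function(x, a, b) {
  m <- x@counts
  if (!a %in% rownames(m) || !b %in% rownames(m))
    stop("unknown genome id: ", paste(setdiff(c(a, b), rownames(m)),
                                      collapse = ", "))
  unname(m[a, b])
})

setMethod("perturbationDelta", "PerturbationProfile",
          function(x) x@after - x@before)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %g, p = %.4g (%s; n = %s)\n",
              object@method, object@statistic, object@pValue,
              if (object@exact) "exact" else "approximate",
              paste(object@n, collapse = "/")))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition (%s): %d nodes in %d clusters",
              object@method, length(object@membership),
              length(unique(object@membership))))
  if (!is.na(object@modularity))
    cat(sprintf(", modularity %.4f", object@modularity))
  cat("\n")
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat(sprintf("SimilarityNetwork: %d TE copies, %d bitscore edges, %d genomes\n",
              nodeCount(object), edgeCount(object),
              length(unique(igraph::vertex_attr(object@graph, "genome_id")))))
})

setMethod("show", "ContentNetwork", function(object) {
  cls <- igraph::vertex_attr(object@graph, "nodeClass")
  cat(sprintf("ContentNetwork (%s): %d genomes x %d TE families, %d edges\n",
              object@metric, sum(cls == "genome"), sum(cls == "te"),
              edgeCount(object)))
})

setMethod("show", "OrthoNetwork", function(object) {
  ec <- igraph::edge_attr(object@graph, "edgeClass")
  cat(sprintf(
    "OrthoNetwork (threshold %g): %d nodes, %d genome-te + %d genome-genome edges\n",
    object@threshold, nodeCount(object),
    sum(ec == "genome_te"), sum(ec == "genome_genome")))
})

setMethod("show", "OrthoTable", function(object) {
  cat(sprintf("OrthoTable: %d genomes, %d reported pairs\n",
              nrow(object@counts),
              sum(!is.na(object@counts[upper.tri(object@counts)]))))
})

setMethod("show", "PerturbationProfile", function(object) {
  cat(sprintf("PerturbationProfile [%s]\n", object@target))
  print(rbind(before = object@before, after = object@after,
              delta = object@after - object@before))
  cat(sprintf("genome-partition rand index vs baseline: %.4f\n",
              object@genomeRand))
})
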