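#' @import methods
#' @importFrom igraph is_directed gorder gsize V E vertex_attr edge_attr
NULL

setOldClass("igraph")

#' Result of a statistical test
#'
#' Container returned by [wilcoxonRankSum()], [wilcoxonSignedRank()] and
#' [fisherExact2x2()]. The `exact` slot records whether the p-value was
#' obtained by enumeration of the null distribution rather than a
#' tie-corrected normal approximation.
#'
#' @slot statistic numeric test statistic (rank-sum W, signed-rank V, or the
#'   top-left cell for the Fisher test).
#' @slot pValue numeric p-value in \[0, 1\].
#' @slot method character tag naming the test.
#' @slot n integer vector of per-group sample sizes.
#' @slot exact logical; `TRUE` when computed by exact enumeration.
#' @exportClass TestResult
setClass("TestResult",
  representation(statistic = "numeric", pValue = "numeric",
                 method = "character", n = "integer", exact = "logical"))

setValidity("TestResult", function(object) {
  if (length(object@pValue) != 1 || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    return("pValue must be a single number in [0, 1]")
  if (any(object@n < 0)) return("sample sizes must be non-negative")
  TRUE
})

#' Partition of network nodes into clusters
#'
#' @slot membership named integer vector: node id -> cluster id.
#' @slot method character; `"louvain"` or `"connected_components"`.
#' @slot modularity numeric; weighted modularity of the partition
#'   (`NA` for component partitions, where it is not the objective).
#' @exportClass Partition
setClass("Partition",
  representation(membership = "integer", method = "character",
                 modularity = "numeric"))

setValidity("Partition", function(object) {
  if (length(object@membership) > 0 && is.null(names(object@membership)))
    return("membership must be named by node id")
  if (anyNA(object@membership)) return("every node must be assigned a cluster")
  if (anyDuplicated(names(object@membership)))
    return("duplicate node ids in membership")
  TRUE
})

## Virtual parent for the three graph containers; all carry one igraph whose
## edge attribute 'weight' is the network's edge metric.
setClass("TENetwork", representation("VIRTUAL", graph = "igraph"))

#' Sequence-similarity network of TE copies
#'
#' Undirected weighted graph: one node per annotated TE copy, edge weight the
#' best alignment bitscore between the two copies (bits). Node attributes
#' carry `genome_id`, `family`, `superfamily` and the analysis flags
#' `has_dde3` and `cryptic_hit`.
#'
#' @slot graph igraph object.
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork", contains = "TENetwork")

setValidity("SimilarityNetwork", function(object) {
  g <- object@graph
  if (is_directed(g)) return("similarity network must be undirected")
  if (any(igraph::which_loop(g))) return("self-loops are not allowed")
  if (gsize(g) > 0 && (is.null(edge_attr(g, "weight")) ||
                       any(edge_attr(g, "weight") <= 0)))
    return("all edge weights (bitscores) must be > 0")
  need <- c("genome_id", "superfamily", "family", "has_dde3", "cryptic_hit")
  miss <- setdiff(need, igraph::vertex_attr_names(g))
  if (gorder(g) > 0 && length(miss))
    return(paste("missing node attributes:", paste(miss, collapse = ", ")))
  TRUE
})

#' Bipartite genome-TE content network
#'
#' Genome nodes versus TE-family nodes; each edge connects a genome to a
#' family present in it, weighted by the chosen abundance metric.
#'
#' @slot graph igraph object; vertex attribute `nodeClass` is `"genome"` or
#'   `"te"`, and `type` is the logical bipartite marker (`TRUE` for TE nodes).
#' @slot metric abundance metric tag: `"count"`, `"total_bp"`,
#'   `"pct_genome"` or `"pct_of_te"`.
#' @exportClass ContentNetwork
setClass("ContentNetwork", contains = "TENetwork",
  representation(metric = "character"))

setValidity("ContentNetwork", function(object) {
  g <- object@graph
  if (!object@metric %in% c("count", "total_bp", "pct_genome", "pct_of_te"))
    return("unknown metric tag")
  cls <- vertex_attr(g, "nodeClass")
  if (gorder(g) > 0 && (is.null(cls) || !all(cls %in% c("genome", "te"))))
    return("every node needs nodeClass 'genome' or 'te'")
  if (gsize(g) > 0) {
    ends <- igraph::ends(g, E(g))
    cl <- matrix(cls[match(ends, V(g)$name)], ncol = 2)
    if (any(cl[, 1] == cl[, 2]))
      return("network must be strictly bipartite (genome-te edges only)")
    if (any(edge_attr(g, "weight") <= 0)) return("edge weights must be > 0")
  }
  TRUE
})

#' Phylogeny-aware orthonetwork
#'
#' The bipartite content network with edge weights replaced by the
#' log-adjusted TE content metric, plus genome-genome edges weighted by
#' normalised shared-orthogroup counts for pairs at or above the sparsity
#' threshold.
#'
#' @slot graph igraph; vertex attribute `nodeClass` in `{"genome","te"}`,
#'   edge attribute `edgeClass` in `{"genome_te","genome_genome"}`.
#' @slot threshold minimum shared-orthogroup count for a genome-genome edge.
#' @exportClass OrthoNetwork
setClass("OrthoNetwork", contains = "TENetwork",
  representation(threshold = "numeric"))

setValidity("OrthoNetwork", function(object) {
  g <- object@graph
  if (gsize(g) > 0) {
    w <- edge_attr(g, "weight")
    if (any(w <= 0) || any(w > 1 + 1e-12))
      return("all normalised edge weights must lie in (0, 1]")
    if (is.null(edge_attr(g, "edgeClass")))
      return("edges must carry edgeClass")
  }
  TRUE
})

#' Symmetric table of shared orthogroup counts
#'
#' @slot counts symmetric numeric matrix with genome ids as dimnames;
#'   `NA` marks pairs that were never reported. The diagonal is ignored.
#' @exportClass OrthoTable
setClass("OrthoTable", representation(counts = "matrix"))

setValidity("OrthoTable", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("counts must be a square matrix with matching dimnames")
  off <- m[row(m) != col(m)]
  if (any(off < 0, na.rm = TRUE)) return("orthogroup counts must be >= 0")
  if (!isTRUE(all.equal(m, t(m)))) return("counts must be symmetric")
  TRUE
})

#' Before/after profile of a network perturbation
#'
#' @slot target description of what was removed.
#' @slot before,after named numeric vectors of network statistics
#'   (`nodes`, `edges`, `n_clusters`, `modularity`, `n_components`).
#' @slot genomeRand rand index between the genome-node partitions of the
#'   baseline and the perturbed network.
#' @exportClass PerturbationProfile
setClass("PerturbationProfile",
  representation(target = "character", before = "numeric", after = "numeric",
                 genomeRand = "numeric"))

#' Configuration for the synthetic TE landscape generator
#'
#' See [landscapeConfig()] for field semantics and defaults; the constructor
#' is the supported way to build one (the seed is mandatory).
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(nSpecies = "integer", nClades = "integer",
    piwiFraction = "numeric", dnmtFraction = "numeric",
    famMeanNoPiwi = "numeric", famRatioPiwi = "numeric",
    copyMeanNoPiwi = "numeric", copyRatioPiwi = "numeric",
    privateMean = "numeric", inactiveSingletonMeanDnmt = "numeric",
    lengthMeanlog = "numeric", lengthSdlog = "numeric",
    orthoMax = "numeric", orthoDecay = "numeric", orthoNoiseSd = "numeric",
    nSuperfamilies = "integer", dominantSuperfamily = "character",
    dominantWeight = "numeric", regimeByClade = "logical",
    seed = "integer"))

setValidity("LandscapeConfig", function(object) {
  pos <- c(object@nSpecies, object@nClades, object@famMeanNoPiwi,
           object@famRatioPiwi, object@copyMeanNoPiwi, object@copyRatioPiwi,
           object@lengthSdlog, object@orthoMax)
  if (any(pos <= 0)) return("all sizes, means and ratios must be > 0")
  if (object@privateMean < 0 || object@inactiveSingletonMeanDnmt < 0)
    return("singleton rates must be >= 0")
  if (object@piwiFraction < 0 || object@piwiFraction > 1 ||
      object@dnmtFraction < 0 || object@dnmtFraction > 1)
    return("regime fractions must lie in [0, 1]")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("a seed is mandatory")
  TRUE
})

#' Configuration for the synthetic alignment-hit generator
#'
#' See [hitModelConfig()]; enforces the planted-signal ordering
#' within-family mean bitscore > convergent-segment mean > between-family
#' mean >= 0.
#' @exportClass HitModelConfig
setClass("HitModelConfig",
  representation(withinMean = "numeric", withinSd = "numeric",
    withinDensity = "numeric", betweenMean = "numeric",
    betweenDensity = "numeric", convergentPair = "character",
    convergentMean = "numeric", convergentDensity = "numeric",
    dde3Families = "character", seed = "integer"))

setValidity("HitModelConfig", function(object) {
  if (object@withinMean <= 0) return("withinMean must be > 0")
  if (length(object@convergentPair) &&
      (length(object@convergentPair) != 2 ||
       object@convergentMean <= 0 ||
       object@convergentMean >= object@withinMean))
    return("need withinMean > convergentMean > 0 and exactly two families")
  if (object@betweenDensity > 0 && object@betweenMean >= object@withinMean)
    return("betweenMean must be below withinMean")
  if (any(c(object@withinDensity, object@betweenDensity,
            object@convergentDensity) < 0) ||
      any(c(object@withinDensity, object@betweenDensity,
            object@convergentDensity) > 1))
    return("densities must lie in [0, 1]")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("a seed is mandatory")
  TRUE
})
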