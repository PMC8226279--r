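## Phylogeny-collapsed "orthonetwork": the genome-TE content network with
## log-adjusted edge weights, plus genome-genome edges from shared
## orthogroup counts, so Louvain can group closely related species and
## group-level statistics count each clade once.

#' Build the orthonetwork
#'
#' Genome-TE edges are weighted by the length-adjusted content metric
#' `log(total TE bp of the family in the genome) / log(max such total)`,
#' a ratio that is invariant to the logarithm base and lies in (0, 1] with
#' 1 attained by the largest genome-family total. Genome-genome edges are
#' added for species pairs sharing at least `threshold` orthogroups
#' (default 4,500, chosen to sparsify the species side), weighted by the
#' pair's count divided by the maximum count over retained pairs, so both
#' edge families are on the same (0, 1] scale.
#'
#' @param copies TE copy table.
#' @param orthoTable an [OrthoTable-class] covering all genome pairs
#'   present in `copies`.
#' @param annotations species annotation table.
#' @param threshold minimum shared-orthogroup count for a genome-genome
#'   edge.
#' @param maxScope `"global"` (default) normalises TE totals by the maximum
#'   over all genome-family edges; `"family"` normalises within each family.
#' @return an [OrthoNetwork-class].
#' @export
buildOrthoNetwork <- function(copies, orthoTable, annotations,
                              threshold = 4500, maxScope = "global") {
  maxScope <- match.arg(maxScope, c("global", "family"))
  validateCopies(copies)
  validateAnnotations(annotations)
  base <- buildContentNetwork(copies, annotations, metric = "total_bp")
  g <- asIgraph(base)

  w <- igraph::E(g)$weight
  if (any(w <= 1))
    stop("every genome-family total must exceed 1 bp for the log ",
         "adjustment; smallest observed total is ", min(w), " bp")
  if (maxScope == "global") {
    adj <- log(w) / log(max(w))
  } else {
    ends <- igraph::ends(g, igraph::E(g))
    fam <- ifelse(igraph::V(g)$nodeClass[match(ends[, 2], igraph::V(g)$name)]
                  == "te", ends[, 2], ends[, 1])
    famMax <- tapply(w, fam, max)
    adj <- log(w) / log(famMax[fam])
    adj[log(famMax[fam]) == 0] <- 1
  }
  g <- igraph::set_edge_attr(g, "weight", value = as.numeric(adj))
  g <- igraph::set_edge_attr(g, "edgeClass", value = "genome_te")

  genomes <- igraph::V(g)$name[igraph::V(g)$nodeClass == "genome"]
  m <- orthoTable@counts
  miss <- setdiff(genomes, rownames(m))
  if (length(miss))
    stop("ortho table lacks genome(s): ", paste(miss, collapse = ", "))
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- pairs[rownames(m)[pairs[, 1]] %in% genomes &
                 colnames(m)[pairs[, 2]] %in% genomes, , drop = FALSE]
  cnt <- m[pairs]
  if (anyNA(cnt)) {
    bad <- pairs[is.na(cnt), , drop = FALSE][1, ]
    stop("ortho table has no count for pair (", rownames(m)[bad[1]], ", ",
         colnames(m)[bad[2]], ")")
  }
  keep <- cnt >= threshold
  if (any(keep)) {
    ww <- cnt[keep] / max(cnt[keep])
    g <- igraph::add_edges(
      g, rbind(rownames(m)[pairs[keep, 1]], colnames(m)[pairs[keep, 2]]),
      weight = ww, edgeClass = "genome_genome")
  }
  new("OrthoNetwork", graph = g, threshold = threshold)
}

#' Collapse genomes into related-species groups
#'
#' Louvain-clusters the full mixed network (genome-TE and genome-genome
#' edges together); every cluster containing at least one genome becomes a
#' group. Because closely related species share far more orthogroups than
#' the threshold, they co-cluster, and group-level statistics then count
#' each group of related, same-silencing-mechanism species once:
#' \describe{
#'   \item{degree}{number of distinct TE families incident to any member}
#'   \item{weighted_degree}{sum of the members' genome-TE edge weights}
#'   \item{n_singletons}{families found only within the group's members}
#' }
#' Silencing labels (`has_dnmt`, `has_piwi`) and the clade label are
#' assigned by majority vote over members, with the agreement fraction
#' reported.
#'
#' @param orthonet an [OrthoNetwork-class] built with annotations.
#' @param seed,resolution Louvain parameters.
#' @return data.frame with one row per group: `group_id`, `n_genomes`,
#'   `members`, `clade_label`, `clade_agreement`, `has_dnmt`,
#'   `dnmt_agreement`, `has_piwi`, `piwi_agreement`, `degree`,
#'   `weighted_degree`, `n_singletons`.
#' @export
collapseToGroups <- function(orthonet, seed = 0, resolution = 1) {
  g <- asIgraph(orthonet)
  part <- louvainPartition(orthonet, resolution, seed)
  memb <- clusterAssignments(part)
  cls <- setNames(igraph::V(g)$nodeClass, igraph::V(g)$name)
  genomes <- names(cls)[cls == "genome"]
  clusters <- split(names(memb), memb)
  nDropped <- sum(vapply(clusters, function(v) !any(cls[v] == "genome"),
                         logical(1)))
  if (nDropped)
    warning(nDropped, " cluster(s) contain no genome node; excluded")
  rows <- list()
  for (cid in names(clusters)) {
    members <- intersect(clusters[[cid]], genomes)
    if (!length(members)) next
    fams <- unique(unlist(lapply(members, function(v) {
      nb <- igraph::neighbors(g, v)
      nb$name[cls[nb$name] == "te"]
    })))
    nSing <- sum(vapply(fams, function(f) {
      nb <- igraph::neighbors(g, f)
      all(nb$name[cls[nb$name] == "genome"] %in% members)
    }, logical(1)))
    wdeg <- sum(vapply(members, function(v) {
      inc <- igraph::incident(g, v)
      sum(inc$weight[inc$edgeClass == "genome_te"])
    }, numeric(1)))
    clade <- majorityVote(igraph::vertex_attr(g, "clade_label",
                                              members))
    dnmt <- majorityVote(igraph::vertex_attr(g, "has_dnmt", members))
    piwi <- majorityVote(igraph::vertex_attr(g, "has_piwi", members))
    rows[[cid]] <- data.frame(
      group_id = as.integer(cid), n_genomes = length(members),
      members = paste(sort(members), collapse = ";"),
      clade_label = clade$value, clade_agreement = clade$agreement,
      has_dnmt = as.logical(dnmt$value), dnmt_agreement = dnmt$agreement,
      has_piwi = as.logical(piwi$value), piwi_agreement = piwi$agreement,
      degree = length(fams), weighted_degree = wdeg,
      n_singletons = nSing, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_genomes, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
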