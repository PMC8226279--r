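## Graph serialisation (GEXF for the network visualisers, GraphML for
## interchange) and the end-to-end pipeline runner. Both writers preserve
## node attributes and full-precision edge weights; readGraph() restores
## attribute types so a write/read round trip is lossless.

gexfType <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "integer"
  else if (is.numeric(x)) "double"
  else "string"
}

fmtNum <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE), character(1))
}

#' Write a network to GEXF or GraphML
#'
#' Node attributes (genome/TE class, superfamily, flags, cluster id if a
#' partition is supplied) and edge weights are written at full precision.
#' GraphML is written through igraph; logical attributes are stored as
#' `"TRUE"`/`"FALSE"` strings there and restored by [readGraph()]. GEXF
#' (the native format of the usual network visualisers) is written with
#' typed attvalues.
#'
#' @param net a network object or igraph.
#' @param path output file.
#' @param format `"gexf"` or `"graphml"` (default: from the file
#'   extension).
#' @param partition optional [Partition-class]; stored as node attribute
#'   `cluster_id`.
#' @return `path`, invisibly.
#' @export
writeGraph <- function(net, path, format = NULL, partition = NULL) {
  g <- if (is(net, "TENetwork")) asIgraph(net) else net
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("gexf", "graphml"))
    stop("unsupported format '", format, "'")
  if (!is.null(partition)) {
    memb <- clusterAssignments(partition)
    g <- igraph::set_vertex_attr(g, "cluster_id",
                                 value = unname(memb[igraph::V(g)$name]))
  }
  if (format == "graphml") {
    for (a in igraph::vertex_attr_names(g))
      if (is.logical(igraph::vertex_attr(g, a)))
        g <- igraph::set_vertex_attr(
          g, a, value = ifelse(igraph::vertex_attr(g, a), "TRUE", "FALSE"))
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  writeGexf(g, path)
}

writeGexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  vAttrs <- setdiff(igraph::vertex_attr_names(g), "name")
  attrsNode <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(vAttrs))
    xml2::xml_add_child(attrsNode, "attribute", id = as.character(i - 1),
                        title = vAttrs[i],
                        type = gexfType(igraph::vertex_attr(g, vAttrs[i])))
  nodes <- xml2::xml_add_child(graph, "nodes")
  names_ <- igraph::V(g)$name
  attrVals <- lapply(vAttrs, function(a) igraph::vertex_attr(g, a))
  for (v in seq_along(names_)) {
    nd <- xml2::xml_add_child(nodes, "node", id = names_[v],
                              label = names_[v])
    if (length(vAttrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vAttrs)) {
        val <- attrVals[[i]][v]
        if (is.na(val)) next
        sval <- if (is.logical(val)) tolower(as.character(val))
                else if (is.double(val)) fmtNum(val)
                else as.character(val)
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = sval)
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  eAttrs <- setdiff(igraph::edge_attr_names(g), "weight")
  if (igraph::gsize(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    w <- igraph::E(g)$weight
    for (e in seq_len(nrow(ends))) {
      el <- xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                                source = ends[e, 1], target = ends[e, 2],
                                weight = fmtNum(w[e]))
      for (a in eAttrs)
        xml2::xml_set_attr(el, paste0("data-", a),
                           as.character(igraph::edge_attr(g, a)[e]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network written by [writeGraph()]
#'
#' @param path input file.
#' @param format `"gexf"` or `"graphml"` (default: from the extension).
#' @return an igraph object with typed node attributes and numeric edge
#'   weights. (Rewrap with the appropriate network class constructor if
#'   needed; the graph itself round-trips losslessly.)
#' @export
readGraph <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::vertex_attr(g, "name")) &&
        !is.null(igraph::vertex_attr(g, "id")))
      g <- igraph::set_vertex_attr(g, "name",
                                   value = igraph::vertex_attr(g, "id"))
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.character(v) && length(v) && all(v %in% c("TRUE", "FALSE")))
        g <- igraph::set_vertex_attr(g, a, value = v == "TRUE")
    }
    return(g)
  }
  if (format != "gexf") stop("unsupported format '", format, "'")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attrDefs <- xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute")
  defs <- data.frame(
    id = xml2::xml_attr(attrDefs, "id"),
    title = xml2::xml_attr(attrDefs, "title"),
    type = xml2::xml_attr(attrDefs, "type"), stringsAsFactors = FALSE)
  nodeEls <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(nodeEls, "id")
  attrs <- list()
  for (k in seq_len(nrow(defs))) {
    raw <- vapply(nodeEls, function(nd) {
      av <- xml2::xml_find_first(nd, sprintf(".//attvalue[@for='%s']",
                                             defs$id[k]))
      if (inherits(av, "xml_missing")) NA_character_
      else xml2::xml_attr(av, "value")
    }, character(1))
    attrs[[defs$title[k]]] <- switch(defs$type[k],
      boolean = raw == "true",
      integer = as.integer(raw),
      double = as.numeric(raw),
      raw)
  }
  edgeEls <- xml2::xml_find_all(doc, ".//edges/edge")
  edf <- data.frame(from = xml2::xml_attr(edgeEls, "source"),
                    to = xml2::xml_attr(edgeEls, "target"),
                    weight = as.numeric(xml2::xml_attr(edgeEls, "weight")),
                    stringsAsFactors = FALSE)
  extra <- setdiff(unique(unlist(lapply(edgeEls, function(e)
    names(xml2::xml_attrs(e))))), c("id", "source", "target", "weight"))
  for (a in extra)
    edf[[sub("^data-", "", a)]] <- xml2::xml_attr(edgeEls, a)
  vdf <- cbind(data.frame(name = ids, stringsAsFactors = FALSE),
               as.data.frame(attrs, optional = TRUE,
                             stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Write a run manifest
#'
#' Records the command/stage name, a digest of the configuration, the
#' seeds, md5 digests of every input file, the package version and a
#' timestamp, so a run can be reproduced and verified.
#'
#' @param path output JSON file.
#' @param command stage name.
#' @param config configuration list (hashed after serialisation).
#' @param seeds named or unnamed seed vector.
#' @param inputs character vector of input file paths to digest.
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(path, command, config = list(), seeds = NULL,
                             inputs = character()) {
  cfgFile <- tempfile()
  on.exit(unlink(cfgFile))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE),
             cfgFile)
  manifest <- list(
    command = command,
    config_md5 = unname(tools::md5sum(cfgFile)),
    seeds = seeds,
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))),
    package_version = as.character(utils::packageVersion("TEnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full analysis pipeline
#'
#' Executes build, cluster, statistics and export stages from one
#' configuration and writes every table, network and a run manifest to an
#' output directory. The configuration is a list (or a YAML file holding
#' one) with:
#' \describe{
#'   \item{seed}{master seed for every random stage (default 0)}
#'   \item{inputs}{optional list of file paths: `copies`, `hits`,
#'     `annotations`, `ortho`, `domains` (canonical TSV forms); all listed
#'     files are checked before any compute}
#'   \item{landscape, hits_model}{when `inputs` is absent, argument lists
#'     for [landscapeConfig()] and [hitModelConfig()] used to simulate
#'     the data}
#'   \item{metric}{content-network metric (default `"total_bp"`)}
#'   \item{resolution}{Louvain resolution (default 1)}
#'   \item{ortho_threshold}{orthonetwork sparsity threshold (default 4500)}
#' }
#' Outputs (TSV tables, GEXF networks, `manifest.json`) are deterministic
#' for a fixed configuration: reruns produce byte-identical tables.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of the main in-memory results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  resolution <- if (is.null(config$resolution)) 1 else config$resolution

  inputFiles <- character()
  if (!is.null(config$inputs)) {
    inputFiles <- unlist(config$inputs)
    missing <- inputFiles[!file.exists(inputFiles)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    copies <- readTsv(config$inputs$copies)
    annotations <- if (!is.null(config$inputs$annotations))
      readTsv(config$inputs$annotations) else NULL
    hits <- if (!is.null(config$inputs$hits))
      readTsv(config$inputs$hits) else NULL
    ortho <- if (!is.null(config$inputs$ortho))
      readOrthoTable(config$inputs$ortho) else NULL
  } else {
    lc <- do.call(landscapeConfig,
                  c(config$landscape, list(seed = seed)))
    land <- simulateLandscape(lc)
    copies <- land$copies
    annotations <- land$annotations
    ortho <- land$orthoTable
    hits <- NULL
    if (!is.null(config$hits_model)) {
      hm <- do.call(hitModelConfig,
                    c(config$hits_model, list(seed = seed + 1L)))
      hits <- simulateHits(copies, hm)$hits
    }
    writeTsv(copies, file.path(outDir, "copies.tsv"))
    writeTsv(annotations, file.path(outDir, "annotations.tsv"))
    if (!is.null(hits)) writeTsv(hits, file.path(outDir, "hits.tsv"))
  }

  results <- list(copies = copies, annotations = annotations)

  if (!is.null(hits)) {
    ssn <- buildSSN(hits, copies)
    lp <- louvainPartition(ssn, resolution, seed)
    cp <- componentPartition(ssn)
    comp <- clusterComposition(ssn, lp)
    writeTsv(comp, file.path(outDir, "ssn_clusters.tsv"))
    writeTsv(data.frame(copy_id = names(clusterAssignments(lp)),
                        louvain = unname(clusterAssignments(lp)),
                        component = unname(clusterAssignments(cp)[
                          names(clusterAssignments(lp))])),
             file.path(outDir, "ssn_partition.tsv"))
    writeGraph(ssn, file.path(outDir, "ssn.gexf"), partition = lp)
    results$ssn <- ssn
    results$ssn_rand <- randIndex(lp, cp)
  }

  metric <- if (is.null(config$metric)) "total_bp" else config$metric
  net <- buildContentNetwork(copies, annotations, metric)
  stats <- genomeStatistics(net, annotations)
  writeTsv(stats, file.path(outDir, "genome_statistics.tsv"))
  writeTsv(familySummary(copies), file.path(outDir, "family_summary.tsv"))
  writeGraph(net, file.path(outDir, "content_network.gexf"),
             partition = louvainPartition(net, resolution, seed))
  results$content <- net
  results$genome_stats <- stats

  if (!is.null(ortho)) {
    thr <- if (is.null(config$ortho_threshold)) 4500
           else config$ortho_threshold
    orthonet <- buildOrthoNetwork(copies, ortho, annotations,
                                  threshold = thr)
    groups <- collapseToGroups(orthonet, seed, resolution)
    writeTsv(groups, file.path(outDir, "orthonet_groups.tsv"))
    writeGraph(orthonet, file.path(outDir, "orthonet.gexf"))
    results$orthonet <- orthonet
    results$groups <- groups
  }

  writeRunManifest(file.path(outDir, "manifest.json"), "run",
                   config = config, seeds = seed, inputs = inputFiles)
  invisible(results)
}
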