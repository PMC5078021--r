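#' Build the thresholded chemical-protein interaction network
#'
#' Keeps the cells of the compound x protein `P_Z` matrix that are strictly
#' below `pz_cutoff` (1e-4 in the published networks) and turns them into a
#' bipartite network.  Each edge is weighted by the reciprocal of the
#' negative common logarithm of `P_Z` (so `P_Z` = 1e-8 gives weight 0.125);
#' the weight decreases strictly as `P_Z` grows.
#'
#' @param result A fitted [tlsea()] object, or a numeric `P_Z` matrix
#'   (phenotype compounds x proteins) with dimnames.
#' @param pz_cutoff Strict upper bound on `P_Z` for an edge.
#' @return An object of class `"chemprot_network"`: a list with `graph`
#'   (bipartite igraph; vertex attribute `type` is `"compound"` or
#'   `"protein"`), `edges` (data frame `compound_id`, `protein_id`, `p_z`,
#'   `weight`) and `pz_cutoff`.
#' @export
build_network <- function(result, pz_cutoff = 1e-4) {
  pz <- if (inherits(result, "tlsea")) result$pz else result
  stopifnot(is.matrix(pz), pz_cutoff > 0)
  hit <- which(pz < pz_cutoff, arr.ind = TRUE)
  edges <- data.frame(compound_id = rownames(pz)[hit[, 1]],
                      protein_id = colnames(pz)[hit[, 2]],
                      p_z = pz[hit],
                      stringsAsFactors = FALSE)
  edges$weight <- edge_weight(edges$p_z)
  edges <- edges[order(edges$compound_id, edges$protein_id), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L)
    tlsea_log("build_network: no P_Z below %g; empty network", pz_cutoff)
  nodes <- data.frame(
    name = c(unique(edges$compound_id), unique(edges$protein_id)),
    type = rep(c("compound", "protein"),
               c(length(unique(edges$compound_id)),
                 length(unique(edges$protein_id)))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("compound_id", "protein_id", "p_z", "weight")],
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, edges = edges, pz_cutoff = pz_cutoff),
            class = "chemprot_network")
}

#' Edge weight from a layer-one significance
#'
#' weight = 1 / (-log10(P_Z)); strictly decreasing in `P_Z` on (0, 1).
#'
#' @param p_z Numeric vector of significances in (0, 1).
#' @return Positive weights.
#' @export
edge_weight <- function(p_z) {
  stopifnot(all(p_z > 0), all(p_z < 1))
  1 / (-log10(p_z))
}

#' @export
print.chemprot_network <- function(x, ...) {
  types <- igraph::V(x$graph)$type
  cat(sprintf("chemical-protein network (P_Z < %g): %d compounds, %d proteins, %d edges\n",
              x$pz_cutoff, sum(types == "compound"), sum(types == "protein"),
              nrow(x$edges)))
  invisible(x)
}

#' Table of highly connected proteins
#'
#' Proteins linked to strictly more than `min_degree` compounds in the
#' network (the published analysis tabulated proteins with more than 15
#' links), sorted by decreasing degree with ties broken by identifier.
#'
#' @param net A `"chemprot_network"`.
#' @param min_degree Strict lower bound on the number of linked compounds.
#' @return Data frame with columns `protein_id`, `degree`.
#' @export
protein_degree_table <- function(net, min_degree = 15) {
  if (nrow(net$edges) == 0L)
    return(data.frame(protein_id = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  deg <- table(net$edges$protein_id)
  deg <- deg[deg > min_degree]
  out <- data.frame(protein_id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the first-neighborhood sub-network of one node
#'
#' Returns the seed node, its direct neighbors, and the connecting edges (a
#' star, since the network is bipartite).
#'
#' @param net A `"chemprot_network"`.
#' @param node Compound or protein identifier present in the network.
#' @return A `"chemprot_network"` restricted to the neighborhood.
#' @export
extract_subnetwork <- function(net, node) {
  if (!node %in% igraph::V(net$graph)$name)
    stop("unknown node: ", node)
  keep <- net$edges$compound_id == node | net$edges$protein_id == node
  sub <- net
  sub$edges <- net$edges[keep, , drop = FALSE]
  rownames(sub$edges) <- NULL
  nbrs <- igraph::neighbors(net$graph, node)
  g <- igraph::induced_subgraph(net$graph,
                                c(node, igraph::V(net$graph)$name[nbrs]))
  sub$graph <- g
  sub$seed <- node
  sub
}

#' Overlay networks from several conditions
#'
#' Unions two or more networks computed over a shared identifier space
#' (e.g. the same proteins against different cell lines) and annotates every
#' node and edge with the set of conditions it appears in, so
#' condition-specific structure can be rendered in one layout.
#'
#' @param nets Named list of `"chemprot_network"` objects (names are the
#'   condition labels).
#' @return A list of class `"chemprot_overlay"` with `graph` (igraph whose
#'   vertex/edge attribute `membership` is the comma-joined condition set),
#'   `nodes` and `edges` data frames, and `conditions`.
#' @export
overlay_networks <- function(nets) {
  stopifnot(length(nets) >= 2L)
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    names(nets) <- sprintf("condition%d", seq_along(nets))
  conds <- names(nets)
  edge_tabs <- lapply(conds, function(cn) {
    e <- nets[[cn]]$edges
    if (nrow(e) == 0L) return(NULL)
    data.frame(compound_id = e$compound_id, protein_id = e$protein_id,
               condition = cn, stringsAsFactors = FALSE)
  })
  all_edges <- do.call(rbind, edge_tabs)
  if (is.null(all_edges))
    all_edges <- data.frame(compound_id = character(), protein_id = character(),
                            condition = character())
  key <- paste(all_edges$compound_id, all_edges$protein_id, sep = "\r")
  edge_membership <- tapply(all_edges$condition, key,
                            function(x) paste(sort(unique(x)), collapse = ","))
  ukey <- names(edge_membership)
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  edges <- data.frame(compound_id = vapply(parts, `[`, "", 1L),
                      protein_id = vapply(parts, `[`, "", 2L),
                      membership = as.character(edge_membership),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$compound_id, edges$protein_id), , drop = FALSE]
  rownames(edges) <- NULL
  node_tabs <- lapply(conds, function(cn) {
    g <- nets[[cn]]$graph
    if (igraph::vcount(g) == 0L) return(NULL)
    data.frame(name = igraph::V(g)$name, type = igraph::V(g)$type,
               condition = cn, stringsAsFactors = FALSE)
  })
  all_nodes <- do.call(rbind, node_tabs)
  node_membership <- tapply(all_nodes$condition, all_nodes$name,
                            function(x) paste(sort(unique(x)), collapse = ","))
  nodes <- data.frame(name = names(node_membership),
                      type = all_nodes$type[match(names(node_membership),
                                                  all_nodes$name)],
                      membership = as.character(node_membership),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    cbind(edges[, c("compound_id", "protein_id")],
          membership = edges$membership),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges, conditions = conds),
            class = "chemprot_overlay")
}

#' Export a network for Cytoscape
#'
#' `write_network_sif()` writes the simple interaction format (source,
#' relation `cp`, target); `write_network_graphml()` writes GraphML with all
#' node and edge attributes; `write_edge_attributes()` writes a TSV of
#' `compound_id`, `protein_id`, `p_z`, `weight`.
#'
#' @param net A `"chemprot_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  lines <- sprintf("%s\tcp\t%s", net$edges$compound_id, net$edges$protein_id)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_edge_attributes <- function(net, path) {
  out <- net$edges
  out$p_z <- sprintf("%.17g", out$p_z)
  out$weight <- sprintf("%.17g", out$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
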