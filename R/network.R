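#' Default currency-metabolite names
#'
#' Ubiquitous cofactors excluded (optionally) from the metabolite graph:
#' they co-occur with nearly everything and inflate connectivity. Matching
#' is on the metabolite name across all compartments.
#' @export
CURRENCY_METABOLITES <- c("ATP", "ADP", "AMP", "H2O", "H+", "Pi", "PPi",
                          "NAD+", "NADH", "NADP+", "NADPH", "CO2", "O2",
                          "CoA")

#' Build the undirected metabolite graph of a model
#'
#' One node per metabolite (enzyme and arm pseudo-metabolites included, as
#' they appear as reactants); an edge joins two metabolites iff they occur
#' in at least one common reaction. The graph is simple: no self-loops, no
#' multi-edges. Currency metabolites may be dropped before edge
#' construction; isolated nodes are dropped.
#'
#' @param model an \code{ec_model}.
#' @param exclude_currency character vector of metabolite names to drop
#'   (across all compartments), or NULL to keep everything.
#' @return an \code{igraph} graph with vertex attributes \code{kind} and
#'   \code{compartment}.
#' @export
build_graph <- function(model, exclude_currency = NULL) {
  met <- model$metabolites
  drop <- if (is.null(exclude_currency)) character()
          else met$id[met$name %in% exclude_currency]
  edges <- character()
  for (r in model$reactions) {
    ms <- setdiff(names(r$stoich), drop)
    if (length(ms) >= 2) {
      pr <- utils::combn(sort(ms), 2)
      edges <- c(edges, as.vector(pr))
    }
  }
  if (!length(edges)) return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::simplify(igraph::graph_from_edgelist(
    matrix(edges, ncol = 2, byrow = TRUE), directed = FALSE))
  idx <- match(igraph::V(g)$name, met$id)
  igraph::V(g)$kind <- met$kind[idx]
  igraph::V(g)$compartment <- met$compartment[idx]
  g
}

#' Connectivity indices of a metabolite graph
#'
#' Computes node/edge counts, average number of neighbors, diameter, radius
#' and characteristic path length (on the largest connected component),
#' average local clustering coefficient (degree <= 1 nodes count 0), density
#' mean(k)/(n-1), heterogeneity sd(k)/mean(k) with population variance, and
#' centralization max(k)/n.
#'
#' @param graph an igraph graph from \code{\link{build_graph}}.
#' @return list of class \code{ec_network_metrics}.
#' @export
network_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  k <- igraph::degree(graph)
  comp <- igraph::components(graph)
  big <- igraph::induced_subgraph(graph,
           which(comp$membership == which.max(comp$csize)))
  het <- {
    mu <- mean(k); v <- mean((k - mu)^2)
    if (mu > 0) sqrt(v) / mu else 0
  }
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(graph),
    avg_neighbors = mean(k),
    diameter = if (igraph::vcount(big) > 1) igraph::diameter(big) else 0,
    radius = if (igraph::vcount(big) > 1) igraph::radius(big) else 0,
    char_path_length = if (igraph::vcount(big) > 1)
      igraph::mean_distance(big) else 0,
    clustering = igraph::transitivity(graph, type = "localaverage",
                                      isolates = "zero"),
    density = if (n > 1) mean(k) / (n - 1) else 0,
    heterogeneity = het,
    centralization = max(k) / n), class = "ec_network_metrics")
}

#' @export
print.ec_network_metrics <- function(x, ...) {
  cat("Metabolite-graph connectivity indices\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Top-degree nodes of the metabolite graph
#'
#' Ranks nodes by degree (hubs first); ties break lexicographically on the
#' node id. \code{role_filter} restricts the ranking to one metabolite kind,
#' e.g. "enzyme" for enzyme-connectivity rankings.
#'
#' @param graph an igraph graph from \code{\link{build_graph}}.
#' @param k how many nodes (capped at the node count).
#' @param role_filter optional kind ("chemical", "enzyme", "arm").
#' @return data.frame: \code{id}, \code{kind}, \code{degree}.
#' @export
top_degree <- function(graph, k = 20, role_filter = NULL) {
  if (k < 1) stop("k must be >= 1")
  deg <- igraph::degree(graph)
  kind <- igraph::V(graph)$kind
  d <- data.frame(id = names(deg), kind = kind, degree = unname(deg),
                  stringsAsFactors = FALSE)
  if (!is.null(role_filter)) d <- d[d$kind == role_filter, , drop = FALSE]
  d <- d[order(-d$degree, d$id), , drop = FALSE]
  utils::head(d, k)
}

#' Export a graph as an edge-list TSV
#' @param graph igraph graph.
#' @param path output TSV (columns: from, to).
#' @return path, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
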