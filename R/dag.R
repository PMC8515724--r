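#' Validate a directed acyclic graph
#'
#' Builds the structure object used throughout the package: a set of node
#' names plus directed edges (parent -> child), rejected unless acyclic.
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data frame of directed edges
#'   (parent, child). May have zero rows.
#' @return An object of class `bn_dag` with elements `nodes`, `edges`
#'   (character matrix with columns `from`, `to`) and `order` (a topological
#'   order of the nodes).
#' @examples
#' validate_dag(c("X", "Z", "Y", "W"),
#'              rbind(c("X", "Y"), c("Y", "W"), c("Z", "W")))
#' @export
validate_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("from", "to")
  bad <- !(edges %in% nodes)
  if (any(bad)) {
    stop("edge endpoint(s) not among nodes: ",
         paste(unique(edges[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge", call. = FALSE)
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), , drop = FALSE]
  }
  g <- dag_igraph(nodes, edges)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("graph contains a directed cycle through: ",
         paste(sort(cyc), collapse = ", "), call. = FALSE)
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))
  structure(list(nodes = nodes, edges = edges, order = ord),
            class = "bn_dag")
}

dag_igraph <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

as_igraph <- function(dag) dag_igraph(dag$nodes, dag$edges)

#' Parents of a node in a DAG
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector of parent names (in stable edge order).
#' @export
dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, "to"] == node, "from"])
}

dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, "from"] == node, "to"])
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2]), sep = "\n")
  }
  invisible(x)
}

#' Read and write plain-text edge lists
#'
#' The interchange format is one `parent<TAB>child` pair per line; node
#' names may also be supplied for isolated vertices.
#'
#' @param path File path.
#' @param nodes Optional character vector of node names; defaults to the
#'   union of edge endpoints.
#' @return `read_edge_list()` returns a `bn_dag`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(validate_dag(nodes %||% character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("malformed edge list line: ", lines[lengths(parts) != 2][1],
         call. = FALSE)
  }
  edges <- do.call(rbind, parts)
  validate_dag(nodes %||% unique(as.vector(t(edges))), edges)
}

#' @rdname read_edge_list
#' @param dag A `bn_dag` to write.
#' @export
write_edge_list <- function(dag, path) {
  writeLines(paste(dag$edges[, 1], dag$edges[, 2], sep = "\t"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# d-separation via the moralized ancestral graph: x and y are d-separated
# by z iff they are disconnected in the moralized subgraph induced by the
# ancestors of {x, y, z} after removing z.
d_separated <- function(dag, x, y, z = character(0)) {
  g <- as_igraph(dag)
  anc <- unique(unlist(lapply(c(x, y, z), function(v) {
    names(igraph::subcomponent(g, v, mode = "in"))
  })))
  sub <- igraph::induced_subgraph(g, anc)
  # moralize: marry co-parents, then drop direction
  el <- igraph::as_edgelist(sub)
  extra <- list()
  for (v in igraph::V(sub)$name) {
    pa <- names(igraph::neighbors(sub, v, mode = "in"))
    if (length(pa) > 1) extra[[v]] <- t(utils::combn(pa, 2))
  }
  moral <- igraph::graph_from_edgelist(rbind(el, do.call(rbind, extra)),
                                       directed = FALSE)
  moral <- moral + igraph::vertices(setdiff(anc, igraph::V(moral)$name))
  moral <- igraph::delete_vertices(moral, intersect(z, igraph::V(moral)$name))
  d <- igraph::distances(moral, v = x, to = y)
  all(is.infinite(d))
}
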