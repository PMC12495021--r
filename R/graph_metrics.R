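#' Graph-level and node-level measures of a binary directed graph
#'
#' All functions take a 0/1 adjacency matrix with rows as sources and
#' columns as targets; self-loops are ignored.  Shortest-path quantities
#' use unweighted directed breadth-first distances.
#'
#' @param a 0/1 adjacency matrix.
#' @return `graph_density`: `m / (n (n - 1))`.
#' @export
graph_density <- function(a) {
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  sum(a) / (n * (n - 1))
}

check_adjacency <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  if (is.null(rownames(a))) dimnames(a) <- list(seq_len(nrow(a)), seq_len(nrow(a)))
  a
}

as_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "directed")
}

#' Node degrees
#'
#' @param a 0/1 adjacency matrix.
#' @return data frame with `node`, `in_degree`, `out_degree`,
#'   `total_degree`.
#' @export
node_degrees <- function(a) {
  a <- check_adjacency(a)
  data.frame(node = rownames(a),
             in_degree = colSums(a),
             out_degree = rowSums(a),
             total_degree = colSums(a) + rowSums(a),
             row.names = NULL)
}

#' High-degree nodes by the mean-plus-one-SD rule
#'
#' A node is flagged when its total degree exceeds the mean plus one
#' standard deviation of all total degrees.  The SD is the population
#' standard deviation (divide by `n`), a fixed documented convention.
#'
#' @param degrees data frame from [node_degrees()] (or an adjacency
#'   matrix, converted internally).
#' @return character vector of flagged node labels.
#' @export
high_degree_nodes <- function(degrees) {
  if (is.matrix(degrees)) degrees <- node_degrees(degrees)
  d <- degrees$total_degree
  thr <- mean(d) + pop_sd(d)
  degrees$node[d > thr]
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Directed (Fagiolo) clustering coefficients
#'
#' Local clustering of node `i` counts all directed triangles through `i`:
#' `C_i = ((A + A')^3)_ii / (2 * (d_i (d_i - 1) - 2 d_i^bidir))` with
#' `d_i` the total degree and `d_i^bidir` the number of reciprocated
#' neighbours.  Nodes whose denominator is zero have undefined clustering
#' (`NA`) and are excluded from the global mean.
#'
#' @param a 0/1 adjacency matrix.
#' @return `local_clustering`: named numeric vector (with `NA` for
#'   undefined nodes); `global_clustering`: mean of the defined values.
#' @export
local_clustering <- function(a) {
  a <- check_adjacency(a)
  s <- a + t(a)
  num <- diag(s %*% s %*% s)
  dtot <- rowSums(a) + colSums(a)
  dbi <- diag(a %*% a)
  den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  out <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(out, rownames(a))
}

#' @rdname local_clustering
#' @export
global_clustering <- function(a) {
  ci <- local_clustering(a)
  if (all(is.na(ci))) return(NA_real_)
  mean(ci, na.rm = TRUE)
}

#' Characteristic path length and global efficiency
#'
#' Directed shortest-path distances over all ordered node pairs.  The
#' characteristic path length averages the finite distances only
#' (unreachable pairs are excluded, so graphs with unreachable nodes still
#' yield a finite value); global efficiency averages `1/d` over all
#' ordered pairs with `1/Inf = 0`.
#'
#' @param a 0/1 adjacency matrix.
#' @return list with `char_path_length` and `global_efficiency`.
#' @export
shortest_path_stats <- function(a) {
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- igraph::distances(as_igraph(a), mode = "out")
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  cpl <- if (length(finite)) mean(finite) else {
    warning("no reachable pair; characteristic path length undefined",
            call. = FALSE)
    NA_real_
  }
  eff <- mean(ifelse(is.finite(off), 1 / off, 0))
  list(char_path_length = cpl, global_efficiency = eff)
}

#' Betweenness centrality
#'
#' Directed shortest-path betweenness with fractional counting over all
#' shortest paths (Brandes), normalized by `(n - 1)(n - 2)` so that values
#' lie in `[0, 1]`.
#'
#' @param a 0/1 adjacency matrix.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(a) {
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  b <- igraph::betweenness(as_igraph(a), directed = TRUE)
  stats::setNames(b / ((n - 1) * (n - 2)), rownames(a))
}

#' Full graph-metrics report
#'
#' Bundles density, characteristic path length, global efficiency, global
#' clustering, the per-node table (degrees, local clustering, betweenness),
#' the high-degree node set and the hub ranking.
#'
#' @param a 0/1 adjacency matrix.
#' @return object of class `graph_metrics_report`.
#' @export
graph_metrics_report <- function(a) {
  a <- check_adjacency(a)
  deg <- node_degrees(a)
  sp <- shortest_path_stats(a)
  bc <- betweenness_centrality(a)
  lc <- local_clustering(a)
  per_node <- cbind(deg, local_clustering = unname(lc), betweenness = unname(bc))
  rep <- structure(list(
    density = graph_density(a),
    char_path_length = sp$char_path_length,
    global_efficiency = sp$global_efficiency,
    global_clustering = global_clustering(a),
    per_node = per_node,
    high_degree_nodes = high_degree_nodes(deg)),
    class = "graph_metrics_report")
  rep$hubs <- find_hubs(rep)
  rep
}

#' @export
print.graph_metrics_report <- function(x, ...) {
  cat("<graph_metrics_report>\n",
      "  density:            ", round(x$density, 4), "\n",
      "  char. path length:  ", round(x$char_path_length, 4), "\n",
      "  global efficiency:  ", round(x$global_efficiency, 4), "\n",
      "  global clustering:  ", round(x$global_clustering, 4), "\n",
      "  high-degree nodes:  ", paste(x$high_degree_nodes, collapse = ", "), "\n",
      "  hubs:               ", paste(x$hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Hub nodes
#'
#' Hubs are the nodes whose total degree exceeds the mean plus one
#' (population) standard deviation, ordered by total degree and then
#' betweenness centrality (both descending), ties broken by label; the
#' first entry is "the hub" of the graph.
#'
#' @param report a [graph_metrics_report()] (or adjacency matrix).
#' @param k optional cap on the number of hubs returned.
#' @return character vector of hub labels (possibly empty).
#' @export
find_hubs <- function(report, k = Inf) {
  if (is.matrix(report)) report <- graph_metrics_report(report)
  pn <- report$per_node
  sel <- pn[pn$node %in% report$high_degree_nodes, , drop = FALSE]
  ord <- order(-sel$total_degree, -sel$betweenness, sel$node)
  hubs <- sel$node[ord]
  if (is.finite(k)) hubs <- utils::head(hubs, k)
  hubs
}
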