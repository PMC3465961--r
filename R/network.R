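## Simple undirected graph container and the Cytoscape-NetworkAnalyzer-style
## node and network metrics computed on it. All shortest-path quantities come
## from one BFS pass per source that also counts shortest paths (sigma).

#' Construct an interaction network
#'
#' Simple undirected graph over gene identifiers: no self-loops, no duplicate
#' edges, every edge endpoint a node.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column character matrix (or data frame) of edges; may be
#'   `NULL` for an edgeless graph.
#' @return Object of class `interaction_network` with elements `nodes`
#'   (character) and `edges` (two-column character matrix, endpoints sorted
#'   within each row).
#' @export
interaction_network <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed", call. = FALSE)
    if (!all(edges %in% nodes))
      stop("edge endpoint(s) not in node set: ",
           paste(setdiff(as.vector(edges), nodes), collapse = ", "),
           call. = FALSE)
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2], sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Adjacency list of a network
#' @param net An [interaction_network].
#' @return Named list mapping each node to its neighbors.
#' @export
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (n in net$nodes) adj[[n]] <- character(0)
  if (nrow(net$edges)) for (i in seq_len(nrow(net$edges))) {
    a <- net$edges[i, 1]; b <- net$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Convert to an igraph object
#' @param net An [interaction_network].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' All-pairs shortest-path distances and path counts
#'
#' Breadth-first search from every node, counting the number of distinct
#' shortest paths `sigma[s, t]` alongside the distances. Disconnected pairs
#' get distance `Inf` and path count 0.
#'
#' @param net An [interaction_network].
#' @return List with matrices `dist` and `sigma` (node x node).
#' @export
all_pairs_shortest_paths <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- adjacency_list(net)
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- d
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Node degree
#' @param net An [interaction_network].
#' @param node Node identifier, or `NULL` for all nodes.
#' @return Named numeric vector (or scalar).
#' @export
node_degree <- function(net, node = NULL) {
  deg <- lengths(adjacency_list(net))
  if (is.null(node)) return(deg)
  check_node(net, node)
  deg[[node]]
}

check_node <- function(net, node) {
  if (!node %in% net$nodes)
    stop("unknown node: ", node, call. = FALSE)
  TRUE
}

#' Clustering coefficient
#'
#' `C_n = 2 e_n / (k_n (k_n - 1))` with `e_n` the number of edges among the
#' neighbors of `n`; defined as 0 when the degree is below 2.
#'
#' @inheritParams node_degree
#' @return Numeric in `[0, 1]` (named vector for all nodes).
#' @export
clustering_coefficient <- function(net, node = NULL) {
  adj <- adjacency_list(net)
  one <- function(n) {
    nb <- adj[[n]]
    k <- length(nb)
    if (k < 2) return(0)
    e_n <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) e_n <- e_n + 1
    2 * e_n / (k * (k - 1))
  }
  if (!is.null(node)) {
    check_node(net, node)
    return(one(node))
  }
  vapply(stats::setNames(net$nodes, net$nodes), one, numeric(1))
}

## Shared pair accumulation for betweenness and stress: a pair {s,t} routes
## through n iff d(s,n) + d(n,t) = d(s,t), contributing
## sigma_sn * sigma_nt paths.
.pair_flow <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- all_pairs_shortest_paths(net)
  nodes <- net$nodes
  n <- length(nodes)
  btw <- stats::setNames(numeric(n), nodes)
  str <- stats::setNames(numeric(n), nodes)
  if (n >= 3) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- nodes[i]; t <- nodes[j]
    if (!is.finite(sp$dist[s, t])) next
    mid <- nodes[sp$dist[s, ] + sp$dist[, t] == sp$dist[s, t]]
    mid <- setdiff(mid, c(s, t))
    if (!length(mid)) next
    through <- sp$sigma[s, mid] * sp$sigma[mid, t]
    btw[mid] <- btw[mid] + through / sp$sigma[s, t]
    str[mid] <- str[mid] + through
  }
  list(betweenness = btw, stress = str)
}

#' Betweenness centrality
#'
#' Sum over unordered pairs `{s, t}` (both distinct from `n`) of the fraction
#' of shortest s-t paths passing through `n`; disconnected pairs contribute
#' 0. The normalized variant divides by `(N - 1)(N - 2) / 2`.
#'
#' @inheritParams node_degree
#' @param normalized Divide by the number of eligible pairs.
#' @return Numeric (named vector for all nodes).
#' @export
betweenness <- function(net, node = NULL, normalized = FALSE) {
  b <- .pair_flow(net)$betweenness
  if (normalized) {
    n <- length(net$nodes)
    b <- if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
  }
  if (is.null(node)) return(b)
  check_node(net, node)
  b[[node]]
}

#' Stress centrality
#'
#' Number (not fraction) of shortest paths between other node pairs passing
#' through the node.
#'
#' @inheritParams node_degree
#' @return Numeric (named vector for all nodes).
#' @export
stress <- function(net, node = NULL) {
  s <- .pair_flow(net)$stress
  if (is.null(node)) return(s)
  check_node(net, node)
  s[[node]]
}

#' Full per-node topology table
#'
#' All node-level metrics reported by Cytoscape's NetworkAnalyzer for simple
#' undirected graphs: degree, clustering coefficient, betweenness (raw and
#' normalized), closeness, eccentricity, radiality, stress, neighborhood
#' connectivity, topological coefficient, and average shortest path length.
#' Distance-based metrics are computed within the node's connected component;
#' for an isolated node closeness and radiality are `NA`.
#'
#' @param net An [interaction_network].
#' @param node Node identifier, or `NULL` for all nodes.
#' @return Data frame with one row per node.
#' @export
node_topology <- function(net, node = NULL) {
  nodes <- net$nodes
  adj <- adjacency_list(net)
  sp <- all_pairs_shortest_paths(net)
  flow <- .pair_flow(net, sp)
  deg <- lengths(adj)
  cc <- clustering_coefficient(net)
  nrm <- length(nodes)
  bnorm <- if (nrm > 2) flow$betweenness / ((nrm - 1) * (nrm - 2) / 2)
           else flow$betweenness * 0

  one <- function(n) {
    d <- sp$dist[n, ]
    reach <- d[is.finite(d) & nodes != n]
    comp <- nodes[is.finite(sp$dist[n, ])]
    delta <- if (length(comp) > 1)
      max(sp$dist[comp, comp][is.finite(sp$dist[comp, comp])]) else 0
    mean_d <- if (length(reach)) mean(reach) else NA_real_
    # topological coefficient: average over nodes sharing >= 1 neighbor
    tc <- 0
    if (deg[[n]] >= 2) {
      nb <- adj[[n]]
      shared <- vapply(setdiff(nodes, n), function(m)
        length(intersect(adj[[m]], nb)), numeric(1))
      m_set <- names(shared)[shared > 0]
      if (length(m_set)) {
        jj <- shared[m_set] + as.numeric(m_set %in% nb)
        tc <- mean(jj) / deg[[n]]
      }
    }
    data.frame(
      node = n,
      degree = deg[[n]],
      clustering = cc[[n]],
      betweenness = flow$betweenness[[n]],
      betweenness_norm = bnorm[[n]],
      closeness = if (is.na(mean_d)) NA_real_ else 1 / mean_d,
      eccentricity = if (length(reach)) max(reach) else 0,
      radiality = if (delta > 0) (delta + 1 - mean_d) / delta else NA_real_,
      stress = flow$stress[[n]],
      neighborhood_connectivity =
        if (deg[[n]] > 0) mean(deg[adj[[n]]]) else NA_real_,
      topological_coefficient = tc,
      avg_shortest_path = mean_d,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(node)) {
    check_node(net, node)
    return(one(node))
  }
  out <- do.call(rbind, lapply(nodes, one))
  rownames(out) <- NULL
  out
}

#' Network-level summary
#'
#' Node and edge counts, diameter (largest finite pairwise distance),
#' characteristic path length (mean distance over connected unordered pairs)
#' and mean number of neighbors (`2 |E| / |V|`). Disconnected graphs are
#' summarized over connected pairs with `connected = FALSE`.
#'
#' @param net An [interaction_network].
#' @return List of class `network_summary`.
#' @export
network_summary <- function(net) {
  if (length(net$nodes) == 0L) stop("empty network", call. = FALSE)
  sp <- all_pairs_shortest_paths(net)
  d <- sp$dist[upper.tri(sp$dist)]
  finite <- d[is.finite(d)]
  structure(list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    diameter = if (length(finite)) max(finite) else 0,
    characteristic_path_length = if (length(finite)) mean(finite) else NA_real_,
    mean_neighbors = 2 * nrow(net$edges) / length(net$nodes),
    connected = length(finite) == length(d)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> ", x$n_nodes, " nodes, ", x$n_edges, " edges; ",
      "diameter ", x$diameter, ", CPL ",
      signif(x$characteristic_path_length, 5),
      ", mean neighbors ", signif(x$mean_neighbors, 5),
      if (!x$connected) " (disconnected)", "\n", sep = "")
  invisible(x)
}
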