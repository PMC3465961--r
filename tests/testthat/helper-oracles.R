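# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations: shortest-path quantities
# come from exhaustive simple-path enumeration, correlations from direct
# rank/pair-counting formulas.

# All simple paths from s to t over an adjacency list (node indices).
oracle_simple_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  out
}

# Distances, shortest-path counts, betweenness and stress for a small graph
# given as an integer edge matrix over nodes 1..n.
oracle_graph_metrics <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  btw <- numeric(n)
  str <- numeric(n)
  if (n >= 2) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_simple_paths(adj, s, t)
    if (!length(paths)) next
    lens <- lengths(paths) - 1L
    d <- min(lens)
    minimal <- paths[lens == d]
    dist[s, t] <- dist[t, s] <- d
    sigma[s, t] <- sigma[t, s] <- length(minimal)
    for (v in setdiff(1:n, c(s, t))) {
      through <- sum(vapply(minimal, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(minimal)
      str[v] <- str[v] + through
    }
  }
  deg <- vapply(seq_len(n), function(v) length(adj[[v]]), numeric(1))
  clust <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    e_n <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) e_n <- e_n + 1
    2 * e_n / (k * (k - 1))
  }, numeric(1))
  list(dist = dist, sigma = sigma, betweenness = btw, stress = str,
       degree = deg, clustering = clust)
}

# interaction_network over nodes n1..n for an integer edge matrix.
net_from_int_edges <- function(n, edges) {
  nodes <- paste0("n", seq_len(n))
  interaction_network(nodes, if (nrow(edges))
    cbind(nodes[edges[, 1]], nodes[edges[, 2]]) else NULL)
}

# One representative per isomorphism class of connected graphs on <= max_n
# nodes, generated by exhaustive edge-set enumeration and canonical-form
# deduplication (the node metrics are label-invariant, which the suite
# checks separately).
enumerate_connected_classes <- function(max_n) {
  classes <- list()
  for (n in seq_len(max_n)) {
    if (n == 1) {
      classes[[length(classes) + 1L]] <-
        list(n = 1L, edges = matrix(integer(0), ncol = 2))
      next
    }
    pairs <- t(utils::combn(n, 2))
    m <- nrow(pairs)
    seen_keys <- character(0)
    for (mask in 0:(2^m - 1)) {
      sel <- which(intToBits(mask)[1:m] == as.raw(1))
      if (length(sel) < n - 1) next
      e <- pairs[sel, , drop = FALSE]
      adj <- vector("list", n)
      for (i in seq_len(nrow(e))) {
        adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
        adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
      }
      reached <- logical(n)
      reached[1] <- TRUE
      frontier <- 1L
      while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[!reached[nxt]]
        reached[nxt] <- TRUE
        frontier <- nxt
      }
      if (!all(reached)) next
      g <- igraph::graph_from_edgelist(e, directed = FALSE)
      lab <- igraph::canonical_permutation(g)$labeling
      ce <- cbind(lab[e[, 1]], lab[e[, 2]])
      ce <- t(apply(ce, 1, sort))
      ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
      key <- paste(n, paste(ce[, 1], ce[, 2], sep = "-", collapse = ","))
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      classes[[length(classes) + 1L]] <- list(n = n, edges = e)
    }
  }
  classes
}

# Correlation oracles.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Proportion of differing sites between two sequences in a 1-based window.
oracle_window_mismatch <- function(a, b, start, end) {
  av <- strsplit(substr(a, start, end), "")[[1]]
  bv <- strsplit(substr(b, start, end), "")[[1]]
  mean(av != bv)
}

# Seeded permutation helper (keeps test RNG state untouched).
local_seed_sample <- function(seed, x) {
  withr::with_seed(seed + 1000L, sample(x))
}

# Random gap-free DNA string.
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Translate a coding sequence with the package's code table.
translate_codons <- function(seq) {
  unname(genetic_code()[split_codons_for_test(seq)])
}

split_codons_for_test <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}
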