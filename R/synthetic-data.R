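## Generators for every input the pipeline consumes: codon ortholog pairs
## evolved under a Goldman-Yang-style codon model with known omega, ortholog
## pools with a heavy-tailed omega distribution, and random undirected
## graphs. All randomness is driven by an explicit integer seed and leaves
## the caller's RNG state untouched.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the codon-pair simulator
#'
#' @param length_codons Number of codons (>= 1).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_true dN/dS ratio (>= 0).
#' @param branch_length Expected substitutions per codon separating the two
#'   sequences (>= 0).
#' @param seed Integer seed.
#' @param codon_freqs Equilibrium frequencies over the 61 sense codons;
#'   `NULL` for equal frequencies.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(length_codons, kappa = 2, omega_true = 0.2,
                              branch_length = 0.5, seed = 1,
                              codon_freqs = NULL) {
  if (length_codons < 1) stop("length_codons must be >= 1", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (omega_true < 0) stop("omega_true must be >= 0", call. = FALSE)
  if (branch_length < 0) stop("branch_length must be >= 0", call. = FALSE)
  if (!is.null(codon_freqs)) {
    if (length(codon_freqs) != 61L || any(codon_freqs < 0))
      stop("codon_freqs must be 61 nonnegative values", call. = FALSE)
    codon_freqs <- codon_freqs / sum(codon_freqs)
  }
  structure(list(length_codons = as.integer(length_codons), kappa = kappa,
                 omega_true = omega_true, branch_length = branch_length,
                 seed = as.integer(seed), codon_freqs = codon_freqs),
            class = "simulation_config")
}

## Goldman-Yang instantaneous rate matrix over the 61 sense codons,
## scaled so the expected number of substitutions per codon per unit time
## is 1 (branch lengths are then in substitutions per codon).
codon_rate_matrix <- function(kappa, omega, codon_freqs = NULL) {
  tb <- codon_tables()
  n <- length(tb$sense)
  pi <- if (is.null(codon_freqs)) rep(1 / n, n) else codon_freqs
  names(pi) <- tb$sense
  Q <- matrix(0, n, n, dimnames = list(tb$sense, tb$sense))
  for (cod in tb$sense) for (nb in tb$neighbors[[cod]]) {
    if (nb$stop) next
    Q[cod, nb$to] <- pi[[nb$to]] *
      (if (nb$ts) kappa else 1) * (if (nb$syn) 1 else omega)
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu > 0) Q <- Q / mu
  list(Q = Q, pi = pi)
}

## Transition probabilities P(t) = exp(Qt) via symmetric eigendecomposition
## (the model is reversible).
codon_transition_probs <- function(Q, pi, t) {
  sq <- sqrt(pi)
  S <- (sq %o% (1 / sq)) * Q         # diag(sq) Q diag(1/sq), symmetric
  S <- (S + t(S)) / 2                # guard round-off
  eg <- eigen(S, symmetric = TRUE)
  P <- ((1 / sq) %o% sq) * (eg$vectors %*%
        (exp(eg$values * t) * t(eg$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an ortholog codon sequence pair
#'
#' Draws an ancestral sequence from the equilibrium codon frequencies and
#' evolves a descendant along a branch of `branch_length` expected
#' substitutions per codon under a Goldman-Yang-style codon model (universal
#' code, stop codons excluded from the state space), so the generated
#' sequences never contain stop codons and a true omega is known exactly.
#'
#' @param config A [simulation_config].
#' @return A [codon_pair] (`ancestor` / `descendant`).
#' @export
#' @examples
#' pair <- simulate_codon_pair(simulation_config(100, seed = 7))
simulate_codon_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tb <- codon_tables()
  rm_ <- codon_rate_matrix(config$kappa, config$omega_true, config$codon_freqs)
  L <- config$length_codons
  local_seed(config$seed, {
    anc <- sample(tb$sense, L, replace = TRUE, prob = rm_$pi)
    if (config$branch_length == 0) {
      desc <- anc
    } else {
      P <- codon_transition_probs(rm_$Q, rm_$pi, config$branch_length)
      desc <- anc
      for (state in unique(anc)) {
        idx <- which(anc == state)
        desc[idx] <- sample(tb$sense, length(idx), replace = TRUE,
                            prob = P[state, ])
      }
    }
    codon_pair(paste(anc, collapse = ""), paste(desc, collapse = ""),
               id_a = "ancestor", id_b = "descendant")
  })
}

#' Construct an ortholog pool
#'
#' Per-pair omega values with optional category tags; the population the
#' randomization null resamples from.
#'
#' @param pair_id Unique pair identifiers.
#' @param omega Finite, nonnegative dN/dS values.
#' @param tags Character vector of semicolon-separated category labels
#'   (empty string for none), recycled.
#' @return Data frame of class `ortholog_pool`.
#' @export
ortholog_pool <- function(pair_id, omega, tags = "") {
  pair_id <- as.character(pair_id)
  if (anyDuplicated(pair_id)) stop("pair_ids must be unique", call. = FALSE)
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("every omega must be finite and >= 0", call. = FALSE)
  structure(data.frame(pair_id = pair_id, omega = omega,
                       tags = rep_len(as.character(tags), length(pair_id)),
                       stringsAsFactors = FALSE),
            class = c("ortholog_pool", "data.frame"))
}

#' Does a pool entry carry a tag?
#' @param pool An [ortholog_pool].
#' @param tag_label Category label.
#' @return Logical vector over pool entries.
#' @export
pool_has_tag <- function(pool, tag_label) {
  vapply(strsplit(pool$tags, ";", fixed = TRUE),
         function(t) tag_label %in% t, logical(1))
}

#' Distribution specification for pool omega values
#'
#' @param dist `"gamma"` (heavy-tailed, parameterized by mean and shape) or
#'   `"point"` (degenerate at `mean`).
#' @param mean Distribution mean. The default 0.14 mirrors the genome-wide
#'   average dN/dS between C. elegans and P. pacificus 1:1 orthologs.
#' @param shape Gamma shape; values below 1 give the right-skewed,
#'   heavy-tailed profile typical of ortholog-wide dN/dS distributions.
#' @return List of class `omega_law`.
#' @export
omega_law <- function(dist = c("gamma", "point"), mean = 0.14, shape = 0.6) {
  dist <- match.arg(dist)
  if (mean < 0) stop("mean must be >= 0", call. = FALSE)
  if (shape <= 0) stop("shape must be positive", call. = FALSE)
  structure(list(dist = dist, mean = mean, shape = shape),
            class = "omega_law")
}

#' Simulate an ortholog pool
#'
#' Draws `n_pairs` omega values i.i.d. from `law` and tags exactly
#' `round(n_pairs * tag_fraction)` randomly chosen entries with `tag_label`.
#'
#' @param n_pairs Number of entries (>= 1).
#' @param law An [omega_law].
#' @param tag_fraction Fraction of entries carrying the tag, in `[0, 1]`.
#' @param tag_label Category label for the tagged subset.
#' @param seed Integer seed.
#' @return An [ortholog_pool].
#' @export
simulate_ortholog_pool <- function(n_pairs, law = omega_law(),
                                   tag_fraction = 0, tag_label = "Galpha",
                                   seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (tag_fraction < 0 || tag_fraction > 1)
    stop("tag_fraction must be in [0, 1]", call. = FALSE)
  local_seed(seed, {
    om <- switch(law$dist,
      gamma = stats::rgamma(n_pairs, shape = law$shape,
                            scale = law$mean / law$shape),
      point = rep(law$mean, n_pairs))
    tags <- rep("", n_pairs)
    n_tag <- round(n_pairs * tag_fraction)
    if (n_tag > 0) tags[sample.int(n_pairs, n_tag)] <- tag_label
    ortholog_pool(sprintf("pair%05d", seq_len(n_pairs)), om, tags)
  })
}

#' Simulate a random undirected network
#'
#' @param n_nodes Number of nodes (>= 1); nodes are labeled `g1 ... gn`.
#' @param model `"erdos_renyi"` (`param` = edge probability) or
#'   `"tree_plus_chords"` (random labeled tree plus `param` extra chords).
#' @param param Model parameter.
#' @param seed Integer seed.
#' @return An [interaction_network].
#' @export
simulate_network <- function(n_nodes,
                             model = c("erdos_renyi", "tree_plus_chords"),
                             param = 0.2, seed = 1) {
  model <- match.arg(model)
  if (n_nodes < 1) stop("n_nodes must be >= 1", call. = FALSE)
  nodes <- paste0("g", seq_len(n_nodes))
  local_seed(seed, {
    if (model == "erdos_renyi") {
      if (param < 0 || param > 1)
        stop("edge probability must be in [0, 1]", call. = FALSE)
      g <- igraph::sample_gnp(n_nodes, param)
      e <- igraph::as_edgelist(g)
      edges <- if (nrow(e)) cbind(nodes[e[, 1]], nodes[e[, 2]]) else NULL
    } else {
      if (n_nodes == 1) {
        edges <- NULL
      } else {
        g <- igraph::sample_tree(n_nodes, method = "lerw")
        e <- igraph::as_edgelist(g)
        edges <- cbind(nodes[e[, 1]], nodes[e[, 2]])
        key <- apply(edges, 1, function(x) paste(sort(x), collapse = "\r"))
        n_chords <- as.integer(param)
        all_pairs <- t(utils::combn(nodes, 2))
        all_key <- apply(all_pairs, 1, paste, collapse = "\r")
        free <- which(!(all_key %in% key))
        if (n_chords > 0 && length(free)) {
          pick <- free[sample.int(length(free),
                                  min(n_chords, length(free)))]
          edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
        }
      }
    }
    interaction_network(nodes, edges)
  })
}
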