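## Universal genetic code and codon-level lookup tables shared by the
## simulator and the divergence estimators. Everything here is deterministic
## and cached once per session in `.codon_env`.

NUCS <- c("T", "C", "A", "G")

#' Universal genetic code
#'
#' Named character vector mapping each of the 64 codons (DNA alphabet) to a
#' one-letter amino acid, with `"*"` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["ATG"]]  # "M"
genetic_code <- function() {
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(vapply(NUCS, function(n1)
    vapply(NUCS, function(n2) paste0(n1, n2, NUCS), character(4)),
    character(16)))
  stats::setNames(aa, codons)
}

#' Sense codons of the universal code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_transition <- function(n1, n2) {
  (n1 == "A" & n2 == "G") | (n1 == "G" & n2 == "A") |
    (n1 == "C" & n2 == "T") | (n1 == "T" & n2 == "C")
}

.codon_env <- new.env(parent = emptyenv())

## Enumerate the minimal substitution paths between two codons differing at
## `nd` positions: the nd! orders in which the differing positions can be
## changed. Paths visiting a stop codon are dropped; if every path is blocked
## the stop-free constraint is relaxed (can only happen for 3-difference
## pairs hemmed in by stops).
.codon_paths <- function(c1, c2, gc) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  nd <- length(pos)
  orders <- switch(nd,
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  build <- function(ord, allow_stop) {
    cur <- s1
    steps <- vector("list", nd)
    for (k in seq_len(nd)) {
      nxt <- cur
      nxt[ord[k]] <- s2[ord[k]]
      to <- paste(nxt, collapse = "")
      if (!allow_stop && gc[[to]] == "*" && k < nd) return(NULL)
      steps[[k]] <- list(
        from = paste(cur, collapse = ""),
        to = to,
        syn = gc[[paste(cur, collapse = "")]] == gc[[to]],
        ts = is_transition(cur[ord[k]], nxt[ord[k]])
      )
      cur <- nxt
    }
    steps
  }
  paths <- Filter(Negate(is.null), lapply(orders, build, allow_stop = FALSE))
  if (length(paths) == 0L)
    paths <- Filter(Negate(is.null), lapply(orders, build, allow_stop = TRUE))
  paths
}

## Build (once) every per-codon and per-codon-pair table used downstream:
##  - syn_sites: per-codon synonymous site count, each codon position
##    normalized over its non-stop alternatives so positions sum to 1 site
##    and a sequence of n codons always has S + N = 3n;
##  - Sd/Nd: expected synonymous/nonsynonymous differences per codon pair
##    under equal weighting of minimal paths (the NG86 convention);
##  - paths: the step-annotated minimal paths, reused by the YN00 estimator
##    with model-based path weights.
codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  n <- length(sense)

  neighbors <- lapply(sense, function(cod) {
    s <- strsplit(cod, "")[[1]]
    out <- list()
    for (p in 1:3) for (alt in setdiff(NUCS, s[p])) {
      nxt <- s
      nxt[p] <- alt
      to <- paste(nxt, collapse = "")
      out[[length(out) + 1L]] <- list(
        pos = p, to = to, stop = gc[[to]] == "*",
        syn = gc[[cod]] == gc[[to]], ts = is_transition(s[p], alt)
      )
    }
    out
  })
  names(neighbors) <- sense

  syn_sites <- vapply(sense, function(cod) {
    nb <- neighbors[[cod]]
    total <- 0
    for (p in 1:3) {
      at <- Filter(function(x) x$pos == p && !x$stop, nb)
      if (length(at) == 0L) next  # cannot occur in the universal code
      total <- total + sum(vapply(at, `[[`, logical(1), "syn")) / length(at)
    }
    total
  }, numeric(1))

  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  Nd <- Sd
  paths <- vector("list", n * n)
  dim(paths) <- c(n, n)
  dimnames(paths) <- list(sense, sense)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pth <- .codon_paths(sense[i], sense[j], gc)
    paths[[i, j]] <- pth
    syn <- vapply(pth, function(p)
      sum(vapply(p, `[[`, logical(1), "syn")), numeric(1))
    Sd[i, j] <- mean(syn)
    Nd[i, j] <- mean(lengths(pth) - syn)
  }

  .codon_env$tables <- list(
    gc = gc, sense = sense, neighbors = neighbors,
    syn_sites = syn_sites, Sd = Sd, Nd = Nd, paths = paths
  )
  .codon_env$tables
}

## Split a nucleotide string into codons; errors if not a multiple of 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
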