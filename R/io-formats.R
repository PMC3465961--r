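## Readers/writers for the plain-text formats the pipeline touches, gap
## handling for aligned pairs, and the CodonSequencePair container.

#' Construct a codon sequence pair
#'
#' A gap-free, in-frame pair of aligned coding sequences — the substrate of
#' all divergence estimates. Sequences must be equal-length, a multiple of 3,
#' over A/C/G/T, and free of internal stop codons (a terminal stop codon is
#' permitted and ignored by the estimators).
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param id_a,id_b Sequence identifiers.
#' @return An object of class `codon_pair`.
#' @export
codon_pair <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  seq_a <- normalize_seq(seq_a)
  seq_b <- normalize_seq(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences have unequal lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), ")", call. = FALSE)
  if (grepl("-", seq_a, fixed = TRUE) || grepl("-", seq_b, fixed = TRUE))
    stop("gap characters present; strip_gaps() the alignment first",
         call. = FALSE)
  if (!grepl("^[ACGT]*$", seq_a) || !grepl("^[ACGT]*$", seq_b))
    stop("sequences must contain only A, C, G, T", call. = FALSE)
  gc <- genetic_code()
  for (s in list(a = seq_a, b = seq_b)) {
    cods <- split_codons(s)
    internal <- cods[-length(cods)]
    if (any(gc[internal] == "*"))
      stop("internal stop codon in sequence", call. = FALSE)
  }
  structure(list(id_a = id_a, id_b = id_b, seq_a = seq_a, seq_b = seq_b),
            class = "codon_pair")
}

#' @export
print.codon_pair <- function(x, ...) {
  cat("<codon_pair> ", x$id_a, " / ", x$id_b, ": ",
      nchar(x$seq_a) / 3, " codons\n", sep = "")
  invisible(x)
}

normalize_seq <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

#' Read sequences from a FASTA file
#'
#' Order-preserving; sequences are upper-cased and RNA `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = FALSE),
    error = function(e)
      stop("empty or malformed FASTA file: ", path, " (", conditionMessage(e),
           ")", call. = FALSE))
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  stats::setNames(vapply(recs, function(r) normalize_seq(r[[1]]),
                         character(1)),
                  names(recs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param linewidth Characters per sequence line.
#' @export
write_fasta <- function(seqs, path, linewidth = 60L) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = linewidth)
  invisible(path)
}

#' Strip alignment gaps from a sequence pair
#'
#' `mode = "nucleotide"` removes every column where either sequence carries a
#' gap. `mode = "codon"` removes whole codon columns (frame fixed at position
#' 1) containing any gap, so the reading frame survives — the required mode
#' for divergence estimation.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (gaps as `-`).
#' @param mode `"codon"` or `"nucleotide"`.
#' @return Character vector of length 2: the de-gapped sequences.
#' @export
strip_gaps <- function(aligned_a, aligned_b, mode = c("codon", "nucleotide")) {
  mode <- match.arg(mode)
  aligned_a <- normalize_seq(aligned_a)
  aligned_b <- normalize_seq(aligned_b)
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences have unequal lengths", call. = FALSE)
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  gap <- a == "-" | b == "-"
  if (mode == "nucleotide") {
    keep <- !gap
  } else {
    n_full <- floor(length(a) / 3)
    keep <- logical(length(a))
    if (n_full > 0) {
      cod_gap <- vapply(seq_len(n_full), function(i)
        any(gap[(3 * i - 2):(3 * i)]), logical(1))
      keep[seq_len(3 * n_full)] <- rep(!cod_gap, each = 3)
    }
    # trailing partial codon (out of frame) is dropped
  }
  c(paste(a[keep], collapse = ""), paste(b[keep], collapse = ""))
}

#' Read an undirected edge list
#'
#' Accepts bare two-column pairs or three-column SIF
#' (`geneA interacts geneB`), whitespace- or tab-delimited. Duplicate and
#' reversed-duplicate edges collapse to one undirected edge with a warning;
#' self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @return An [interaction_network].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  edges <- t(vapply(parts, function(p) {
    if (length(p) == 2L) c(p[1], p[2])
    else if (length(p) == 3L) c(p[1], p[3])  # SIF: source type target
    else stop("edge line with ", length(p), " fields", call. = FALSE)
  }, character(2)))
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- apply(edges, 1, function(e) paste(sort(e), collapse = "\r"))
  if (anyDuplicated(key))
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed")
  edges <- edges[!duplicated(key), , drop = FALSE]
  interaction_network(nodes = unique(as.vector(edges)), edges = edges)
}

#' Write an undirected edge list
#'
#' @param net An [interaction_network].
#' @param path Output path.
#' @param sif Write three-column SIF (`a interacts b`) instead of two columns.
#' @export
write_edge_list <- function(net, path, sif = FALSE) {
  e <- net$edges
  lines <- if (sif) paste(e[, 1], "interacts", e[, 2], sep = "\t")
           else paste(e[, 1], e[, 2], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

.chemo_cols <- c("gene", "neuron", "assay", "ci_wt", "ci_mut", "ci_diff",
                 "n_odors")

#' Read a chemotaxis table
#'
#' Tab-delimited with columns `gene, neuron, assay, ci_wt, ci_mut, ci_diff,
#' n_odors`. `neuron` is one of AWA/AWB/AWC; `assay` is `odortaxis` or `LTA`.
#' Checks chemotaxis indices lie in `[-1, 1]` and that `ci_diff` is
#' consistent with `ci_wt - ci_mut` where both are present.
#'
#' @param path Path to the table.
#' @return A data frame of chemotaxis records.
#' @export
read_chemotaxis_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.chemo_cols, names(df))
  if (length(missing))
    stop("chemotaxis table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(abs(df$ci_wt) > 1, na.rm = TRUE))
    stop("ci_wt outside [-1, 1]", call. = FALSE)
  both <- !is.na(df$ci_mut) & !is.na(df$ci_diff)
  if (any(abs(df$ci_wt[both] - df$ci_mut[both] - df$ci_diff[both]) > 1e-9))
    stop("ci_diff inconsistent with ci_wt - ci_mut", call. = FALSE)
  df
}

#' Read an ortholog pool table
#'
#' Tab-delimited with columns `pair_id`, `omega` and an optional `tags`
#' column of semicolon-separated category labels.
#'
#' @param path Path to the table.
#' @return An [ortholog_pool].
#' @export
read_pool_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pair_id", "omega") %in% names(df)))
    stop("pool table needs columns pair_id and omega", call. = FALSE)
  ortholog_pool(df$pair_id, df$omega,
                tags = if ("tags" %in% names(df)) df$tags else "")
}

#' Write a delimited table
#'
#' Thin wrapper fixing the dialect used throughout the package: tab-separated,
#' no quotes, no row names.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
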