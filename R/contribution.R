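## Contribution metrics derived from chemotaxis assays: chemotaxis-index
## differences, the per-gene phenotype index (PI), the long-term-adaptation
## (LTA) phenotype index, the group-level weighted phenotype index (WPI),
## and the grouping schemes used to organize genes.

#' Chemotaxis index difference
#'
#' Wildtype minus mutant chemotaxis index: the behavioral deficit
#' attributable to the gene in one neuron class.
#'
#' @param ci_wt,ci_mut Chemotaxis indices in `[-1, 1]`.
#' @return `ci_wt - ci_mut`.
#' @export
#' @examples
#' ci_diff(0.9, 0.5)  # 0.4
ci_diff <- function(ci_wt, ci_mut) {
  if (any(abs(ci_wt) > 1) || any(abs(ci_mut) > 1))
    stop("chemotaxis indices must lie in [-1, 1]", call. = FALSE)
  ci_wt - ci_mut
}

#' Wildtype odortaxis chemotaxis indices
#'
#' Reference chemotaxis indices of wildtype animals per odor-sensing neuron
#' class, against which mutant deficits are normalized.
#'
#' @return Named numeric vector over AWA, AWB, AWC.
#' @export
wildtype_ci <- function() {
  c(AWA = 0.9, AWB = -0.95, AWC = 0.85)
}

#' Phenotype index for one gene
#'
#' Sum over the three odor-sensing neuron classes of the squared
#' neuron-normalized chemotaxis deficit `(ci_diff / ci_wt)^2`. Neurons
#' without a recorded assay contribute 0 (absence of evidence is treated as
#' no measured defect); the returned score carries the number of neurons
#' measured so completeness stays visible.
#'
#' @param records Data frame of chemotaxis records for a single gene, with
#'   columns `neuron` and `ci_diff` (LTA rows are scored via their
#'   `ci_diff`-ratio separately and should be excluded here).
#' @param wt_refs Named wildtype reference indices per neuron;
#'   default [wildtype_ci()].
#' @param root Return the Euclidean-norm (square-root) form instead of the
#'   printed sum-of-squares form.
#' @return List of class `contribution_score`: `gene`, `PI`, `n_neurons`.
#' @export
phenotype_index <- function(records, wt_refs = wildtype_ci(), root = FALSE) {
  if (nrow(records) == 0L)
    return(structure(list(gene = NA_character_, PI = 0, n_neurons = 0L),
                     class = "contribution_score"))
  if (anyDuplicated(records$neuron))
    stop("multiple records for one neuron", call. = FALSE)
  refs <- wt_refs[records$neuron]
  if (any(is.na(refs) | refs == 0))
    stop("zero or missing wildtype reference for neuron(s): ",
         paste(records$neuron[is.na(refs) | refs == 0], collapse = ", "),
         call. = FALSE)
  pi_val <- sum((records$ci_diff / refs)^2)
  if (root) pi_val <- sqrt(pi_val)
  gene <- if ("gene" %in% names(records)) unique(records$gene)[1]
          else NA_character_
  structure(list(gene = gene, PI = pi_val, n_neurons = nrow(records)),
            class = "contribution_score")
}

#' Long-term-adaptation phenotype index
#'
#' Fraction of the wildtype adaptation response lost in the mutant:
#' `(ci_diff_wt_lta - ci_diff_mut_lta) / ci_diff_wt_lta`. A mutant with no
#' residual adaptation response scores 1; a mutant adapting at wildtype
#' level scores 0.
#'
#' @param ci_diff_wt_lta Wildtype adaptation response (unadapted minus
#'   adapted chemotaxis index); must be nonzero.
#' @param ci_diff_mut_lta Residual adaptation response of the mutant.
#' @return Numeric phenotype index.
#' @export
#' @examples
#' lta_phenotype_index(0.6, 0)    # fully adaptation-defective: 1
#' lta_phenotype_index(0.6, 0.3)  # half-defective: 0.5
lta_phenotype_index <- function(ci_diff_wt_lta, ci_diff_mut_lta) {
  if (any(ci_diff_wt_lta == 0))
    stop("wildtype LTA response must be nonzero", call. = FALSE)
  (ci_diff_wt_lta - ci_diff_mut_lta) / ci_diff_wt_lta
}

#' Weighted phenotype index of a group
#'
#' Weight-normalized average of member phenotype indices,
#' `sum(PI * w) / sum(w)`, with `w` the number of odors for which each
#' mutant shows a phenotype.
#'
#' @param pi_values Member phenotype indices (>= 0).
#' @param weights Nonnegative weights, not all zero.
#' @param group Group label.
#' @return List of class `group_contribution`: `group`, `WPI`, `n_members`.
#' @export
weighted_phenotype_index <- function(pi_values, weights, group = NA) {
  if (length(pi_values) == 0L) stop("empty group", call. = FALSE)
  if (length(weights) != length(pi_values))
    stop("weights and pi_values differ in length", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(weights) == 0) stop("all-zero weights", call. = FALSE)
  structure(list(group = group,
                 WPI = sum(pi_values * weights) / sum(weights),
                 n_members = length(pi_values)),
            class = "group_contribution")
}

#' Per-gene phenotype index table
#'
#' Applies [phenotype_index()] to every mutant gene in a chemotaxis table
#' (odortaxis assay rows; wildtype reference rows excluded). The weight `w`
#' is taken from `n_odors` where present, defaulting to the number of
#' neurons with a recorded phenotype.
#'
#' @param chemotaxis Chemotaxis records data frame (see
#'   [read_chemotaxis_table()]).
#' @param wt_refs Named wildtype reference indices per neuron.
#' @param root Use the square-root PI form.
#' @return Data frame with columns `gene`, `PI`, `n_neurons`, `w`.
#' @export
phenotype_index_table <- function(chemotaxis, wt_refs = wildtype_ci(),
                                  root = FALSE) {
  df <- chemotaxis[chemotaxis$assay == "odortaxis" &
                     chemotaxis$gene != "wildtype", , drop = FALSE]
  genes <- unique(df$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    rec <- df[df$gene == g, , drop = FALSE]
    sc <- phenotype_index(rec, wt_refs, root = root)
    w <- if ("n_odors" %in% names(rec) && all(!is.na(rec$n_odors)))
      max(rec$n_odors) else sc$n_neurons
    data.frame(gene = g, PI = sc$PI, n_neurons = sc$n_neurons, w = w,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign genes to groups
#'
#' `scheme = "pathway_position"` uses a supplied gene-to-category map (the
#' three pathway-position classes of the odor network); `scheme =
#' "quantiles_of_metric"` cuts the metric into `k` equally populated ordered
#' bins, ties broken deterministically by gene-id order.
#'
#' @param values Named numeric vector (gene -> metric value).
#' @param scheme Binning scheme.
#' @param k Number of bins (quantile scheme).
#' @param categories Named character vector (gene -> category), required for
#'   `pathway_position`.
#' @return Named character vector of group labels.
#' @export
bin_nodes <- function(values,
                      scheme = c("pathway_position", "quantiles_of_metric"),
                      k = 3L, categories = NULL) {
  scheme <- match.arg(scheme)
  if (length(values) == 0L) stop("empty value map", call. = FALSE)
  if (scheme == "pathway_position") {
    if (is.null(categories))
      stop("pathway_position binning needs a categories map", call. = FALSE)
    missing <- setdiff(names(values), names(categories))
    if (length(missing))
      stop("no category for gene(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    return(categories[names(values)])
  }
  if (k > length(values))
    stop("more bins than genes", call. = FALSE)
  ord <- order(values, names(values))   # ties broken by gene id
  sizes <- rep(length(values) %/% k, k) +
    (seq_len(k) <= length(values) %% k)
  labels <- rep(paste0("bin", seq_len(k)), times = sizes)
  stats::setNames(labels[order(ord)], names(values))
}
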