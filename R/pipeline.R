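## End-to-end orchestration: divergence -> topology -> contribution ->
## correlation battery -> randomization, producing a reproducible report.

#' Analysis configuration
#'
#' Collects the inputs and decision flags of a full analysis run. Inputs may
#' be in-memory objects or file paths; `fixture = TRUE` preloads the
#' built-in odor-network fixture for any of network/chemotaxis/categories
#' not supplied explicitly.
#'
#' @param network An [interaction_network] or edge-list path.
#' @param chemotaxis Chemotaxis data frame, path, or `NULL` to skip the
#'   contribution stage.
#' @param pairs Named list of [codon_pair] objects (gene -> ortholog pair),
#'   or `NULL` to skip the divergence stage.
#' @param pool An [ortholog_pool], pool-table path, or `NULL` to skip the
#'   randomization stage.
#' @param categories Named character vector gene -> pathway category, or
#'   `NULL`.
#' @param fixture Preload the built-in fixture.
#' @param seed Integer seed governing every stochastic stage.
#' @param estimator Divergence estimator: `"yn00"` or `"ng86"`.
#' @param betweenness_normalized Correlate on normalized rather than raw
#'   betweenness.
#' @param pi_root Use the square-root phenotype-index form.
#' @param n_reps,set_size,constraint Randomization-null parameters (see
#'   [randomization_null()]).
#' @param replace_within_set Sampling mode of the randomization null.
#' @param aliases Named character vector mapping alternate gene ids to the
#'   ids used by the network (e.g. `c("pkg-1" = "egl-4")`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(network = NULL, chemotaxis = NULL, pairs = NULL,
                            pool = NULL, categories = NULL, fixture = FALSE,
                            seed = 1L, estimator = c("yn00", "ng86"),
                            betweenness_normalized = FALSE, pi_root = FALSE,
                            n_reps = 50000L, set_size = 16L,
                            constraint = NULL, replace_within_set = TRUE,
                            aliases = c("pkg-1" = "egl-4")) {
  estimator <- match.arg(estimator)
  if (fixture) {
    fx <- make_odor_fixture()
    network <- network %||% fx$network
    chemotaxis <- chemotaxis %||% fx$chemotaxis
    categories <- categories %||% fx$categories
  }
  if (is.character(network)) network <- read_edge_list(network)
  if (is.character(chemotaxis))
    chemotaxis <- read_chemotaxis_table(chemotaxis)
  if (is.character(pool)) pool <- read_pool_table(pool)
  if (is.null(network)) stop("an interaction network is required",
                             call. = FALSE)
  structure(list(network = network, chemotaxis = chemotaxis, pairs = pairs,
                 pool = pool, categories = categories, seed = as.integer(seed),
                 estimator = estimator,
                 betweenness_normalized = betweenness_normalized,
                 pi_root = pi_root, n_reps = as.integer(n_reps),
                 set_size = as.integer(set_size), constraint = constraint,
                 replace_within_set = replace_within_set, aliases = aliases),
            class = "analysis_config")
}

.apply_aliases <- function(ids, aliases) {
  hit <- ids %in% names(aliases)
  ids[hit] <- aliases[ids[hit]]
  ids
}

#' Run the full topology-evolution-contribution analysis
#'
#' Executes every configured stage in order: per-node topology metrics,
#' per-gene divergence estimates, phenotype indices, group-level weighted
#' phenotype indices (by pathway position and by betweenness/degree
#' tertiles), the correlation battery (each topology metric against omega
#' and against PI, by Spearman and Kendall), and the randomization null for
#' the network-mean omega. Every numeric output is reproducible from
#' (inputs, config, seed).
#'
#' @param config An [analysis_config].
#' @return List of class `analysis_report` with elements `per_node`,
#'   `per_group`, `correlations`, `randomization`, `summary`, `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  net <- config$network
  topo <- node_topology(net)
  per_node <- topo
  names(per_node)[names(per_node) == "node"] <- "gene"

  if (!is.null(config$categories)) {
    cats <- config$categories
    names(cats) <- .apply_aliases(names(cats), config$aliases)
    per_node$pathway_category <- unname(cats[per_node$gene])
  }

  ## --- divergence ---------------------------------------------------------
  if (!is.null(config$pairs)) {
    ids <- .apply_aliases(names(config$pairs), config$aliases)
    bad <- setdiff(ids, net$nodes)
    if (length(bad))
      stop("sequence pair gene id(s) not in network: ",
           paste(bad, collapse = ", "), call. = FALSE)
    est_fun <- if (config$estimator == "yn00") estimate_yn00 else estimate_ng86
    ests <- stats::setNames(lapply(config$pairs, est_fun), ids)
    div <- divergence_table(ests)
    names(div)[names(div) == "pair_id"] <- "gene"
    per_node <- merge(per_node, div[, c("gene", "dN", "dS", "omega",
                                        "kappa_hat", "flags")],
                      by = "gene", all.x = TRUE, sort = FALSE)
  }

  ## --- contribution -------------------------------------------------------
  if (!is.null(config$chemotaxis)) {
    chem <- config$chemotaxis
    chem$gene <- .apply_aliases(chem$gene, config$aliases)
    bad <- setdiff(setdiff(unique(chem$gene), "wildtype"), net$nodes)
    if (length(bad))
      stop("chemotaxis gene id(s) not in network: ",
           paste(bad, collapse = ", "), call. = FALSE)
    pit <- phenotype_index_table(chem, root = config$pi_root)
    per_node <- merge(per_node, pit, by = "gene", all.x = TRUE, sort = FALSE)
    per_node$PI[is.na(per_node$PI)] <- 0   # genes without assays
    per_node$w[is.na(per_node$w)] <- 0
  }

  per_node <- per_node[match(net$nodes, per_node$gene), , drop = FALSE]
  rownames(per_node) <- NULL

  ## --- group-level WPI ----------------------------------------------------
  per_group <- NULL
  if (!is.null(config$chemotaxis)) {
    schemes <- list()
    if (!is.null(config$categories))
      schemes$pathway_position <-
        stats::setNames(per_node$pathway_category, per_node$gene)
    for (metric in c("betweenness", "degree")) {
      v <- stats::setNames(per_node[[metric]], per_node$gene)
      schemes[[metric]] <- bin_nodes(v, "quantiles_of_metric", k = 3L)
    }
    rows <- list()
    for (sn in names(schemes)) {
      grp <- schemes[[sn]]
      for (g in unique(grp)) {
        members <- names(grp)[grp == g]
        sub <- per_node[per_node$gene %in% members, , drop = FALSE]
        keep <- sub$w > 0
        wpi <- if (any(keep))
          weighted_phenotype_index(sub$PI[keep], sub$w[keep], group = g)$WPI
          else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = sn, group = g, n_members = length(members), WPI = wpi,
          mean_omega = if ("omega" %in% names(sub))
            mean(sub$omega, na.rm = TRUE) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    per_group <- do.call(rbind, rows)
  }

  ## --- correlation battery ------------------------------------------------
  btw_col <- if (config$betweenness_normalized) "betweenness_norm"
             else "betweenness"
  metrics <- c(degree = "degree", betweenness = btw_col,
               clustering = "clustering", closeness = "closeness",
               neighborhood_connectivity = "neighborhood_connectivity")
  targets <- c(if ("omega" %in% names(per_node)) c(omega = "omega"),
               if ("PI" %in% names(per_node)) c(PI = "PI"))
  corr_rows <- list()
  for (tn in names(targets)) for (mn in names(metrics)) {
    x <- per_node[[metrics[[mn]]]]
    y <- per_node[[targets[[tn]]]]
    ok <- stats::complete.cases(x, y)
    row <- data.frame(target = tn, metric = mn, n = sum(ok),
                      spearman_rs = NA_real_, spearman_p = NA_real_,
                      kendall_tau = NA_real_, kendall_p = NA_real_,
                      flag = "", stringsAsFactors = FALSE)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      sp <- spearman(x[ok], y[ok])
      kt <- kendall_tau(x[ok], y[ok])
      row$spearman_rs <- sp$estimate
      row$spearman_p <- sp$p_value
      row$kendall_tau <- kt$estimate
      row$kendall_p <- kt$p_value
    } else row$flag <- "degenerate"
    corr_rows[[length(corr_rows) + 1L]] <- row
  }
  correlations <- if (length(corr_rows)) do.call(rbind, corr_rows)

  ## --- randomization ------------------------------------------------------
  randomization <- NULL
  if (!is.null(config$pool)) {
    obs <- if ("omega" %in% names(per_node) &&
               any(!is.na(per_node$omega)))
      network_mean_omega(per_node$omega[!is.na(per_node$omega)])
      else NA_real_
    randomization <- randomization_null(
      config$pool, set_size = config$set_size, n_reps = config$n_reps,
      constraint = config$constraint, seed = config$seed,
      observed_mean = obs,
      replace_within_set = config$replace_within_set)
  }

  structure(list(
    per_node = per_node,
    per_group = per_group,
    correlations = correlations,
    randomization = randomization,
    summary = network_summary(net),
    provenance = list(
      package_version = as.character(utils::packageVersion("odornet")),
      seed = config$seed, estimator = config$estimator,
      n_nodes = length(net$nodes), n_edges = nrow(net$edges),
      stages = c(topology = TRUE,
                 divergence = !is.null(config$pairs),
                 contribution = !is.null(config$chemotaxis),
                 randomization = !is.null(config$pool)))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", nrow(x$per_node), " genes; stages: ",
      paste(names(which(x$provenance$stages)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Delimited tables (`per_node.tsv`, `per_group.tsv`, `correlations.tsv`,
#' `null_histogram.tsv`) plus a machine-readable `summary.json`; no binary
#' formats.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @param bin_width Bin width of the null-distribution histogram.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, bin_width = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$per_node, file.path(dir, "per_node.tsv"))
  if (!is.null(report$per_group))
    write_table(report$per_group, file.path(dir, "per_group.tsv"))
  if (!is.null(report$correlations))
    write_table(report$correlations, file.path(dir, "correlations.tsv"))
  summ <- list(
    network = report$summary[c("n_nodes", "n_edges", "diameter",
                               "characteristic_path_length",
                               "mean_neighbors", "connected")],
    provenance = report$provenance)
  if (!is.null(report$randomization)) {
    rz <- report$randomization
    summ$randomization <- list(
      n_reps = rz$n_reps, set_size = rz$set_size,
      constraint = rz$constraint, seed = rz$seed,
      null_mean_of_means = rz$null_mean_of_means,
      observed_mean = rz$observed_mean, empirical_p = rz$empirical_p)
    write_table(histogram_bins(rz$null_means, bin_width),
                file.path(dir, "null_histogram.tsv"))
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
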