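## Correlation statistics used across the analysis battery and the
## constrained randomization null for network-mean dN/dS.

.check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
}

correlation_result <- function(method, estimate, p_value, n) {
  structure(list(method = method, estimate = unname(estimate),
                 p_value = unname(p_value), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", x$method, ": estimate ",
      signif(x$estimate, 4), ", p = ", signif(x$p_value, 4),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-sided
#' p-value by the t approximation, switching to the exact null distribution
#' for tie-free samples of up to 8 observations.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return A `correlation_result`.
#' @export
spearman <- function(x, y) {
  .check_xy(x, y)
  n <- length(x)
  exact <- n <= 8L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  correlation_result("spearman", ct$estimate, ct$p.value, n)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau; two-sided p-value by the normal approximation, exact
#' for tie-free samples of up to 8 observations.
#'
#' @inheritParams spearman
#' @return A `correlation_result`.
#' @export
kendall_tau <- function(x, y) {
  .check_xy(x, y)
  n <- length(x)
  exact <- n <= 8L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = exact))
  correlation_result("kendall", ct$estimate, ct$p.value, n)
}

#' Pearson correlation and coefficient of determination
#'
#' @inheritParams spearman
#' @return List with `r` and `r_squared`.
#' @export
pearson_r2 <- function(x, y) {
  .check_xy(x, y)
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Randomization null for a network-mean omega
#'
#' Each replicate assembles a random gene set of `set_size` entries drawn
#' from the pool with replacement and records its mean omega. Under a
#' composition constraint `(tag_label, required_count)` exactly
#' `required_count` draws come from tagged entries and the remainder from
#' untagged entries (both with replacement), mirroring a fixed number of
#' Galpha-subunit genes per set. The one-sided empirical p-value for an
#' observed mean below the null (stronger purifying selection than random
#' sets) uses the add-one rule `(1 + #[null <= observed]) / (1 + n_reps)`
#' and so is never 0.
#'
#' @param pool An [ortholog_pool] (or data frame with `omega` and `tags`).
#' @param set_size Genes per replicate set.
#' @param n_reps Number of replicates.
#' @param constraint `NULL`, or `list(tag_label =, required_count =)`.
#' @param seed Integer seed.
#' @param observed_mean Observed network-mean omega to test, or `NA`.
#' @param replace_within_set With-replacement draws within each set (the
#'   default); `FALSE` samples each set without replacement.
#' @return Object of class `randomization_result`: `null_means`,
#'   `null_mean_of_means`, `observed_mean`, `empirical_p`, plus the run
#'   parameters.
#' @export
randomization_null <- function(pool, set_size = 16L, n_reps = 50000L,
                               constraint = NULL, seed = 1L,
                               observed_mean = NA_real_,
                               replace_within_set = TRUE) {
  if (set_size < 1L) stop("set_size must be >= 1", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  om <- pool$omega
  if (!is.null(constraint)) {
    if (is.null(constraint$tag_label) || is.null(constraint$required_count))
      stop("constraint needs tag_label and required_count", call. = FALSE)
    tagged <- pool_has_tag(pool, constraint$tag_label)
    k <- as.integer(constraint$required_count)
    if (k > 0 && !any(tagged))
      stop("constraint unsatisfiable: no entries tagged '",
           constraint$tag_label, "'", call. = FALSE)
    if (k > set_size)
      stop("required_count exceeds set_size", call. = FALSE)
    if (set_size - k > 0 && !any(!tagged))
      stop("constraint unsatisfiable: no untagged entries", call. = FALSE)
  }
  null_means <- local_seed(seed, {
    if (is.null(constraint)) {
      if (replace_within_set) {
        colMeans(matrix(sample(om, set_size * n_reps, replace = TRUE),
                        nrow = set_size))
      } else {
        if (set_size > length(om))
          stop("set_size exceeds pool size for without-replacement draws",
               call. = FALSE)
        vapply(seq_len(n_reps),
               function(i) mean(om[sample.int(length(om), set_size)]),
               numeric(1))
      }
    } else {
      k <- as.integer(constraint$required_count)
      tagged <- pool_has_tag(pool, constraint$tag_label)
      om_t <- om[tagged]
      om_u <- om[!tagged]
      draw_part <- function(vals, m) {
        if (m == 0L) return(numeric(n_reps))
        if (replace_within_set) {
          colSums(matrix(sample(vals, m * n_reps, replace = TRUE), nrow = m))
        } else {
          if (m > length(vals))
            stop("constraint exceeds available entries for ",
                 "without-replacement draws", call. = FALSE)
          vapply(seq_len(n_reps),
                 function(i) sum(vals[sample.int(length(vals), m)]),
                 numeric(1))
        }
      }
      (draw_part(om_t, k) + draw_part(om_u, set_size - k)) / set_size
    }
  })
  structure(list(
    n_reps = as.integer(n_reps), set_size = as.integer(set_size),
    constraint = constraint, seed = as.integer(seed),
    null_means = null_means,
    null_mean_of_means = mean(null_means),
    observed_mean = observed_mean,
    empirical_p = if (is.na(observed_mean)) NA_real_
                  else (1 + sum(null_means <= observed_mean)) / (1 + n_reps)
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result> ", x$n_reps, " sets of ", x$set_size,
      if (!is.null(x$constraint))
        paste0(" (", x$constraint$required_count, " x '",
               x$constraint$tag_label, "')"),
      "; null mean of means ", signif(x$null_mean_of_means, 4), sep = "")
  if (!is.na(x$observed_mean))
    cat("; observed ", signif(x$observed_mean, 4),
        ", empirical p = ", signif(x$empirical_p, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Bin values into an equal-width frequency table
#'
#' Half-open bins `[lo, hi)` of width `bin_width`, anchored at
#' `floor(min / bin_width) * bin_width`; the maximum falls in the last bin.
#' Counts always sum to the number of values.
#'
#' @param values Nonempty numeric vector (e.g. null means).
#' @param bin_width Positive bin width.
#' @return Data frame with columns `lo`, `hi`, `mid`, `count`.
#' @export
histogram_bins <- function(values, bin_width) {
  if (length(values) == 0L) stop("no values to bin", call. = FALSE)
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  lo0 <- floor(min(values) / bin_width) * bin_width
  idx <- pmin(floor((values - lo0) / bin_width),
              floor((max(values) - lo0) / bin_width))
  tab <- table(factor(idx, levels = 0:max(idx)))
  lo <- lo0 + as.numeric(names(tab)) * bin_width
  data.frame(lo = lo, hi = lo + bin_width, mid = lo + bin_width / 2,
             count = as.integer(tab))
}
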