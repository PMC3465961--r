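## Nucleotide diversity (pi) and its sliding-window profile along an
## alignment. For the two-sequence interspecies case pi reduces to the
## proportion of differing sites, which is the default pipeline path.

.seq_matrix <- function(sequences) {
  sequences <- vapply(sequences, normalize_seq, character(1))
  if (length(sequences) < 2L)
    stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths", call. = FALSE)
  if (lens[1] < 1L) stop("sequences are empty", call. = FALSE)
  do.call(rbind, strsplit(sequences, ""))
}

.pi_on_matrix <- function(mat) {
  n <- nrow(mat)
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  total <- 0
  count <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]   # ambiguity-free columns for this pair
    if (!any(ok)) next
    total <- total + sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    count <- count + 1L
  }
  if (count == 0L) return(NA_real_)
  total / count
}

#' Nucleotide diversity
#'
#' Average over all unordered sequence pairs of the proportion of differing
#' sites. Sites carrying an ambiguity code in either member of a pair are
#' excluded from both numerator and denominator for that pair.
#'
#' @param sequences Character vector of >= 2 equal-length, gap-free
#'   sequences.
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' pairwise_pi(c("AAAA", "AAAT"))  # 0.25
pairwise_pi <- function(sequences) {
  .pi_on_matrix(.seq_matrix(sequences))
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows start at positions `1, 1 + step, 1 + 2 step, ...`; only full
#' windows are emitted (a trailing partial window is dropped). Defaults
#' match the 100-bp window / 20-bp step scan used for coding-region
#' diversity profiles.
#'
#' @param sequences Character vector of >= 2 equal-length sequences.
#' @param window Window width in base pairs.
#' @param step Increment between window starts.
#' @return Object of class `diversity_profile`: list with `windows` (data
#'   frame `start`, `end`, `midpoint`, `pi`), `global_pi`, `window`, `step`.
#' @export
sliding_window_pi <- function(sequences, window = 100L, step = 20L) {
  if (window < 1L || step < 1L)
    stop("window and step must be >= 1", call. = FALSE)
  mat <- .seq_matrix(sequences)
  len <- ncol(mat)
  if (len < window)
    stop("alignment (", len, " bp) shorter than one window (", window,
         " bp)", call. = FALSE)
  window <- as.integer(window)
  step <- as.integer(step)
  starts <- seq.int(1L, len - window + 1L, by = step)
  wins <- data.frame(
    start = starts,
    end = starts + window - 1L,
    midpoint = starts + (window - 1) / 2,
    pi = vapply(starts, function(s)
      .pi_on_matrix(mat[, s:(s + window - 1L), drop = FALSE]), numeric(1))
  )
  structure(list(windows = wins, global_pi = .pi_on_matrix(mat),
                 window = as.integer(window), step = as.integer(step)),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("<diversity_profile> ", nrow(x$windows), " windows (", x$window,
      " bp / step ", x$step, "), global pi = ", signif(x$global_pi, 5),
      "\n", sep = "")
  invisible(x)
}
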