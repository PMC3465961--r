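## Pairwise codon-level divergence: synonymous (dS) and nonsynonymous (dN)
## substitution rates and omega = dN/dS, by two routes.
##
## NG86 (Nei & Gojobori 1986): mutation-opportunity site counting per codon,
## equal weighting of all minimal substitution paths between differing
## codons, Jukes-Cantor correction of the two proportions.
##
## YN00 (Yang & Nielsen 2000, approximate method): F3x4 codon frequencies
## estimated from the pair, kappa from fourfold-degenerate vs nondegenerate
## sites, site counts and path weights under the HKY-type mutation model,
## omega-dependent path weighting iterated to convergence, K80-style
## two-parameter correction applied separately to synonymous and
## nonsynonymous divergence.

divergence_estimate <- function(method, dN, dS, omega, kappa_hat,
                                S_sites, N_sites, Sd, Nd,
                                flags = character(0)) {
  structure(list(method = method, dN = dN, dS = dS, omega = omega,
                 kappa_hat = kappa_hat, S_sites = S_sites, N_sites = N_sites,
                 Sd = Sd, Nd = Nd, flags = flags),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("<divergence_estimate ", x$method, "> dN=", signif(x$dN, 5),
      " dS=", signif(x$dS, 5), " omega=", signif(x$omega, 5),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

## Codon columns used for estimation: drop any column where either codon is
## a stop (only a terminal stop can pass the codon_pair validator).
.pair_codons <- function(pair) {
  gc <- genetic_code()
  ca <- split_codons(pair$seq_a)
  cb <- split_codons(pair$seq_b)
  keep <- gc[ca] != "*" & gc[cb] != "*"
  list(a = ca[keep], b = cb[keep])
}

jc_correct <- function(p) {
  if (p < 1e-12) return(list(d = 0, saturated = FALSE))
  if (p >= 0.75) return(list(d = NA_real_, saturated = TRUE))
  list(d = -0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' Nei-Gojobori (1986) divergence estimate
#'
#' Counting method: each codon position contributes one site split between
#' synonymous and nonsynonymous in proportion to the fraction of its
#' non-stop single-nucleotide changes that are synonymous (so `S + N = 3n`
#' exactly); differences are averaged over all minimal substitution paths
#' with equal weights (stop-codon-crossing paths excluded); the Jukes-Cantor
#' correction converts proportions to distances.
#'
#' @param pair A [codon_pair].
#' @return A `divergence_estimate` (method `"NG86"`). `omega` is `NA` with
#'   flag `"undefined_omega"` when `dS = 0`; a proportion at or beyond the
#'   correction's domain yields `NA` with flag `"saturated"`.
#' @export
estimate_ng86 <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  tb <- codon_tables()
  cod <- .pair_codons(pair)
  n <- length(cod$a)
  if (n == 0L) stop("no usable codons", call. = FALSE)
  S <- (sum(tb$syn_sites[cod$a]) + sum(tb$syn_sites[cod$b])) / 2
  N <- 3 * n - S
  diff <- cod$a != cod$b
  Sd <- sum(tb$Sd[cbind(cod$a[diff], cod$b[diff])])
  Nd <- sum(tb$Nd[cbind(cod$a[diff], cod$b[diff])])
  ps <- jc_correct(Sd / S)
  pn <- jc_correct(Nd / N)
  flags <- character(0)
  if (ps$saturated || pn$saturated) flags <- c(flags, "saturated")
  dS <- ps$d
  dN <- pn$d
  omega <- if (is.na(dS) || is.na(dN)) NA_real_
           else if (dS == 0) NA_real_ else dN / dS
  if (!is.na(dS) && dS == 0 && !is.na(dN) && dN > 0)
    flags <- c(flags, "undefined_omega")
  if (!is.na(dS) && dS == 0 && !is.na(dN) && dN == 0) omega <- 0
  divergence_estimate("NG86", dN, dS, omega, NA_real_, S, N, Sd, Nd, flags)
}

## F3x4: position-specific nucleotide frequencies pooled over both
## sequences, normalized over sense codons.
.f3x4_freqs <- function(cod) {
  tb <- codon_tables()
  all_cod <- c(cod$a, cod$b)
  mat <- do.call(rbind, strsplit(all_cod, ""))
  f <- lapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = NUCS))
    as.numeric(tab) / sum(tab)
  })
  pi <- vapply(tb$sense, function(codon) {
    s <- strsplit(codon, "")[[1]]
    f[[1]][match(s[1], NUCS)] * f[[2]][match(s[2], NUCS)] *
      f[[3]][match(s[3], NUCS)]
  }, numeric(1))
  if (sum(pi) == 0) pi[] <- 1
  pi / sum(pi)
}

## Degeneracy class of each position of a codon: 0 = no change synonymous,
## 4 = every change synonymous, 2 otherwise.
.degeneracy <- function() {
  tb <- codon_tables()
  out <- matrix(2L, length(tb$sense), 3, dimnames = list(tb$sense, NULL))
  for (cod in tb$sense) for (p in 1:3) {
    at <- Filter(function(x) x$pos == p, tb$neighbors[[cod]])
    syn <- vapply(at, `[[`, logical(1), "syn")
    stp <- vapply(at, `[[`, logical(1), "stop")
    syn_ok <- syn[!stp]
    out[cod, p] <- if (length(syn_ok) && all(syn_ok) && !any(stp)) 4L
                   else if (!any(syn)) 0L else 2L
  }
  out
}

k80_distance <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(list(d = NA_real_, ts = NA_real_, tv = NA_real_,
                saturated = TRUE))
  ts <- -0.5 * log(a1) + 0.25 * log(a2)
  tv <- -0.5 * log(a2)
  list(d = ts + tv, ts = ts, tv = tv, saturated = FALSE)
}

## kappa from fourfold-degenerate and nondegenerate sites: K80 transition and
## transversion distances are computed within each class and combined with
## weights proportional to the class site counts; kappa is twice the
## ts/tv distance ratio (one transition vs two transversion alternatives
## per site). Falls back to kappa = 1 (flagged) when inestimable.
.estimate_kappa <- function(cod) {
  deg <- .codon_env$degeneracy %||% (.codon_env$degeneracy <- .degeneracy())
  ts_cnt <- c(`0` = 0, `4` = 0)
  tv_cnt <- c(`0` = 0, `4` = 0)
  tot <- c(`0` = 0, `4` = 0)
  for (i in seq_along(cod$a)) {
    sa <- strsplit(cod$a[i], "")[[1]]
    sb <- strsplit(cod$b[i], "")[[1]]
    for (p in 1:3) {
      da <- deg[cod$a[i], p]
      db <- deg[cod$b[i], p]
      if (da != db || da == 2L) next
      cls <- as.character(da)
      tot[cls] <- tot[cls] + 1
      if (sa[p] != sb[p]) {
        if (is_transition(sa[p], sb[p])) ts_cnt[cls] <- ts_cnt[cls] + 1
        else tv_cnt[cls] <- tv_cnt[cls] + 1
      }
    }
  }
  usable <- tot > 0
  if (!any(usable)) return(list(kappa = 1, flag = "kappa_fallback"))
  ts_d <- 0; tv_d <- 0; wsum <- 0; sat <- FALSE
  for (cls in names(tot)[usable]) {
    k <- k80_distance(ts_cnt[cls] / tot[cls], tv_cnt[cls] / tot[cls])
    if (k$saturated) { sat <- TRUE; next }
    ts_d <- ts_d + tot[cls] * k$ts
    tv_d <- tv_d + tot[cls] * k$tv
    wsum <- wsum + tot[cls]
  }
  if (wsum == 0 || tv_d <= 0)
    return(list(kappa = 1,
                flag = if (sat) "kappa_fallback_saturated"
                       else "kappa_fallback"))
  list(kappa = max(2 * ts_d / tv_d, 1e-6), flag = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Site counts under the mutation model: each position of each observed
## codon contributes sites split by rate-weighted opportunity
## (pi_target * kappa^is_ts), averaged over the two sequences.
.yn00_sites <- function(cod, kappa, pi) {
  tb <- codon_tables()
  site_one <- function(codon) {
    total <- 0
    for (p in 1:3) {
      at <- Filter(function(x) x$pos == p && !x$stop, tb$neighbors[[codon]])
      w <- vapply(at, function(x)
        pi[[x$to]] * (if (x$ts) kappa else 1), numeric(1))
      if (sum(w) == 0) next
      total <- total + sum(w[vapply(at, `[[`, logical(1), "syn")]) / sum(w)
    }
    total
  }
  key <- unique(c(cod$a, cod$b))
  per <- vapply(key, site_one, numeric(1))
  S <- (sum(per[cod$a]) + sum(per[cod$b])) / 2
  list(S = S, N = 3 * length(cod$a) - S)
}

## Expected difference counts with omega-dependent path weighting: each
## minimal path between a differing codon pair gets weight equal to the
## product of its step rates (pi_target * kappa^ts * omega^nonsyn); the
## normalized weights apportion transitions/transversions within
## synonymous and nonsynonymous differences.
.yn00_differences <- function(cod, kappa, omega, pi) {
  tb <- codon_tables()
  omega_w <- max(omega, 1e-10)
  acc <- c(syn_ts = 0, syn_tv = 0, nsyn_ts = 0, nsyn_tv = 0)
  for (i in which(cod$a != cod$b)) {
    paths <- tb$paths[[cod$a[i], cod$b[i]]]
    w <- numeric(length(paths))
    contrib <- matrix(0, length(paths), 4)
    for (k in seq_along(paths)) {
      pw <- 1
      for (st in paths[[k]]) {
        pw <- pw * pi[[st$to]] * (if (st$ts) kappa else 1) *
          (if (st$syn) 1 else omega_w)
        col <- 1 + (!st$syn) * 2 + (!st$ts)
        contrib[k, col] <- contrib[k, col] + 1
      }
      w[k] <- pw
    }
    if (sum(w) == 0) w[] <- 1
    w <- w / sum(w)
    acc <- acc + colSums(contrib * w)
  }
  acc
}

#' Yang-Nielsen (2000) divergence estimate
#'
#' Approximate pairwise method: codon frequencies from F3x4 estimated from
#' the pair (equal frequencies available via `equal_freqs`), kappa from
#' fourfold-degenerate and nondegenerate sites, mutation-opportunity site
#' counting weighted by kappa and codon frequencies, minimal-path difference
#' counting with omega-dependent path weights iterated to convergence
#' (start omega = 1, tolerance `1e-6`, 100 iterations), and K80-style
#' correction of synonymous and nonsynonymous divergence for multiple hits.
#'
#' @param pair A [codon_pair].
#' @param equal_freqs Use equal codon frequencies instead of F3x4.
#' @return A `divergence_estimate` (method `"YN00"`). Saturation and
#'   non-convergence are flagged; `omega` is `NA` when `dS` is 0 or
#'   unestimable.
#' @export
estimate_yn00 <- function(pair, equal_freqs = FALSE) {
  stopifnot(inherits(pair, "codon_pair"))
  tb <- codon_tables()
  cod <- .pair_codons(pair)
  n <- length(cod$a)
  if (n == 0L) stop("no usable codons", call. = FALSE)
  pi <- if (equal_freqs)
    stats::setNames(rep(1 / 61, 61), tb$sense) else .f3x4_freqs(cod)
  kap <- .estimate_kappa(cod)
  flags <- kap$flag
  sites <- .yn00_sites(cod, kap$kappa, pi)

  if (all(cod$a == cod$b)) {
    return(divergence_estimate("YN00", 0, 0, 0, kap$kappa,
                               sites$S, sites$N, 0, 0,
                               flags %||% character(0)))
  }

  omega <- 1
  dN <- dS <- NA_real_
  Sd <- Nd <- NA_real_
  converged <- FALSE
  saturated <- FALSE
  for (iter in seq_len(100)) {
    d <- .yn00_differences(cod, kap$kappa, omega, pi)
    Sd <- d[["syn_ts"]] + d[["syn_tv"]]
    Nd <- d[["nsyn_ts"]] + d[["nsyn_tv"]]
    ks <- k80_distance(d[["syn_ts"]] / sites$S, d[["syn_tv"]] / sites$S)
    kn <- k80_distance(d[["nsyn_ts"]] / sites$N, d[["nsyn_tv"]] / sites$N)
    dS <- ks$d
    dN <- kn$d
    if (ks$saturated || kn$saturated) { saturated <- TRUE; break }
    if (dS == 0) break
    omega_new <- dN / dS
    if (abs(omega_new - omega) < 1e-6) {
      omega <- omega_new
      converged <- TRUE
      break
    }
    omega <- omega_new
  }
  if (saturated) flags <- c(flags, "saturated")
  else if (!converged && !(is.na(dS) || dS == 0))
    flags <- c(flags, "nonconverged")
  omega_out <- if (is.na(dS) || is.na(dN)) NA_real_
               else if (dS == 0) {
                 if (dN == 0) 0 else NA_real_
               } else dN / dS
  if (!is.na(dS) && dS == 0 && !is.na(dN) && dN > 0)
    flags <- c(flags, "undefined_omega")
  divergence_estimate("YN00", dN, dS, omega_out, kap$kappa,
                      sites$S, sites$N, Sd, Nd, flags %||% character(0))
}

#' Mean omega across a set of divergence estimates
#'
#' Arithmetic mean of per-pair omega values; undefined (flagged `NA`)
#' entries are excluded with a message reporting how many.
#'
#' @param estimates List of `divergence_estimate` objects, or a numeric
#'   vector of omega values.
#' @return Numeric scalar.
#' @export
network_mean_omega <- function(estimates) {
  om <- if (is.numeric(estimates)) estimates
        else vapply(estimates, function(e) e$omega, numeric(1))
  if (length(om) == 0L) stop("no estimates supplied", call. = FALSE)
  n_bad <- sum(is.na(om))
  if (n_bad == length(om))
    stop("all omega values are undefined", call. = FALSE)
  if (n_bad > 0)
    message(n_bad, " undefined omega value(s) excluded from the mean")
  mean(om, na.rm = TRUE)
}

#' Tabulate divergence estimates
#'
#' @param estimates Named list of `divergence_estimate` objects.
#' @return Data frame with one row per pair.
#' @export
divergence_table <- function(estimates) {
  ids <- names(estimates) %||% as.character(seq_along(estimates))
  do.call(rbind, lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(pair_id = ids[i], method = e$method, dN = e$dN, dS = e$dS,
               omega = e$omega, kappa_hat = e$kappa_hat,
               S_sites = e$S_sites, N_sites = e$N_sites,
               Sd = e$Sd, Nd = e$Nd,
               flags = paste(e$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
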