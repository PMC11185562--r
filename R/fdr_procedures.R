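## Reference FDR-control procedures that entrapment experiments audit:
## target-decoy competition (TDC), the PSM-and-peptide double competition,
## and decoy-based empirical p-values with BH or Storey adjustment.

## Rank pairs by decreasing score, shuffling exact ties with `seed` so tdc
## and tdcQvalues agree on the ordering.
tdcOrder <- function(w, seed) {
  jitter <- withSeed(seed, sample.int(length(w)))
  order(-w, jitter)
}

#' Target-decoy competition
#'
#' Sorts the (score, label) pairs by decreasing score (exact ties shuffled
#' by `seed`), finds the largest rank `K` with
#' `(D_K + 1) / max(T_K, 1) <= alpha`, where `D_k`/`T_k` count decoys and
#' targets among the top `k`, and reports all targets among the top `K`.
#'
#' @param w numeric scores (larger is better).
#' @param l labels, `+1` for target, `-1` for decoy.
#' @param alpha desired FDR level in (0, 1).
#' @param id optional identifiers (defaults to indices).
#' @param seed tie-break seed.
#' @return A list with class `"TdcResult"`: `alpha`, `K`, `d_k`, `t_k`
#'   (decoy/target counts among the top K), and `reported` (target ids).
#' @examples
#' tdc(w = 7:1, l = c(1, 1, -1, 1, 1, -1, 1), alpha = 0.5)
#' @export
tdc <- function(w, l, alpha, id = NULL, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (length(w) != length(l)) stop("w and l lengths differ", call. = FALSE)
  if (!all(l %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (is.null(id)) id <- as.character(seq_along(w))
  if (!length(w))
    return(structure(list(alpha = alpha, K = 0L, d_k = 0L, t_k = 0L,
                          reported = character()), class = "TdcResult"))
  ord <- tdcOrder(w, seed)
  ls <- l[ord]
  D <- cumsum(ls == -1)
  T <- seq_along(ls) - D
  ratio <- (D + 1) / pmax(T, 1)
  pass <- which(ratio <= alpha)
  K <- if (length(pass)) max(pass) else 0L
  structure(list(alpha = alpha, K = K,
                 d_k = if (K) D[K] else 0L,
                 t_k = if (K) T[K] else 0L,
                 reported = if (K) id[ord][seq_len(K)][ls[seq_len(K)] == 1]
                            else character()),
            class = "TdcResult")
}

#' Per-target q-values from target-decoy competition
#'
#' Inverts the TDC rejection rule: the q-value of the pair at rank `k` is
#' the minimum over ranks `k' >= k` of `(D_k' + 1) / max(T_k', 1)`, capped
#' at 1.  Thresholding these q-values at any `alpha` reproduces
#' [tdc()] exactly (given the same `seed`).
#'
#' @inheritParams tdc
#' @return Numeric q-values aligned with the input order (decoy positions
#'   receive the q-value of their rank too, for convenience).
#' @export
tdcQvalues <- function(w, l, seed = NULL) {
  if (length(w) != length(l)) stop("w and l lengths differ", call. = FALSE)
  if (!all(l %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (!length(w)) return(numeric())
  ord <- tdcOrder(w, seed)
  ls <- l[ord]
  D <- cumsum(ls == -1)
  T <- seq_along(ls) - D
  ratio <- (D + 1) / pmax(T, 1)
  q <- pmin(rev(cummin(rev(ratio))), 1)
  out <- numeric(length(w))
  out[ord] <- q
  out
}

#' PSM-and-peptide double competition
#'
#' Peptide-level TDC preprocessing.  Stage 1: for each spectrum keep only
#' its best-scoring PSM (ties broken randomly).  Stage 2: each target or
#' decoy peptide is scored by the maximum over its surviving PSMs; a
#' peptide with no surviving PSM scores `-Inf`.  Stage 3: within each
#' target-decoy pair only the higher-scoring peptide survives (ties broken
#' randomly), yielding the winner's score `W` and label `L = +1/-1` ready
#' for [tdc()].
#'
#' @param psms data.frame with columns `spectrum_id`, `peptide`,
#'   `peptide_class` (`"target"`/`"decoy"`), `score`.
#' @param pairing data.frame with columns `target`, `decoy` (one row per
#'   pair), or a shuffled-mode r = 1 [PairedEntrapmentDB-class] whose
#'   entrapments act as the decoys.
#' @param seed tie-break seed.
#' @return data.frame with columns `id` (the pair's target peptide), `w`,
#'   `l`, one row per pair.
#' @export
psmAndPeptide <- function(psms, pairing, seed = NULL) {
  need <- c("spectrum_id", "peptide", "peptide_class", "score")
  if (!all(need %in% names(psms)))
    stop("psms must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is(pairing, "PairedEntrapmentDB")) {
    if (pairing@mode != "shuffled" || round(pairing@r) != 1L)
      stop("pairing database must be shuffled mode with r = 1",
           call. = FALSE)
    pairing <- data.frame(target = pairing@pairs$target,
                          decoy = pairing@pairs$entrapment)
  }
  known <- c(pairing$target, pairing$decoy)
  bad <- setdiff(unique(psms$peptide), known)
  if (length(bad))
    stop("PSM peptides missing from the pairing: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  withSeed(seed, {
    ## stage 1: best PSM per spectrum, ties random
    ord <- order(psms$spectrum_id, -psms$score,
                 sample.int(nrow(psms)))
    best <- psms[ord, ][!duplicated(psms$spectrum_id[ord]), ]
    ## stage 2: peptide score = max over surviving PSMs, else -Inf
    pepScore <- function(p) {
      s <- best$score[best$peptide == p]
      if (length(s)) max(s) else -Inf
    }
    ts <- vapply(pairing$target, pepScore, numeric(1))
    ds <- vapply(pairing$decoy, pepScore, numeric(1))
    ## stage 3: pair competition, ties random
    coin <- runif(nrow(pairing)) < 0.5
    target_wins <- ts > ds | (ts == ds & coin)
    data.frame(id = pairing$target,
               w = pmax(ts, ds),
               l = ifelse(target_wins, 1, -1),
               stringsAsFactors = FALSE)
  })
}

#' Decoy-based empirical p-values
#'
#' The p-value of a target score `t` is the proportion of decoy scores at
#' least as high: `#\{d >= t\} / #decoys`.  This literal definition can
#' yield p = 0; `pseudoCount = TRUE` computes
#' `(1 + #\{d >= t\}) / (1 + #decoys)` instead.
#'
#' @param targetScores numeric target peptide scores.
#' @param decoyScores numeric decoy peptide scores (non-empty).
#' @param pseudoCount use the add-one variant.
#' @return Numeric p-values aligned with `targetScores`.
#' @examples
#' empiricalPvalues(10, c(12, 8, 5, 3))   # 0.25
#' @export
empiricalPvalues <- function(targetScores, decoyScores,
                             pseudoCount = FALSE) {
  if (!length(decoyScores)) stop("need at least one decoy score",
                                 call. = FALSE)
  d <- sort(decoyScores)
  n <- length(d)
  ## #\{d >= t\} = n - #\{d < t\}
  ge <- n - findInterval(targetScores, d, left.open = TRUE)
  if (pseudoCount) (1 + ge) / (1 + n) else ge / n
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment of a p-value vector (via
#' `stats::p.adjust(method = "BH")`), with input validation.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @examples
#' bhAdjust(c(0.005, 0.1))   # 0.01 0.10
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution over a
#' lambda grid -- `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`,
#' smoothed with a cubic spline (df = 3) and evaluated at the largest
#' lambda, as in the default smoother of the canonical implementation --
#' and returns `pi0` times the BH-style cumulative-minimum q-values.  With
#' `pi0 = 1` the result equals [bhAdjust()].
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param lambda grid of tuning values in `[0, 1)`; a single value skips
#'   the smoother.
#' @return q-values in input order, with attribute `"pi0"`.
#' @export
storeyQvalues <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  lambda <- sort(lambda)
  if (all(pvalues <= min(lambda))) {
    warning("degenerate p-value distribution; falling back to pi0 = 1",
            call. = FALSE)
    pi0 <- 1
  } else if (length(lambda) == 1L) {
    pi0 <- sum(pvalues > lambda) / (m * (1 - lambda))
  } else {
    pi0l <- vapply(lambda, function(lam)
      sum(pvalues > lam) / (m * (1 - lam)), numeric(1))
    fit <- smooth.spline(lambda, pi0l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
  }
  if (!is.finite(pi0) || pi0 <= 0) {
    warning("pi0 estimate not positive; falling back to pi0 = 1",
            call. = FALSE)
    pi0 <- 1
  }
  pi0 <- min(pi0, 1)
  ord <- order(pvalues)
  q_sorted <- pi0 * pvalues[ord] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(q_sorted))), 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  attr(out, "pi0") <- pi0
  out
}
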