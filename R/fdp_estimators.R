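## The four entrapment FDP estimators (combined, lower bound, sample,
## paired) plus the k-matched generalization, FDP-vs-threshold curves,
## coverage bands, inflation rates and the double-entrapment direct
## estimate.

cap1 <- function(x) {
  out <- pmin(x, 1)
  attr(out, "raw") <- x
  out
}

#' Combined entrapment estimate of the FDP
#'
#' Estimates the FDP among the pooled original-target + entrapment
#' discoveries, accounting for the effective entrapment-to-target ratio r:
#' `N_E * (1 + 1/r) / (N_T + N_E)`.  This is an upper bound (on average)
#' on the true FDP of the pooled discovery list.
#'
#' @param nTarget number of original-target discoveries (N_T).
#' @param nEntrap number of entrapment discoveries (N_E).
#' @param r effective entrapment-to-original-target ratio (> 0).
#' @return The estimate, capped at 1 (the uncapped value is kept in the
#'   `"raw"` attribute).  0 when there are no discoveries.
#' @examples
#' combinedFdp(96, 4, r = 1)   # 0.08
#' combinedFdp(96, 4, r = 5)   # 0.048
#' @export
combinedFdp <- function(nTarget, nEntrap, r) {
  assertCount(nTarget, "nTarget"); assertCount(nEntrap, "nEntrap")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("'r' must be a single positive number", call. = FALSE)
  if (nTarget + nEntrap == 0) return(cap1(0))
  cap1(nEntrap * (1 + 1 / r) / (nTarget + nEntrap))
}

#' Lower-bound entrapment estimate of the FDP
#'
#' `N_E / (N_T + N_E)`: the fraction of entrapment discoveries in the
#' pooled list.  Always a lower bound on the pooled-list FDP (entrapment
#' discoveries are known false), so it can expose invalid FDR control but
#' can never establish valid control.
#'
#' @inheritParams combinedFdp
#' @return The estimate; 0 when there are no discoveries.
#' @examples
#' lowerBoundFdp(96, 4)   # 0.04
#' @export
lowerBoundFdp <- function(nTarget, nEntrap) {
  assertCount(nTarget, "nTarget"); assertCount(nEntrap, "nEntrap")
  if (nTarget + nEntrap == 0) return(0)
  nEntrap / (nTarget + nEntrap)
}

#' Sample entrapment estimate of the FDP
#'
#' `(N_E / r) / N_T`: an estimate of the FDP among the original-target
#' discoveries only.  This estimator is neither an upper nor a lower bound
#' (it typically under- but can over-estimate), so it cannot be used to
#' argue for or against FDR control; it is provided for comparison and is
#' flagged accordingly.
#'
#' @inheritParams combinedFdp
#' @return The estimate, capped at 1, with attributes `"raw"` and
#'   `"note" = "not a valid bound"`.
#' @examples
#' sampleFdp(96, 4, r = 2)   # 0.0208...
#' @export
sampleFdp <- function(nTarget, nEntrap, r) {
  assertCount(nTarget, "nTarget"); assertCount(nEntrap, "nEntrap")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("'r' must be a single positive number", call. = FALSE)
  if (nEntrap == 0) out <- cap1(0)
  else if (nTarget == 0)
    stop("sample estimate undefined: no original-target discoveries",
         call. = FALSE)
  else out <- cap1((nEntrap / r) / nTarget)
  attr(out, "note") <- "not a valid bound"
  out
}

## Resolve, for every entrapment row of `table`, the score of its paired
## original target (-Inf when the original is not in the table).
resolvePairScores <- function(rows, pairs = NULL) {
  ent <- rows[rows$label == "entrapment", , drop = FALSE]
  key <- ent$pair_key
  if (!is.null(pairs)) {
    stopifnot(is(pairs, "PairedEntrapmentDB"))
    if (pairs@mode != "shuffled")
      stop("paired estimation requires a paired (shuffled-mode) database",
           call. = FALSE)
    lookup <- pairs@pairs$target[match(ent$id, pairs@pairs$entrap_id)]
    key <- ifelse(is.na(key), lookup, key)
  }
  bad <- ent$id[is.na(key)]
  if (length(bad))
    stop("entrapment rows with unresolvable pairing: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  orig <- rows[rows$label == "original", , drop = FALSE]
  tscore <- orig$score[match(key, orig$id)]
  tscore[is.na(tscore)] <- -Inf
  list(entrapScore = ent$score, targetScore = tscore, key = key)
}

#' Paired-count statistics at a discovery cutoff
#'
#' Classifies every discovered entrapment (score >= `s`) by the fate of its
#' paired original target: target below the cutoff
#' (`n_e_ge_s_t_lt`), or target also discovered but scoring below the
#' entrapment (`n_e_gt_t_ge_s`); an entrapment whose paired target scores
#' above it is not counted.  Exact score ties between an entrapment and
#' its paired target are broken by a seeded fair coin.
#'
#' @param table a [DiscoveryTable-class]; entrapment rows must carry a
#'   `pair_key` or be resolvable through `pairs`.  An original target that
#'   is absent from the table is treated as scoring `-Inf`.
#' @param pairs optional shuffled-mode [PairedEntrapmentDB-class] used to
#'   resolve entrapment-to-target pairing when `pair_key` is missing.
#' @param s the discovery cutoff score.
#' @param k matching multiplicity (1 for the paired estimator; when a
#'   `pairs` database is supplied its ratio must equal `k`).
#' @param seed seed for the tie-breaking coin.
#' @return A list with class `"PairedCounts"`: `s`, `n_entrap`,
#'   `n_e_ge_s_t_lt`, `n_e_gt_t_ge_s`, `k`.
#' @examples
#' tab <- DiscoveryTable(id = c("T1", "T2", "T3", "E4"),
#'                       label = c(rep("original", 3), "entrapment"),
#'                       score = c(9, 8, 7.5, 7.2),
#'                       pairKey = c(NA, NA, NA, "T4"))
#' pairedCounts(tab, s = 7)
#' @export
pairedCounts <- function(table, pairs = NULL, s, k = 1L, seed = NULL) {
  stopifnot(is(table, "DiscoveryTable"))
  if (!is.null(pairs) && round(effectiveRatio(pairs)) != k)
    stop("database ratio does not match the requested multiplicity k",
         call. = FALSE)
  rows <- table@rows
  ps <- resolvePairScores(rows, pairs)
  disc <- ps$entrapScore >= s
  e <- ps$entrapScore[disc]
  t <- ps$targetScore[disc]
  if (k > 1L) {
    sizes <- table(ps$key)
    ## with a pairs db we can check the full grouping; from the table alone
    ## we only require no key to exceed k
    if (any(sizes > k))
      stop("entrapment group size exceeds k", call. = FALSE)
  }
  tie <- e == t
  if (any(tie)) {
    coin <- withSeed(seed, runif(sum(tie)) < 0.5)
    e[tie] <- e[tie] + ifelse(coin, 1e-9, -1e-9)
  }
  structure(list(s = s,
                 n_entrap = sum(disc),
                 n_e_ge_s_t_lt = sum(t < s),
                 n_e_gt_t_ge_s = sum(t >= s & e > t),
                 k = as.integer(k)),
            class = "PairedCounts")
}

#' Paired entrapment estimate of the FDP
#'
#' `(N_E + N_{E>=s>T} + 2*N_{E>T>=s}) / (N_T + N_E)`: uses the pairing
#' between each original target and its unique entrapment (r = 1) to
#' tighten the combined upper bound while retaining its upper-bound nature
#' on average.
#'
#' @param counts a `"PairedCounts"` object from [pairedCounts()] with
#'   `k = 1`.
#' @param nTarget number of original-target discoveries (N_T).
#' @return The estimate, capped at 1 (`"raw"` attribute uncapped).
#' @examples
#' cts <- structure(list(s = 7, n_entrap = 1, n_e_ge_s_t_lt = 1,
#'                       n_e_gt_t_ge_s = 0, k = 1L), class = "PairedCounts")
#' pairedFdp(cts, nTarget = 3)   # 0.5
#' @export
pairedFdp <- function(counts, nTarget) {
  stopifnot(inherits(counts, "PairedCounts"))
  if (counts$k != 1L)
    stop("counts were computed with k > 1: use kMatchedFdp()",
         call. = FALSE)
  kMatchedFdp(counts, nTarget)
}

#' k-matched generalization of the paired estimator
#'
#' With each original target uniquely associated with `k` entrapment
#' counterparts (so r = k), the estimate is
#' `(N_E + (N_{E>=s>T} + 2*N_{E>T>=s}) / k) / (N_T + N_E)`:
#' the false-discovery mass a target's entrapments attribute to it is
#' averaged over its `k` entrapments so it is counted once, which reduces
#' exactly to the paired estimator at `k = 1` and remains an upper bound
#' on average (checked against the calibrated simulator).
#'
#' @param counts a `"PairedCounts"` object from [pairedCounts()].
#' @param nTarget number of original-target discoveries (N_T).
#' @return The estimate, capped at 1, with a `"weighting"` attribute
#'   documenting the per-target averaging.
#' @export
kMatchedFdp <- function(counts, nTarget) {
  stopifnot(inherits(counts, "PairedCounts"))
  assertCount(nTarget, "nTarget")
  k <- counts$k
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  denom <- nTarget + counts$n_entrap
  if (denom == 0) return(cap1(0))
  num <- counts$n_entrap +
    (counts$n_e_ge_s_t_lt + 2 * counts$n_e_gt_t_ge_s) / k
  out <- cap1(num / denom)
  attr(out, "weighting") <-
    "per-target contributions averaged over its k entrapments"
  out
}

#' Entrapment-estimated FDP as a function of the FDR threshold
#'
#' For each threshold `t`, the discovery set is all rows with tool-reported
#' q-value <= `t`; the paired estimator's cutoff score `s` is the minimum
#' score in that set.  Estimates are capped at 1.
#'
#' @param table a [DiscoveryTable-class] with q-values (and scores if the
#'   paired estimator is requested).
#' @param pairs optional [PairedEntrapmentDB-class] for pairing resolution.
#' @param methods subset of `c("lower", "combined", "paired", "sample")`.
#' @param thresholds increasing FDR cutoffs in (0, 1]; default is a
#'   200-point logarithmic grid from 1e-4 to the largest reported q-value.
#' @param r effective entrapment-to-target ratio.
#' @param k matching multiplicity for the paired column (uses
#'   [kMatchedFdp()] when `k > 1`).
#' @param seed tie-break seed passed to [pairedCounts()].
#' @return A data.frame: `threshold`, `n_target`, `n_entrap`, and one
#'   column per requested method.
#' @export
fdpCurve <- function(table, pairs = NULL,
                     methods = c("lower", "combined", "paired"),
                     thresholds = NULL, r = 1, k = 1L, seed = NULL) {
  stopifnot(is(table, "DiscoveryTable"))
  methods <- match.arg(methods,
                       c("lower", "combined", "paired", "sample"),
                       several.ok = TRUE)
  rows <- table@rows
  if (!nrow(rows)) stop("empty discovery table", call. = FALSE)
  if (all(is.na(rows$qvalue)))
    stop("fdpCurve needs tool-reported q-values; run an FDR procedure first",
         call. = FALSE)
  if (is.null(thresholds)) {
    qmax <- max(rows$qvalue, na.rm = TRUE)
    thresholds <- exp(seq(log(1e-4), log(max(qmax, 1e-4)),
                          length.out = 200))
  }
  if (is.unsorted(thresholds, strictly = FALSE) ||
      any(thresholds <= 0) || any(thresholds > 1))
    stop("thresholds must be increasing and in (0, 1]", call. = FALSE)
  out <- data.frame(threshold = thresholds, n_target = NA_integer_,
                    n_entrap = NA_integer_)
  for (m in methods) out[[m]] <- NA_real_
  for (i in seq_along(thresholds)) {
    disc <- rows[!is.na(rows$qvalue) & rows$qvalue <= thresholds[i], ,
                 drop = FALSE]
    nT <- sum(disc$label == "original")
    nE <- sum(disc$label == "entrapment")
    out$n_target[i] <- nT; out$n_entrap[i] <- nE
    if ("lower" %in% methods) out$lower[i] <- lowerBoundFdp(nT, nE)
    if ("combined" %in% methods)
      out$combined[i] <- as.numeric(combinedFdp(nT, nE, r))
    if ("sample" %in% methods)
      out$sample[i] <- if (nT == 0 && nE > 0) NA_real_ else
        as.numeric(sampleFdp(nT, nE, r))
    if ("paired" %in% methods) {
      if (nT + nE == 0) { out$paired[i] <- 0; next }
      s <- min(disc$score, na.rm = TRUE)
      cts <- pairedCounts(table, pairs, s = s, k = k, seed = seed)
      out$paired[i] <- as.numeric(kMatchedFdp(cts, nT))
    }
  }
  out
}

#' Coverage band for replicated FDP estimates
#'
#' A 95% band for the mean of `n` replicate FDP estimates (each computed
#' with an independently drawn decoy/entrapment database):
#' `half_width = 1.96 * sd / sqrt(n)` (standard error of the mean).  The
#' literal `1.96 * sd / n` variant is available via `literal = TRUE`.
#'
#' @param fdpEstimates numeric vector of replicate FDP estimates (n >= 2).
#' @param literal use `sd / n` instead of the standard-error reading.
#' @return A list: `n`, `sigma_n` (sample standard deviation),
#'   `half_width`.
#' @examples
#' coverageBand(c(0.01, 0.02, 0.03))
#' @export
coverageBand <- function(fdpEstimates, literal = FALSE) {
  n <- length(fdpEstimates)
  if (n < 2L) stop("need at least 2 replicate estimates", call. = FALSE)
  sigma <- sd(fdpEstimates)
  list(n = n, sigma_n = sigma,
       half_width = 1.96 * sigma / if (literal) n else sqrt(n))
}

#' Discovery inflation rate
#'
#' `100 * (n1 - n2) / n2`, where `n1` is the number of discoveries the
#' tool reports at its own 1% FDR threshold and `n2` is the number at a 1%
#' entrapment-estimated FDP (paired method).  Negative rates are allowed.
#'
#' @param n1 discoveries at the tool's threshold.
#' @param n2 discoveries at the entrapment-estimated threshold (> 0).
#' @return A list: `n1`, `n2`, `rate` (percent).
#' @examples
#' inflationRate(1000, 950)$rate   # 5.26...
#' @export
inflationRate <- function(n1, n2) {
  assertCount(n1, "n1"); assertCount(n2, "n2")
  if (n2 == 0) stop("n2 must be positive", call. = FALSE)
  list(n1 = n1, n2 = n2, rate = 100 * (n1 - n2) / n2)
}

#' Direct FDP estimate from ground-truth flags
#'
#' In a double-entrapment experiment every foreign-in-target or entrapment
#' discovery is a known false discovery, so the FDP of a discovery list can
#' be estimated directly as (# known-false) / (# discoveries).
#'
#' @param table a [DiscoveryTable-class] whose rows are the discovery list,
#'   with the `known_false` flag set.
#' @return A single number.
#' @export
directFdp <- function(table) {
  stopifnot(is(table, "DiscoveryTable"))
  rows <- table@rows
  if (!nrow(rows)) stop("empty discovery set", call. = FALSE)
  if (all(is.na(rows$known_false)))
    stop("directFdp needs the known_false flag", call. = FALSE)
  mean(rows$known_false %in% TRUE)
}
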