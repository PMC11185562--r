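## Calibrated score simulator with known ground truth, used to validate
## the directional guarantees of the entrapment estimators and the FDR
## control of TDC by Monte Carlo.

#' Simulator configuration
#'
#' The simulator implements the equal-chance model the estimators'
#' guarantees rest on: peptides truly present in the sample draw scores
#' from a signal distribution (with probability `detectProb` of being
#' observed at all), while absent original targets, foreign-in-target
#' peptides, all entrapment peptides and all decoys draw i.i.d. scores
#' from one shared null distribution, making them exchangeable.
#'
#' @param nNative number of database peptides truly present.
#' @param nAbsent number of absent original-target peptides.
#' @param nForeign number of foreign-flagged absent peptides inside the
#'   "original target" database (double-entrapment mode; 0 disables).
#' @param r entrapment-to-original-target ratio (integer here: every
#'   original target gets `r` paired entrapments).
#' @param k matching multiplicity used by the paired column of
#'   [boundExperiment()] (`k = r` for the k-matched estimator).
#' @param signalMean,signalSd present-peptide score distribution.
#' @param nullMean,nullSd shared null score distribution.
#' @param detectProb probability a present peptide yields any score.
#' @param scoreModel `"gaussian"` or `"gumbel"` (heavy-tailed option;
#'   search-engine score nulls are extreme-value-like).
#' @param nReplicates number of Monte-Carlo replicates for
#'   [boundExperiment()].
#' @param seed integer seed.
#' @return A list with class `"SimConfig"`.
#' @export
simConfig <- function(nNative = 1000L, nAbsent = 4000L, nForeign = 0L,
                      r = 1L, k = 1L, signalMean = 3, signalSd = 1,
                      nullMean = 0, nullSd = 1, detectProb = 0.7,
                      scoreModel = c("gaussian", "gumbel"),
                      nReplicates = 500L, seed = NULL) {
  scoreModel <- match.arg(scoreModel)
  assertCount(nNative, "nNative"); assertCount(nAbsent, "nAbsent")
  assertCount(nForeign, "nForeign")
  if (r < 1L || k < 1L) stop("r and k must be >= 1", call. = FALSE)
  if (signalSd <= 0 || nullSd <= 0) stop("sds must be positive",
                                         call. = FALSE)
  if (detectProb < 0 || detectProb > 1)
    stop("detectProb must be in [0, 1]", call. = FALSE)
  structure(list(nNative = as.integer(nNative),
                 nAbsent = as.integer(nAbsent),
                 nForeign = as.integer(nForeign),
                 r = as.integer(r), k = as.integer(k),
                 signalMean = signalMean, signalSd = signalSd,
                 nullMean = nullMean, nullSd = nullSd,
                 detectProb = detectProb, scoreModel = scoreModel,
                 nReplicates = as.integer(nReplicates), seed = seed),
            class = "SimConfig")
}

drawNull <- function(n, config) {
  if (config$scoreModel == "gaussian")
    rnorm(n, config$nullMean, config$nullSd)
  else config$nullMean - config$nullSd * log(-log(runif(n)))
}

drawSignal <- function(n, config) {
  if (config$scoreModel == "gaussian")
    rnorm(n, config$signalMean, config$signalSd)
  else config$signalMean - config$signalSd * log(-log(runif(n)))
}

#' Simulate one entrapment search with known ground truth
#'
#' Builds an original-target database (`nNative` present + `nAbsent`
#' absent + `nForeign` foreign-flagged absent peptides), pairs every
#' original target with `r` entrapment peptides, gives every database
#' peptide (original or entrapment) its own decoy, draws scores under the
#' equal-chance model, runs the per-peptide target-decoy competition, and
#' assigns TDC q-values to the competition winners.
#'
#' @param config a [simConfig()].
#' @param seed overrides `config$seed`.
#' @return A list with class `"SimulatedSearch"`: `table` (a
#'   [DiscoveryTable-class] of competition winners, with `known_false`
#'   set to the ground truth and an extra `foreign` column), and `config`.
#' @export
simulateSearch <- function(config = simConfig(), seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(seed, {
    nO <- config$nNative + config$nAbsent + config$nForeign
    if (nO == 0) stop("empty database", call. = FALSE)
    oid <- sprintf("T%05d", seq_len(nO))
    native <- seq_len(nO) <= config$nNative
    foreign <- seq_len(nO) > config$nNative + config$nAbsent
    ## original-target scores
    oscore <- drawNull(nO, config)
    if (config$nNative) {
      det <- rbinom(config$nNative, 1L, config$detectProb) == 1L
      s <- drawSignal(config$nNative, config)
      oscore[seq_len(config$nNative)] <- ifelse(det, s, -Inf)
    }
    ## entrapments: r per original, all null
    r <- config$r
    eid <- sprintf("E%05d_%d", rep(seq_len(nO), each = r),
                   rep(seq_len(r), nO))
    epair <- rep(oid, each = r)
    escore <- drawNull(nO * r, config)
    ## competition of every database peptide against its own decoy
    pep_score <- c(oscore, escore)
    dec_score <- drawNull(length(pep_score), config)
    win <- pep_score > dec_score
    w <- pmax(pep_score, dec_score)
    l <- ifelse(win, 1, -1)
    q <- tdcQvalues(w, l, seed = NULL)
    keep <- win
    rows_id <- c(oid, eid)[keep]
    rows_label <- rep(c("original", "entrapment"),
                      c(nO, nO * r))[keep]
    rows_pair <- c(rep(NA_character_, nO), epair)[keep]
    kf <- c(!native | foreign, rep(TRUE, nO * r))[keep]
    fr <- c(foreign, rep(FALSE, nO * r))[keep]
    tab <- DiscoveryTable(id = rows_id, label = rows_label,
                          score = w[keep], qvalue = q[keep],
                          pairKey = rows_pair, knownFalse = kf)
    tab@rows$foreign <- fr
    structure(list(table = tab, config = config),
              class = "SimulatedSearch")
  })
}

#' True false discovery proportion of a simulated discovery list
#'
#' The realized proportion of ground-truth false discoveries among the
#' rows with q-value at or below the threshold; 0 for an empty set.
#'
#' @param search a `"SimulatedSearch"` from [simulateSearch()].
#' @param threshold FDR/q-value cutoff defining the discovery set.
#' @return A single number.
#' @export
trueFdp <- function(search, threshold) {
  stopifnot(inherits(search, "SimulatedSearch"))
  rows <- search$table@rows
  disc <- rows[rows$qvalue <= threshold, , drop = FALSE]
  if (!nrow(disc)) return(0)
  mean(disc$known_false)
}

## Estimator panel for one replicate at one threshold.
replicateEstimates <- function(search, alpha) {
  rows <- search$table@rows
  k <- search$config$k
  disc <- rows[rows$qvalue <= alpha, , drop = FALSE]
  nT <- sum(disc$label == "original")
  nE <- sum(disc$label == "entrapment")
  r <- search$config$r
  if (nT + nE == 0) {
    est <- c(true = 0, lower = 0, combined = 0, sample = 0, paired = 0)
  } else {
    s <- min(disc$score)
    cts <- pairedCounts(search$table, s = s, k = k)
    est <- c(true = mean(disc$known_false),
             lower = lowerBoundFdp(nT, nE),
             combined = as.numeric(combinedFdp(nT, nE, r)),
             sample = if (nT == 0) NA_real_ else
               as.numeric(sampleFdp(nT, nE, r)),
             paired = as.numeric(kMatchedFdp(cts, nT)))
  }
  direct <- if (search$config$nForeign > 0) {
    if (nrow(disc)) mean(disc$foreign | disc$label == "entrapment") else 0
  } else NA_real_
  c(est, direct = direct, n_disc = nrow(disc))
}

#' Monte-Carlo validation of the estimator bound directions
#'
#' Runs `config$nReplicates` independent simulated searches (each with a
#' freshly drawn set of entrapment and decoy scores, emulating
#' independently rebuilt databases) and, for each FDR level in `alphas`,
#' averages the true FDP and every estimator over the replicates.  The
#' directional checks -- mean lower bound below the true FDR, mean
#' combined and paired estimates above it, paired below combined, and TDC
#' holding the FDR at `alpha` -- are evaluated with a two-standard-error
#' allowance on the paired per-replicate differences.  In
#' double-entrapment mode (`nForeign > 0`) the mean paired estimate is
#' additionally compared with the mean direct (ground-truth-flag)
#' estimate.
#'
#' @param config a [simConfig()].
#' @param alphas FDR levels to evaluate.
#' @return A data.frame, one row per alpha: means, Monte-Carlo standard
#'   errors, 95% coverage-band half-widths, and logical `ok_*` columns for
#'   each directional check.
#' @export
boundExperiment <- function(config = simConfig(),
                            alphas = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(config, "SimConfig"))
  reps <- config$nReplicates
  if (reps < 2L) stop("need at least 2 replicates", call. = FALSE)
  withSeed(config$seed, {
    res <- array(NA_real_, dim = c(reps, length(alphas), 7),
                 dimnames = list(NULL, NULL,
                                 c("true", "lower", "combined", "sample",
                                   "paired", "direct", "n_disc")))
    for (i in seq_len(reps)) {
      search <- simulateSearch(config, seed = NULL)
      for (a in seq_along(alphas))
        res[i, a, ] <- replicateEstimates(search, alphas[a])
    }
    se <- function(x) sd(x) / sqrt(sum(!is.na(x)))
    out <- lapply(seq_along(alphas), function(a) {
      m <- res[, a, ]
      band <- coverageBand(m[, "paired"])
      d_lower <- m[, "lower"] - m[, "true"]
      d_comb <- m[, "true"] - m[, "combined"]
      d_pair <- m[, "true"] - m[, "paired"]
      d_pc <- m[, "paired"] - m[, "combined"]
      row <- data.frame(
        alpha = alphas[a],
        mean_true = mean(m[, "true"]), se_true = se(m[, "true"]),
        mean_lower = mean(m[, "lower"]),
        mean_combined = mean(m[, "combined"]),
        mean_sample = mean(m[, "sample"], na.rm = TRUE),
        mean_paired = mean(m[, "paired"]),
        band_half_width = band$half_width,
        mean_n_disc = mean(m[, "n_disc"]),
        ok_lower_le_true = mean(d_lower) <= 2 * se(d_lower),
        ok_combined_ge_true = mean(d_comb) <= 2 * se(d_comb),
        ok_paired_ge_true = mean(d_pair) <= 2 * se(d_pair),
        ok_paired_le_combined = mean(d_pc) <= 2 * se(d_pc),
        ok_tdc_control = mean(m[, "true"]) <=
          alphas[a] + 2 * se(m[, "true"]))
      if (config$nForeign > 0) {
        ## agreement if the mean direct estimate lies within two standard
        ## errors of the averaged paired estimate (its coverage band)
        row$mean_direct <- mean(m[, "direct"])
        row$ok_paired_eq_direct <-
          abs(mean(m[, "paired"]) - mean(m[, "direct"])) <=
            2 * se(m[, "paired"])
      }
      row
    })
    do.call(rbind, out)
  })
}
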