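## Fixture generators and independent brute-force oracles used across the
## suite.  The oracles deliberately share no code with the package
## implementations they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomPeptides <- function(n, len = 9L, seed = 1L) {
  set.seed(seed)
  unique(vapply(seq_len(n), function(i)
    paste(c(sample(AA20, len - 1L, replace = TRUE), "K"), collapse = ""),
    character(1)))
}

randomProteome <- function(n, len = 60L, seed = 1L) {
  set.seed(seed)
  prots <- vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE), collapse = ""), character(1))
  names(prots) <- sprintf("SYN%04d", seq_len(n))
  prots
}

## A random scored table: originals plus entrapments paired to a random
## subset of original ids (some paired targets absent from the table).
randomDiscoveryTable <- function(nOrig = 50L, nEntrap = 30L, seed = 1L) {
  set.seed(seed)
  oid <- sprintf("T%04d", seq_len(nOrig + 10L))  # 10 ids never reported
  present <- oid[seq_len(nOrig)]
  eid <- sprintf("E%04d", seq_len(nEntrap))
  DiscoveryTable(
    id = c(present, eid),
    label = rep(c("original", "entrapment"), c(nOrig, nEntrap)),
    score = runif(nOrig + nEntrap, 0, 10),
    qvalue = sort(runif(nOrig + nEntrap)),
    pairKey = c(rep(NA, nOrig), sample(oid, nEntrap, replace = TRUE)))
}

## Brute-force classifier for the paired counts: enumerates every
## entrapment row and its paired target directly.
bruteForcePairedCounts <- function(rows, s) {
  nE <- 0L; c1 <- 0L; c2 <- 0L
  for (i in which(rows$label == "entrapment")) {
    e <- rows$score[i]
    if (is.na(e) || e < s) next
    nE <- nE + 1L
    j <- which(rows$label == "original" & rows$id == rows$pair_key[i])
    t <- if (length(j)) rows$score[j[1]] else -Inf
    if (t < s) c1 <- c1 + 1L
    else if (e > t) c2 <- c2 + 1L
  }
  list(n_entrap = nE, n_e_ge_s_t_lt = c1, n_e_gt_t_ge_s = c2)
}

## Quadratic step-up oracle for the BH adjustment, straight from the
## definition q_(i) = min_{j >= i} p_(j) * m / j.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

## Brute-force TDC: evaluates the rejection ratio at every k directly.
bruteForceTdcK <- function(w, l, alpha, ord) {
  ls <- l[ord]
  best <- 0L
  for (k in seq_along(ls)) {
    D <- sum(ls[seq_len(k)] == -1)
    T <- k - D
    if ((D + 1) / max(T, 1) <= alpha) best <- k
  }
  best
}
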