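test_that("shufflePeptide is a uniform permutation with fixed termini", {
  ## "ACK" with C-term fixed has exactly two permutations, roughly equally
  ## likely
  outs <- vapply(1:400, function(i) {
    set.seed(i); shufflePeptide("ACK")
  }, character(1))
  expect_setequal(unique(outs), c("ACK", "CAK"))
  expect_gt(mean(outs == "ACK"), 0.35)
  expect_lt(mean(outs == "ACK"), 0.65)

  set.seed(1)
  expect_identical(shufflePeptide("AAK"), "AAK")

  set.seed(2)
  s <- shufflePeptide("PEPTIDEK")
  expect_equal(sort(strsplit(s, "")[[1]]),
               sort(strsplit("PEPTIDEK", "")[[1]]))
  expect_equal(substring(s, 8, 8), "K")

  set.seed(3)
  both <- shufflePeptide("RPEPTIDEK", shuffleConfig(fixNTerminal = TRUE))
  expect_equal(substring(both, 1, 1), "R")
  expect_equal(substring(both, 9, 9), "K")

  expect_error(shufflePeptide("K"), "too short")
  expect_error(shufflePeptide("AK", shuffleConfig(fixNTerminal = TRUE)),
               "too short")
})

test_that("paired peptide db: entrapments are distinct permutations", {
  db <- generatePairedPeptideDb("ACDEFGK", r = 1, shuffleConfig(seed = 9))
  p <- pairTable(db)
  expect_equal(nrow(p), 1)
  expect_false(p$entrapment == "ACDEFGK")
  expect_equal(sort(strsplit(p$entrapment, "")[[1]]),
               sort(strsplit("ACDEFGK", "")[[1]]))
  expect_equal(substring(p$entrapment, 7, 7), "K")
})

test_that("an unshufflable peptide is removed after exactly 20+r attempts", {
  db <- generatePairedPeptideDb("AAAAAAK", r = 1, shuffleConfig(seed = 4))
  expect_equal(nrow(pairTable(db)), 0)
  rem <- removedTargets(db)
  expect_equal(rem$target, "AAAAAAK")
  expect_equal(rem$attempts, 21L)

  db3 <- generatePairedPeptideDb("AAAAAAK", r = 3, shuffleConfig(seed = 4))
  expect_equal(removedTargets(db3)$attempts, 23L)
})

test_that("r-fold build satisfies group sizes and global distinctness", {
  targets <- randomPeptides(100, len = 9, seed = 21)
  db <- generatePairedPeptideDb(targets, r = 3, shuffleConfig(seed = 21))
  p <- pairTable(db)
  sizes <- table(p$target)
  expect_true(all(sizes == 3))
  ## entrapments distinct from every target and from each other
  expect_length(intersect(p$entrapment, targets), 0)
  expect_false(anyDuplicated(p$entrapment) > 0)
  ## composition conserved
  for (i in sample(nrow(p), 10))
    expect_equal(sort(strsplit(p$entrapment[i], "")[[1]]),
                 sort(strsplit(p$target[i], "")[[1]]))
  expect_equal(effectiveRatio(db), 3)
})

test_that("pairing is a bijection at r = 1 and builds are seed-deterministic", {
  targets <- randomPeptides(80, len = 8, seed = 5)
  db1 <- generatePairedPeptideDb(targets, 1, shuffleConfig(seed = 13))
  db2 <- generatePairedPeptideDb(sample(targets), 1,
                                 shuffleConfig(seed = 13))
  expect_identical(pairTable(db1), pairTable(db2))  # order-independent
  p <- pairTable(db1)
  expect_false(anyDuplicated(p$target) > 0)
  expect_false(anyDuplicated(p$entrapment) > 0)

  db3 <- generatePairedPeptideDb(targets, 1, shuffleConfig(seed = 14))
  expect_false(identical(pairTable(db1)$entrapment,
                         pairTable(db3)$entrapment))
})

test_that("non-canonical peptides are excluded from pairing and logged", {
  db <- generatePairedPeptideDb(c("ACDEFGK", "ACDXEFK"), r = 1,
                                shuffleConfig(seed = 2))
  expect_equal(removedTargets(db)$target, "ACDXEFK")
  expect_match(removedTargets(db)$reason, "non-canonical")
  expect_equal(pairTable(db)$target, "ACDEFGK")
})

test_that("protein-level entrapment swaps peptides with fixed C-termini", {
  db <- generatePairedProteinDb(c(P1 = "PEPKACDR"), r = 1,
                                shuffleConfig(seed = 8))
  e <- pairTable(db)$entrapment
  expect_equal(nchar(e), 8)
  s1 <- substring(e, 1, 4); s2 <- substring(e, 5, 8)
  expect_equal(substring(s1, 4, 4), "K")
  expect_equal(substring(s2, 4, 4), "R")
  expect_equal(sort(strsplit(s1, "")[[1]]),
               sort(strsplit("PEPK", "")[[1]]))
  expect_equal(sort(strsplit(s2, "")[[1]]),
               sort(strsplit("ACDR", "")[[1]]))
  expect_equal(pairTable(db)$entrap_id, "ENTRAP_P1")
})

test_that("a peptide shared between proteins is swapped consistently", {
  db <- generatePairedProteinDb(
    c(P1 = "ACDEFGKLMNPQR", P2 = "ACDEFGKSTVWYK"), r = 1,
    shuffleConfig(seed = 15))
  p <- pairTable(db)
  e1 <- substring(p$entrapment[p$target == "P1"], 1, 7)
  e2 <- substring(p$entrapment[p$target == "P2"], 1, 7)
  expect_identical(e1, e2)
})

test_that("an unpermutable protein yields an identical entrapment", {
  db <- generatePairedProteinDb(c(P = "KKKKK"), r = 1,
                                shuffleConfig(seed = 1))
  expect_equal(pairTable(db)$entrapment, "KKKKK")
})

test_that("entrapment proteins preserve length and peptide boundaries", {
  prots <- randomProteome(10, len = 80, seed = 31)
  db <- generatePairedProteinDb(prots, r = 2, shuffleConfig(seed = 31))
  p <- pairTable(db)
  for (i in seq_len(nrow(p))) {
    acc <- p$target[i]
    expect_equal(nchar(p$entrapment[i]), nchar(prots[[acc]]))
    ## the swap map re-assembles the entrapment protein exactly
    frags <- digest(prots[[acc]], digestConfig(0, applyLengthFilter = FALSE))
    pm <- db@peptideMap
    swapped <- vapply(frags, function(f)
      pm$entrapment[pm$peptide == f & pm$copy == p$copy[i]], character(1))
    expect_equal(paste(swapped, collapse = ""), p$entrapment[i])
    ## within each swapped peptide the C-terminal residue (the tryptic
    ## boundary) is unchanged, so original cleavage sites survive
    ends <- cumsum(nchar(frags))
    expect_equal(substring(p$entrapment[i], ends, ends),
                 substring(prots[[acc]], ends, ends))
  }
})

test_that("entrapment proteins without interior K/R digest back exactly", {
  ## peptides have K/R only at their C-terminus, so the digest of the
  ## entrapment protein returns exactly the chosen entrapment peptides
  prots <- c(Q1 = "ACDEFGKLMNPQVWYR", Q2 = "STVWYACDK")
  db <- generatePairedProteinDb(prots, r = 1, shuffleConfig(seed = 6))
  p <- pairTable(db)
  for (i in seq_len(nrow(p))) {
    frags <- digest(prots[[p$target[i]]],
                    digestConfig(0, applyLengthFilter = FALSE))
    pm <- db@peptideMap
    expected <- vapply(frags, function(f)
      pm$entrapment[pm$peptide == f], character(1))
    got <- digest(p$entrapment[i], digestConfig(0, applyLengthFilter = FALSE))
    expect_equal(got, unname(expected))
  }
})

test_that("foreign database excludes shared peptides and hits the ratio", {
  targets <- c(A = paste0(paste(rep("ACDEFGK", 3), collapse = ""),
                          "LMNPQRSTV"))
  tpep <- buildPeptideDb(targets)
  foreign <- randomProteome(40, len = 100, seed = 77)
  ## inject the target peptides into one foreign protein
  foreign[1] <- paste0("ACDEFGK", foreign[[1]])
  db <- generateForeignDb(tpep, foreign, r = 2, level = "peptide",
                          seed = 77)
  expect_length(intersect(pairTable(db)$entrapment, peptides(tpep)), 0)
  expect_equal(nrow(pairTable(db)), 2 * length(peptides(tpep)))
  expect_equal(effectiveRatio(db), 2)
  expect_true(all(is.na(pairTable(db)$target)))

  expect_error(generateForeignDb(tpep, foreign[1:2], r = 50,
                                 level = "peptide", seed = 1),
               "achievable r")
})

test_that("foreign protein-level sampling reaches r per original protein", {
  orig <- randomProteome(10, seed = 1)
  foreign <- randomProteome(30, seed = 2)
  db <- generateForeignDb(orig, foreign, r = 2, level = "protein",
                          seed = 3)
  expect_equal(nrow(pairTable(db)), 20)
  expect_true(all(startsWith(pairTable(db)$entrap_id, "ENTRAP_")))
  expect_equal(effectiveRatio(db), 2)
})

test_that("database outputs round-trip through files", {
  targets <- randomPeptides(20, len = 8, seed = 51)
  db <- generatePairedPeptideDb(targets, r = 2, shuffleConfig(seed = 51))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePairTable(db, tsv)
  wide <- read.delim(tsv)
  expect_equal(names(wide), c("target", "entrapment_1", "entrapment_2"))
  expect_setequal(wide$target, unique(pairTable(db)$target))

  mf <- withr::local_tempfile(fileext = ".json")
  writeBuildManifest(db, mf)
  manifest <- jsonlite::read_json(mf)
  expect_equal(manifest$r, 2)
  expect_equal(manifest$n_entrapments, nrow(pairTable(db)))

  prots <- randomProteome(5, seed = 52)
  pdb <- generatePairedProteinDb(prots, r = 1, shuffleConfig(seed = 52))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeEntrapmentFasta(pdb, prots, fa)
  back <- readFasta(fa)
  expect_length(back, 10)
  expect_equal(sum(startsWith(names(back), "ENTRAP_")), 5)
})
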