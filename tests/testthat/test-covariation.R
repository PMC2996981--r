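test_that("column profiles report frequencies over non-gap rows", {
  aln <- rnaAlignment(c(r1 = "AAA", r2 = "AA-", r3 = "AGA", r4 = "AG-"))
  p1 <- columnProfile(aln, 1)
  expect_identical(p1$freq[["A"]], 1)
  expect_identical(p1$nEff, 4L)
  p2 <- columnProfile(aln, 2)
  expect_identical(p2$freq[["A"]], 0.5)
  expect_identical(p2$freq[["G"]], 0.5)
  p3 <- columnProfile(aln, 3)
  expect_identical(p3$freq[["A"]], 1)
  expect_identical(p3$nEff, 2L)
  expect_identical(p3$gaps, 2L)

  gappy <- rnaAlignment(c(a = "A-", b = "C-"))
  expect_error(columnProfile(gappy, 2), "uninformative")
})

test_that("mutual information reproduces the hand-evaluated cases", {
  # two constant columns
  aln <- rnaAlignment(c(a = "AU", b = "AU", c = "AU"))
  expect_identical(mutualInformation(aln, 1, 2), 0)
  # 2x2 diagonal joint table: 1 bit
  aln <- rnaAlignment(c(a = "AU", b = "AU", c = "GC", d = "GC"))
  expect_equal(mutualInformation(aln, 1, 2), 1.0)
  # 4-state diagonal joint table: 2 bits
  aln <- rnaAlignment(c(a = "AU", b = "UA", c = "GC", d = "CG",
    e = "AU", f = "UA", g = "GC", h = "CG"))
  expect_equal(mutualInformation(aln, 1, 2), 2.0)
  # undefined below the row minimum: NA, never 0
  sparse <- rnaAlignment(c(a = "A-", b = "-U", c = "AU"))
  expect_true(is.na(mutualInformation(sparse, 1, 2, minNeff = 2L)))
})

test_that("chi-square matches its definition on hand cases", {
  aln <- rnaAlignment(c(a = "AU", b = "AU", c = "AU"))
  expect_identical(pairChiSquare(aln, 1, 2), list(chi2 = 0, df = 0L))

  # perfect 2x2 association with 8 rows: chi2 = n = 8, df = 1
  aln <- rnaAlignment(c(a = "AU", b = "AU", c = "AU", d = "AU",
    e = "GC", f = "GC", g = "GC", h = "GC"))
  res <- pairChiSquare(aln, 1, 2)
  expect_equal(res$chi2, 8)
  expect_identical(res$df, 1L)

  # independent equiprobable 2-state columns: chi2/n -> 0
  set.seed(101)
  n <- 10000L
  seqs <- paste0(sample(c("A", "G"), n, replace = TRUE),
    sample(c("C", "U"), n, replace = TRUE))
  names(seqs) <- paste0("s", seq_len(n))
  big <- rnaAlignment(seqs)
  res <- pairChiSquare(big, 1, 2)
  expect_lt(res$chi2 / n, 0.01)
})

test_that("statistics equal brute-force evaluation of the defining sums", {
  set.seed(77)
  for (rep in 1:12) {
    aln <- randomAlignment(sample(4:10, 1L), sample(3:8, 1L))
    mat <- alignmentMatrix(aln)
    stats <- covariationMatrix(aln, minNeff = 2L)
    for (k in seq_len(nrow(stats))) {
      i <- stats$i[k]; j <- stats$j[k]
      mi <- oracleMi(mat, i, j)
      if (is.na(stats$mi_bits[k])) {
        expect_lt(sum(mat[, i] != "-" & mat[, j] != "-"), 2L)
        next
      }
      expect_equal(stats$mi_bits[k], mi, tolerance = 1e-12)
      chi <- oracleChi2(mat, i, j)
      expect_equal(stats$chi2[k], chi$chi2, tolerance = 1e-12)
      expect_identical(stats$df[k], chi$df)
    }
  }
})

test_that("MI obeys its information-theoretic bounds", {
  set.seed(42)
  for (rep in 1:8) {
    aln <- randomAlignment(8, 6, gapProb = 0.05)
    mat <- alignmentMatrix(aln)
    # MI(i,i) equals the column entropy
    for (i in c(1, 4)) {
      expect_equal(mutualInformation(aln, i, i), oracleEntropy(mat, i),
        tolerance = 1e-12)
    }
    # MI(i,j) <= min(H(i), H(j)); MI >= 0; MI symmetric
    for (k in 1:5) {
      ij <- sample(6, 2L)
      mi <- mutualInformation(aln, ij[1], ij[2])
      if (is.na(mi)) next
      expect_gte(mi, -1e-12)
      expect_lte(mi, min(oracleEntropy(mat, ij[1]),
        oracleEntropy(mat, ij[2])) + 1e-12)
      expect_equal(mi, mutualInformation(aln, ij[2], ij[1]))
    }
  }
})

test_that("covariation statistics are invariant to row permutation", {
  set.seed(8)
  aln <- randomAlignment(9, 7)
  seqs <- alignmentSequences(aln)
  perm <- rnaAlignment(seqs[sample(length(seqs))])
  expect_equal(covariationMatrix(aln, minNeff = 2L),
    covariationMatrix(perm, minNeff = 2L))
})

test_that("the all-pairs table enumerates C(w,2) records in order", {
  aln <- rnaAlignment(c(a = "AUG", b = "ACG", c = "GCA", d = "AUG"))
  stats <- covariationMatrix(aln, minNeff = 2L)
  expect_identical(nrow(stats), 3L)
  expect_identical(stats$i, c(1L, 1L, 2L))
  expect_identical(stats$j, c(2L, 3L, 3L))
})

test_that("greedy pair prediction honors threshold and assignment", {
  # all-zero MI: empty prediction
  aln <- rnaAlignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  stats <- covariationMatrix(aln, minNeff = 2L)
  expect_identical(nrow(basePairs(predictPairs(stats))), 0L)

  # one dominant covarying pair is returned exactly
  seqs <- c(a = "AAUAA", b = "AGCAA", c = "AAUAA", d = "AGCAA",
    e = "AAUAA", f = "AGCAA")
  stats <- covariationMatrix(rnaAlignment(seqs), minNeff = 2L)
  pred <- basePairs(predictPairs(stats, miThreshold = 0.5))
  expect_identical(unname(pred), matrix(c(2L, 3L), ncol = 2))
})
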