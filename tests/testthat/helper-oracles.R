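# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its definition and share
# no code with the package internals.

# joint/marginal frequencies of two alignment columns by direct counting
oracleJoint <- function(mat, i, j) {
  x <- mat[, i]; y <- mat[, j]
  keep <- x != "-" & y != "-"
  list(x = x[keep], y = y[keep], n = sum(keep))
}

# MI(i,j) = sum_xy f_xy log2(f_xy / (f_x f_y)), evaluated letter by letter
oracleMi <- function(mat, i, j) {
  jt <- oracleJoint(mat, i, j)
  if (jt$n < 2L) return(NA_real_)
  letters <- c("A", "C", "G", "U")
  mi <- 0
  for (a in letters) {
    for (b in letters) {
      fxy <- sum(jt$x == a & jt$y == b) / jt$n
      if (fxy == 0) next
      fx <- sum(jt$x == a) / jt$n
      fy <- sum(jt$y == b) / jt$n
      mi <- mi + fxy * log2(fxy / (fx * fy))
    }
  }
  mi
}

# Shannon entropy of one column (bits)
oracleEntropy <- function(mat, i) {
  x <- mat[, i]; x <- x[x != "-"]
  f <- table(x) / length(x)
  -sum(f * log2(f))
}

# Pearson chi-square over the observed joint table, df=(r-1)(c-1)
oracleChi2 <- function(mat, i, j) {
  jt <- oracleJoint(mat, i, j)
  tab <- table(jt$x, jt$y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(list(chi2 = 0, df = 0L))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - E)^2 / E),
    df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

# random gapped alignment for property tests
randomAlignment <- function(nrow, ncol, gapProb = 0.1) {
  letters <- c("A", "C", "G", "U")
  seqs <- vapply(seq_len(nrow), function(k) {
    ch <- sample(letters, ncol, replace = TRUE)
    ch[runif(ncol) < gapProb] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("r", seq_len(nrow))
  rnaAlignment(seqs)
}

# Needleman-Wunsch optimal score with match +1 / mismatch -1 / gap -2
# (linear), by dynamic programming; scores are unique even when the
# alignment itself is not
oracleNwScore <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- seq(0, -2 * n, by = -2)
  D[1, ] <- seq(0, -2 * m, by = -2)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) 1 else -1
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] - 2, D[i + 1, j] - 2)
    }
  }
  D[n + 1L, m + 1L]
}

pairKey <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)

# standard covariation-recovery scenario used across tests: a 60-nt
# molecule with three helices (15 pairs)
recoveryStructure <- function() {
  secondaryStructure(
    paste(rep("A", 60), collapse = ""),
    rbind(cbind(1:5, 20:16), cbind(25:29, 44:40), cbind(46:50, 60:56)))
}
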