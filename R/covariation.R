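#' Covariation statistics over alignment columns
#'
#' Comparative structure analysis predicts a base pair where two
#' alignment columns show correlated (compensatory) variation.  This
#' module quantifies that signal with mutual information (in bits) and
#' the Pearson chi-square statistic on the joint letter table of a
#' column pair, then predicts pairs greedily from the ranked statistics.
#'
#' Gap policy is pairwise deletion: rows gapped at either column are
#' dropped, and the surviving row count is reported as \code{n_eff} so
#' power loss stays visible.  No pseudocounts are applied; with few
#' sequences MI is biased upward, which the greedy threshold must absorb.
#'
#' @name covariation
NULL

columnLetters <- function(aln, i) {
  if (i < 1L || i > alignmentWidth(aln)) stop("column index out of range")
  aln@mat[, i]
}

#' Letter frequencies of one alignment column
#'
#' @param aln an \linkS4class{RnaAlignment}.
#' @param i 1-based column index.
#' @return list with \code{freq} (named frequencies over A/C/G/U summing
#'   to 1 across non-gap rows), \code{nEff} (non-gap rows) and
#'   \code{gaps}.
#' @export
columnProfile <- function(aln, i) {
  x <- columnLetters(aln, i)
  gaps <- sum(x == "-")
  x <- x[x != "-"]
  if (!length(x)) stop(sprintf("column %d is uninformative (all gaps)", i))
  counts <- table(factor(x, levels = c("A", "C", "G", "U")))
  freq <- stats::setNames(as.numeric(counts) / length(x),
    c("A", "C", "G", "U"))
  list(freq = freq, nEff = length(x), gaps = gaps)
}

jointRows <- function(aln, i, j) {
  x <- columnLetters(aln, i)
  y <- columnLetters(aln, j)
  keep <- x != "-" & y != "-"
  list(x = x[keep], y = y[keep])
}

#' Mutual information between two alignment columns
#'
#' \deqn{MI(i,j) = \sum_{x,y} f_{xy} \log_2 \frac{f_{xy}}{f_x f_y}}
#' computed over rows without a gap at either column.  Bounded by
#' \eqn{0 \le MI \le 2} bits for the four-letter alphabet.
#'
#' @inheritParams columnProfile
#' @param j second column index.
#' @param minNeff minimum surviving rows; below it the statistic is
#'   undefined and \code{NA} is returned (never 0).
#' @return MI in bits, or \code{NA_real_} when undefined.
#' @export
mutualInformation <- function(aln, i, j, minNeff = 2L) {
  r <- jointRows(aln, i, j)
  n <- length(r$x)
  if (n < minNeff) return(NA_real_)
  tab <- table(r$x, r$y) / n
  fx <- rowSums(tab); fy <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log2(tab[nz] / outer(fx, fy)[nz]))
}

#' Pearson chi-square association between two alignment columns
#'
#' Computed on the observed joint letter table (unobserved letters are
#' not included as zero categories, so \code{df = (r-1)(c-1)} over
#' observed categories).  A single-category column yields
#' \code{chi2 = 0, df = 0}.
#'
#' @inheritParams mutualInformation
#' @return list with \code{chi2} and \code{df} (both \code{NA} when
#'   fewer than \code{minNeff} rows survive the gap policy).
#' @export
pairChiSquare <- function(aln, i, j, minNeff = 2L) {
  r <- jointRows(aln, i, j)
  if (length(r$x) < minNeff) return(list(chi2 = NA_real_, df = NA_integer_))
  tab <- table(r$x, r$y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(chi2 = 0, df = 0L))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(as.integer(ct$parameter)))
}

#' All-pairs covariation statistics of an alignment
#'
#' @param aln an \linkS4class{RnaAlignment}.
#' @param minNeff minimum non-gap rows for a pair to be evaluated;
#'   below it the statistics are \code{NA} (pair still listed).
#' @return \code{data.frame(i, j, mi_bits, chi2, df, n_eff)}, one row per
#'   unordered column pair, ordered by \code{i} then \code{j}.
#' @export
covariationMatrix <- function(aln, minNeff = 5L) {
  w <- alignmentWidth(aln)
  idx <- which(upper.tri(matrix(0, w, w)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  out <- data.frame(i = idx[, 1], j = idx[, 2], mi_bits = NA_real_,
    chi2 = NA_real_, df = NA_integer_, n_eff = NA_integer_)
  mat <- aln@mat
  for (k in seq_len(n)) {
    x <- mat[, out$i[k]]; y <- mat[, out$j[k]]
    keep <- x != "-" & y != "-"
    ne <- sum(keep)
    out$n_eff[k] <- ne
    if (ne < minNeff) next
    x <- x[keep]; y <- y[keep]
    tab <- table(x, y)
    ftab <- tab / ne
    fx <- rowSums(ftab); fy <- colSums(ftab)
    nz <- ftab > 0
    out$mi_bits[k] <- sum(ftab[nz] * log2(ftab[nz] / outer(fx, fy)[nz]))
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      out$chi2[k] <- 0; out$df[k] <- 0L
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$chi2[k] <- unname(ct$statistic)
      out$df[k] <- unname(as.integer(ct$parameter))
    }
  }
  out
}

consensusLetters <- function(aln) {
  apply(aln@mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
}

#' Greedy base-pair prediction from covariation statistics
#'
#' Records are sorted by \code{mi_bits} descending (ties: higher
#' \code{chi2}, then smaller \code{i}) and accepted greedily: a pair
#' (i, j) is kept when both columns are still unassigned, its MI meets
#' the threshold, and (optionally) each column is the other's
#' highest-MI partner in the full statistic table.  Optionally pairs are
#' restricted to columns whose consensus letters can form a
#' Watson-Crick or GU pair.
#'
#' @param stats output of \code{\link{covariationMatrix}}.
#' @param miThreshold minimum MI in bits (default 0.15).
#' @param requireMutualBest require i and j to be each other's best
#'   partner by MI over the whole table.
#' @param restrictCanonical if \code{TRUE}, \code{aln} must be supplied
#'   and only consensus-canonical column pairs are eligible.
#' @param aln alignment for the consensus restriction.
#' @return a \linkS4class{SecondaryStructure} (sequence empty; pairs are
#'   alignment-column indices).
#' @export
predictPairs <- function(stats, miThreshold = 0.15,
                         requireMutualBest = TRUE,
                         restrictCanonical = FALSE, aln = NULL) {
  if (!nrow(stats)) return(secondaryStructure("", NULL))
  st <- stats[!is.na(stats$mi_bits), , drop = FALSE]
  if (!nrow(st)) return(secondaryStructure("", NULL))
  if (restrictCanonical) {
    if (is.null(aln)) stop("restrictCanonical requires the alignment")
    cons <- consensusLetters(aln)
    ok <- paste0(cons[st$i], cons[st$j]) %in% CANONICAL_PAIRS
    st <- st[ok, , drop = FALSE]
  }
  st <- st[order(-st$mi_bits, -st$chi2, st$i), , drop = FALSE]
  best <- rep(NA_real_, max(stats$j))
  bestPartner <- rep(NA_integer_, max(stats$j))
  for (k in seq_len(nrow(st))) {
    for (side in 1:2) {
      a <- if (side == 1L) st$i[k] else st$j[k]
      b <- if (side == 1L) st$j[k] else st$i[k]
      if (is.na(best[a]) || st$mi_bits[k] > best[a]) {
        best[a] <- st$mi_bits[k]
        bestPartner[a] <- b
      }
    }
  }
  assigned <- logical(max(stats$j))
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nrow(st))) {
    i <- st$i[k]; j <- st$j[k]
    if (assigned[i] || assigned[j]) next
    if (st$mi_bits[k] < miThreshold) next
    if (requireMutualBest &&
        !(bestPartner[i] == j && bestPartner[j] == i)) next
    pairs <- rbind(pairs, c(i, j))
    assigned[c(i, j)] <- TRUE
  }
  secondaryStructure("", pairs)
}

#' Write a covariation statistic table as TSV
#' @param stats output of \code{\link{covariationMatrix}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCovariationTsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
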