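#' Fragment-level sequence statistics
#'
#' Lengths, A+T / G+C content, and pairwise-identity matrices in the
#' asymmetric layout used for fragmented rRNA comparisons: the upper
#' triangle holds 5'-fragment identities, the lower triangle 3'-fragment
#' identities.
#'
#' @name seqstats
NULL

#' A+T and G+C content of a nucleotide sequence
#'
#' Percentages are rounded half-up to integers and reconciled so that
#' AT + GC = 100 (GC is reported as the complement of the rounded AT).
#' Ambiguity codes (including N) are excluded from the denominator.
#'
#' @param sequence DNA or RNA string.
#' @return named vector \code{c(AT = , GC = )}; both \code{NA} (with a
#'   warning) when no unambiguous base is present.
#' @examples
#' baseContent("ACGT")  # 50 / 50
#' @export
baseContent <- function(sequence) {
  ch <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  at <- sum(ch %in% c("A", "T"))
  gc <- sum(ch %in% c("G", "C"))
  denom <- at + gc
  if (denom == 0L) {
    warning("no unambiguous bases; base content undefined")
    return(c(AT = NA_real_, GC = NA_real_))
  }
  atPct <- roundHalfUp(100 * at / denom)
  c(AT = atPct, GC = 100 - atPct)
}

identitySubstitutionMatrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", ] <- -1; m[, "N"] <- -1  # N never counts as a match
  m
}

#' Percent identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap penalty of -2; identity is the fraction of identical
#' columns, rounded half-up to an integer percent.  By default the
#' denominator is the full alignment length (gapped columns count
#' against identity); \code{denominator = "aligned"} divides by the
#' columns where neither sequence is gapped.
#'
#' @param seqA,seqB nucleotide sequences (DNA or RNA).
#' @param denominator \code{"alignment"} (default) or \code{"aligned"}.
#' @return integer percent in [0, 100].
#' @examples
#' pairwiseIdentity("ACGU", "ACGA")  # 75
#' @export
pairwiseIdentity <- function(seqA, seqB,
                             denominator = c("alignment", "aligned")) {
  denominator <- match.arg(denominator)
  a <- chartr("U", "T", toupper(seqA))
  b <- chartr("U", "T", toupper(seqB))
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
    Biostrings::DNAString(b), type = "global",
    substitutionMatrix = identitySubstitutionMatrix(),
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  denom <- if (denominator == "alignment") length(pa) else
    sum(pa != "-" & sa != "-")
  roundHalfUp(100 * matches / denom)
}

#' Asymmetric similarity matrix over a fragment set
#'
#' @param fragmentSet named list: species id -> \code{list(frag5 = ,
#'   frag3 = )}; either fragment may be \code{NULL}/\code{NA} (its cells
#'   become \code{NA}, e.g. for an accession missing the 5' fragment).
#' @param denominator passed to \code{\link{pairwiseIdentity}}.
#' @return square numeric matrix; \code{[i, j]} with \code{i < j} (upper
#'   triangle) is the 5'-fragment identity, \code{[j, i]} the
#'   3'-fragment identity, diagonal \code{NA}.
#' @export
similarityMatrix <- function(fragmentSet, denominator = "alignment") {
  if (length(fragmentSet) < 2L) stop("need at least two species")
  ids <- names(fragmentSet)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ok <- function(s) !is.null(s) && length(s) == 1L && !is.na(s) && nzchar(s)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      f5a <- fragmentSet[[a]]$frag5; f5b <- fragmentSet[[b]]$frag5
      f3a <- fragmentSet[[a]]$frag3; f3b <- fragmentSet[[b]]$frag3
      if (ok(f5a) && ok(f5b)) {
        m[a, b] <- pairwiseIdentity(f5a, f5b, denominator)
      }
      if (ok(f3a) && ok(f3b)) {
        m[b, a] <- pairwiseIdentity(f3a, f3b, denominator)
      }
    }
  }
  m
}

#' Length / A+T / G+C summary table for a fragment set
#'
#' One column block per species and fragment, mirroring the usual
#' molecular-characteristics table (rows: Length (nt), Percent A+T,
#' Percent G+C).
#'
#' @inheritParams similarityMatrix
#' @return \code{data.frame} with columns species, fragment, length_nt,
#'   percent_AT, percent_GC.
#' @export
fragmentSummaryTable <- function(fragmentSet) {
  rows <- list()
  for (sp in names(fragmentSet)) {
    for (fr in c("frag5", "frag3")) {
      s <- fragmentSet[[sp]][[fr]]
      if (is.null(s) || is.na(s) || !nzchar(s)) {
        rows[[length(rows) + 1L]] <- data.frame(species = sp,
          fragment = fr, length_nt = NA_integer_, percent_AT = NA_real_,
          percent_GC = NA_real_, stringsAsFactors = FALSE)
      } else {
        bc <- baseContent(s)
        rows[[length(rows) + 1L]] <- data.frame(species = sp,
          fragment = fr, length_nt = nchar(s), percent_AT = bc[["AT"]],
          percent_GC = bc[["GC"]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
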