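#' EST-driven gene-boundary inference
#'
#' A fragment's 5' boundary is taken from the extreme 5'-most position
#' observed across transcripts, clamped to the first nucleotide after a
#' known upstream gene when the transcript evidence starts downstream of
#' it; the 3' boundary is the modal polyadenylation site (the last
#' templated nucleotide before the non-templated poly(A) tail) among the
#' tailed transcripts, required to be supported by a configurable
#' majority.
#'
#' @name boundary-inference
NULL

#' Detect a terminal poly(A) tail
#'
#' The tail is the longest terminal run of A allowing at most
#' \code{maxMismatch} non-A bases (leading non-A bases are trimmed so
#' the tail starts with an A); runs shorter than \code{minRun} are not
#' called.  Internal A-runs never count.
#'
#' @param sequence EST/cDNA sequence (DNA or RNA).
#' @param minRun minimum tail length (default 8).
#' @param maxMismatch non-A bases tolerated inside the tail (default 1).
#' @return list with \code{templatedLength} and \code{tailLength}.
#' @examples
#' detectPolyA(paste0("ACGT", strrep("A", 10)))
#' @export
detectPolyA <- function(sequence, minRun = 8L, maxMismatch = 1L) {
  if (!nzchar(sequence)) stop("empty sequence")
  ch <- rev(strsplit(chartr("U", "T", toupper(sequence)), "")[[1]])
  nonA <- cumsum(ch != "A")
  s <- max(c(0L, which(nonA <= maxMismatch)))
  if (s > 0L) {
    suffix <- ch[seq_len(s)]          # reversed: suffix[s] is 5'-most
    while (s > 0L && suffix[s] != "A") s <- s - 1L
  }
  if (s < minRun) s <- 0L
  list(templatedLength = length(ch) - s, tailLength = as.integer(s))
}

#' Align ESTs back to their source gene (synthetic-data utility)
#'
#' Maps each EST's templated portion (after poly(A) removal) onto the
#' gene interval by global-local pairwise alignment.  Intended for the
#' synthetic data produced by \code{\link{simulateEsts}}; it is not a
#' general-purpose spliced aligner.
#'
#' @param ests named character vector of EST sequences.
#' @param genome a \linkS4class{CircularGenome}.
#' @param geneStart,geneEnd gene interval (plus strand, 1-based
#'   inclusive, may wrap on circular genomes).
#' @param minRun,maxMismatch passed to \code{\link{detectPolyA}}.
#' @return \code{data.frame(id, genomic_start, genomic_end, strand,
#'   polya_len, polya_site)}; \code{polya_site} is \code{NA} for
#'   tailless ESTs.
#' @export
alignEstsToGene <- function(ests, genome, geneStart, geneEnd,
                            minRun = 8L, maxMismatch = 1L) {
  gene <- extractInterval(genome, geneStart, geneEnd)
  pos <- intervalPositions(geneStart, geneEnd, genomeLength(genome),
    isCircularGenome(genome))
  subject <- Biostrings::DNAString(gene)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
    mismatch = -1, baseOnly = TRUE)
  rows <- lapply(seq_along(ests), function(k) {
    pa <- detectPolyA(ests[[k]], minRun, maxMismatch)
    body <- substr(chartr("Uu", "Tt", toupper(ests[[k]])), 1L,
      pa$templatedLength)
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(body),
      subject, type = "global-local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    sstart <- Biostrings::start(Biostrings::subject(aln))
    send <- Biostrings::end(Biostrings::subject(aln))
    gstart <- pos[sstart]; gend <- pos[send]
    data.frame(id = names(ests)[k] %||% sprintf("est%d", k),
      genomic_start = gstart, genomic_end = gend, strand = "+",
      polya_len = pa$tailLength,
      polya_site = if (pa$tailLength > 0L) gend else NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Infer fragment boundaries from aligned ESTs
#'
#' @param estAlignments \code{data.frame} with columns
#'   \code{genomic_start}, \code{genomic_end}, \code{polya_len},
#'   \code{polya_site} (as from \code{\link{alignEstsToGene}}).
#' @param upstreamFeatureEnd end coordinate of the adjacent upstream
#'   gene, if known; when \code{upstreamFeatureEnd + 1} lies 5' of the
#'   extreme EST start, the boundary is placed immediately downstream of
#'   that feature instead.
#' @param majorityMin minimum supporting fraction for the modal
#'   polyadenylation site (default 0.5, a literal majority).
#' @return a \code{BoundaryCall} list: \code{start}, \code{end},
#'   \code{startEvidence} (\code{"extreme_5prime_est"} or
#'   \code{"downstream_of_feature"}), \code{endEvidence} with the modal
#'   site and its supporting fraction.  Modal-site ties break toward
#'   the 3'-most site.  With no tailed ESTs \code{end} is \code{NA} and
#'   flagged; a modal fraction below \code{majorityMin} is an error
#'   listing the candidate sites.
#' @export
inferBoundaries <- function(estAlignments, upstreamFeatureEnd = NULL,
                            majorityMin = 0.5) {
  if (!nrow(estAlignments)) stop("need at least one EST alignment")
  minStart <- min(estAlignments$genomic_start)
  start <- minStart
  startEvidence <- "extreme_5prime_est"
  if (!is.null(upstreamFeatureEnd) &&
      (upstreamFeatureEnd + 1L) < minStart) {
    start <- upstreamFeatureEnd + 1L
    startEvidence <- "downstream_of_feature"
  }
  sites <- estAlignments$polya_site[estAlignments$polya_len > 0L]
  sites <- sites[!is.na(sites)]
  if (!length(sites)) {
    endEvidence <- list(site = NA_integer_, fraction = NA_real_,
      flag = "no_polyadenylated_ests")
    end <- NA_integer_
  } else {
    tab <- table(sites)
    top <- max(tab)
    modal <- max(as.integer(names(tab)[tab == top]))  # tie -> 3'-most
    fraction <- top / length(sites)
    if (fraction < majorityMin) {
      cand <- sort(as.integer(names(tab)[tab == top]))
      stop(sprintf(
        "ambiguous 3' end: modal fraction %.2f < %.2f; candidates: %s",
        fraction, majorityMin, paste(cand, collapse = ", ")))
    }
    end <- modal
    endEvidence <- list(site = modal, fraction = fraction, flag = NA)
  }
  structure(list(start = as.integer(start), end = as.integer(end),
    startEvidence = startEvidence, endEvidence = endEvidence,
    nEsts = nrow(estAlignments), nTailed = length(sites)),
    class = "BoundaryCall")
}

#' @export
print.BoundaryCall <- function(x, ...) {
  cat(sprintf("BoundaryCall: %s..%s (start: %s; 3' end: %s)\n",
    x$start, ifelse(is.na(x$end), "?", x$end), x$startEvidence,
    if (is.na(x$end)) x$endEvidence$flag else
      sprintf("poly(A) site %d, %.0f%% support", x$endEvidence$site,
        100 * x$endEvidence$fraction)))
  invisible(x)
}

#' Circular separation between two fragment intervals
#'
#' @param genomeLength circular genome size.
#' @param frag5,frag3 \code{c(start, end)} disjoint intervals (1-based
#'   inclusive; \code{start > end} wraps the origin).
#' @return named vector \code{c(gap_a, gap_b)}: \code{gap_a} counts the
#'   nucleotides strictly between the 5' fragment's end and the 3'
#'   fragment's start going forward around the circle; \code{gap_b} is
#'   the complementary gap.  Always \code{gap_a + gap_b + len(frag5) +
#'   len(frag3) == genomeLength}.
#' @examples
#' fragmentSeparation(17244, c(8250, 8997), c(1712, 2430))  # 9958, 5819
#' @export
fragmentSeparation <- function(genomeLength, frag5, frag3) {
  L <- as.integer(genomeLength)
  p5 <- intervalPositions(frag5[1], frag5[2], L)
  p3 <- intervalPositions(frag3[1], frag3[2], L)
  if (length(intersect(p5, p3))) stop("fragment intervals overlap")
  gapA <- (frag3[1] - frag5[2] - 1L) %% L
  gapB <- L - gapA - length(p5) - length(p3)
  if (gapB < 0L) stop("fragment intervals overlap")
  c(gap_a = as.integer(gapA), gap_b = as.integer(gapB))
}
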