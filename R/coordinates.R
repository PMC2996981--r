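#' Circular coordinate helpers
#'
#' All public coordinates in this package are 1-based and inclusive
#' (GenBank/GFF3 convention).  On a circular molecule of length \code{L}
#' an interval with \code{start > end} spans the origin and covers
#' \code{start..L} followed by \code{1..end}.
#'
#' @name circular-coordinates
NULL

#' Length of a 1-based inclusive interval, with circular unwrapping
#'
#' @param start,end 1-based inclusive endpoints.
#' @param genomeLength total sequence length; required when
#'   \code{start > end} (origin-spanning interval).
#' @param circular logical; origin-spanning intervals are only legal on
#'   circular molecules.
#' @return interval length in nucleotides.
#' @examples
#' intervalLength(8250, 8997)            # 748
#' intervalLength(95, 5, genomeLength = 100)  # 11
#' @export
intervalLength <- function(start, end, genomeLength = NULL, circular = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(c(start, end))) || start < 1L || end < 1L) {
    stop("interval endpoints must be positive integers")
  }
  if (!is.null(genomeLength) &&
      (start > genomeLength || end > genomeLength)) {
    stop("interval endpoint beyond genome length")
  }
  if (start <= end) return(end - start + 1L)
  if (!isTRUE(circular)) stop("start > end on a linear molecule")
  if (is.null(genomeLength)) {
    stop("genomeLength required for an origin-spanning interval")
  }
  as.integer(genomeLength) - start + 1L + end
}

#' Enumerate the positions of a (possibly origin-spanning) interval
#' @inheritParams intervalLength
#' @return integer vector of genomic positions in 5'->3' order on the
#'   plus strand.
#' @export
intervalPositions <- function(start, end, genomeLength = NULL,
                              circular = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  if (start <= end) return(start:end)
  if (!isTRUE(circular)) stop("start > end on a linear molecule")
  if (is.null(genomeLength)) {
    stop("genomeLength required for an origin-spanning interval")
  }
  c(start:as.integer(genomeLength), 1:end)
}

#' Extract the sequence of an interval from a genome
#'
#' Honors circular wrap-around and strand (minus-strand intervals are
#' reverse-complemented so the result reads 5'->3' on the annotated
#' strand).
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param start,end 1-based inclusive endpoints on the plus strand.
#' @param strand \code{"+"} or \code{"-"}.
#' @return character DNA sequence.
#' @export
extractInterval <- function(genome, start, end, strand = "+") {
  stopifnot(is(genome, "CircularGenome"))
  pos <- intervalPositions(start, end, genomeLength(genome),
    isCircularGenome(genome))
  s <- paste(strsplit(genomeSequence(genome), "")[[1]][pos], collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Interval (start, end, length) of a named feature
#' @param genome a \linkS4class{CircularGenome}.
#' @param name feature name as in the feature table.
#' @return list with \code{start}, \code{end}, \code{strand}, \code{length}.
#' @export
featureInterval <- function(genome, name) {
  ft <- genomeFeatures(genome)
  k <- which(ft$name == name)
  if (!length(k)) stop(sprintf("no feature named '%s'", name))
  k <- k[1]
  list(start = ft$start[k], end = ft$end[k], strand = ft$strand[k],
    length = intervalLength(ft$start[k], ft$end[k], genomeLength(genome),
      isCircularGenome(genome)))
}

roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
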