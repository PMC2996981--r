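#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importFrom Biostrings DNAString
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom stats setNames chisq.test rgeom rpois runif
NULL

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N")
RNA_ALPHABET_STRICT <- c("A", "C", "G", "U", "N")
FEATURE_KINDS <- c("tRNA", "rRNA_fragment", "CDS", "other")
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Circular (or linear) genome with 1-based inclusive gene features
#'
#' Container for a single mitochondrial-genome-like molecule: a DNA
#' sequence, a circularity flag, and a feature table using GenBank-style
#' 1-based inclusive coordinates.  On a circular molecule a feature with
#' \code{start > end} spans the sequence origin (it covers positions
#' \code{start..L} followed by \code{1..end}).
#'
#' @slot accession single identifier string.
#' @slot sequence a \linkS4class{DNAString} over A/C/G/T/N.
#' @slot circular logical flag; origin-spanning features require \code{TRUE}.
#' @slot features \code{data.frame} with columns \code{name}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}) and \code{kind}
#'   (one of tRNA, rRNA_fragment, CDS, other).
#'
#' @seealso [circularGenome()], [genomeLength()], [featureInterval()]
#' @export
setClass("CircularGenome",
  representation(
    accession = "character",
    sequence = "DNAString",
    circular = "logical",
    features = "data.frame"
  )
)

emptyFeatureTable <- function() {
  data.frame(
    name = character(0), start = integer(0), end = integer(0),
    strand = character(0), kind = character(0),
    stringsAsFactors = FALSE
  )
}

setValidity("CircularGenome", function(object) {
  msgs <- character(0)
  if (length(object@accession) != 1L || is.na(object@accession)) {
    msgs <- c(msgs, "accession must be a single non-NA string")
  }
  L <- length(object@sequence)
  if (L < 1L) msgs <- c(msgs, "sequence length must be >= 1")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
    DNA_ALPHABET_STRICT)
  if (length(bad)) {
    msgs <- c(msgs, paste0("sequence contains non-ACGTN characters: ",
      paste(bad, collapse = ", ")))
  }
  ft <- object@features
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(ft))) {
    msgs <- c(msgs, "features must have columns name/start/end/strand/kind")
  } else if (nrow(ft)) {
    if (any(ft$start < 1L | ft$start > L | ft$end < 1L | ft$end > L)) {
      msgs <- c(msgs, "feature coordinates outside [1, genome length]")
    }
    wrap <- ft$start > ft$end
    if (any(wrap) && !isTRUE(object@circular)) {
      msgs <- c(msgs, sprintf(
        "origin-spanning feature '%s' on a linear genome",
        ft$name[which(wrap)[1]]))
    }
    if (!all(ft$strand %in% c("+", "-"))) {
      msgs <- c(msgs, "feature strand must be '+' or '-'")
    }
    if (!all(ft$kind %in% FEATURE_KINDS)) {
      msgs <- c(msgs, "feature kind must be tRNA/rRNA_fragment/CDS/other")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CircularGenome
#'
#' @param accession identifier string.
#' @param sequence character string or \code{DNAString} (uppercased;
#'   \code{U} converted to \code{T}).
#' @param circular logical, default \code{TRUE}.
#' @param features feature \code{data.frame} (see
#'   \linkS4class{CircularGenome}); defaults to none.
#' @return a validated \linkS4class{CircularGenome}.
#' @examples
#' g <- circularGenome("toy", "ACGTACGTAC", features = data.frame(
#'   name = "f1", start = 9, end = 2, strand = "+", kind = "other"))
#' genomeLength(g)
#' @export
circularGenome <- function(accession, sequence, circular = TRUE,
                           features = emptyFeatureTable()) {
  if (is.character(sequence)) {
    sequence <- chartr("u", "t", tolower(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
  } else {
    features <- emptyFeatureTable()
  }
  new("CircularGenome", accession = as.character(accession),
    sequence = sequence, circular = isTRUE(circular), features = features)
}

#' @describeIn circularGenome genome length in nucleotides.
#' @param x a \code{CircularGenome}.
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn circularGenome genome sequence as a character string.
#' @export
genomeSequence <- function(x) as.character(x@sequence)

#' @describeIn circularGenome the feature table.
#' @export
genomeFeatures <- function(x) x@features

#' @describeIn circularGenome accession string.
#' @export
accession <- function(x) x@accession

#' @describeIn circularGenome circularity flag.
#' @export
isCircularGenome <- function(x) x@circular

setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d nt, %s, %d features\n",
    object@accession, genomeLength(object),
    if (object@circular) "circular" else "linear",
    nrow(object@features)))
  if (nrow(object@features)) {
    print(utils::head(object@features, 8))
    if (nrow(object@features) > 8) cat("  ...\n")
  }
})

#' RNA secondary structure as a non-redundant base-pair set
#'
#' Holds an (optionally empty) RNA sequence, a two-column matrix of
#' 1-based pair indices with \code{i < j} and each position in at most
#' one pair, a pseudoknot flag, and optional named structural-domain
#' intervals (e.g. the LSU rRNA domains I-VI).
#'
#' @slot sequence RNA string (may be \code{""} when only topology is known).
#' @slot pairs integer matrix with columns \code{i}, \code{j}.
#' @slot pseudoknot logical; \code{TRUE} when pairs cross (one extra
#'   bracket layer in dot-bracket output).
#' @slot domains \code{data.frame(name, start, end)} of template-coordinate
#'   intervals; may have zero rows.
#'
#' @seealso [secondaryStructure()], [readDotBracket()], [readCt()]
#' @export
setClass("SecondaryStructure",
  representation(
    sequence = "character",
    pairs = "matrix",
    pseudoknot = "logical",
    domains = "data.frame"
  )
)

setValidity("SecondaryStructure", function(object) {
  msgs <- character(0)
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns (i, j)")
  if (nrow(p)) {
    if (any(p[, 1] >= p[, 2])) msgs <- c(msgs, "pairs must satisfy i < j")
    idx <- as.vector(p)
    if (any(idx < 1L)) msgs <- c(msgs, "pair indices must be >= 1")
    n <- nchar(object@sequence)
    if (n > 0L && any(idx > n)) {
      msgs <- c(msgs, "pair index beyond sequence length")
    }
    if (anyDuplicated(idx)) {
      msgs <- c(msgs, "a position participates in more than one pair")
    }
    if (!isTRUE(object@pseudoknot) && nrow(p) > 1L && hasCrossingPairs(p)) {
      msgs <- c(msgs, "crossing pairs present but pseudoknot flag not set")
    }
  }
  if (length(msgs)) msgs else TRUE
})

hasCrossingPairs <- function(p) {
  if (nrow(p) < 2L) return(FALSE)
  o <- order(p[, 1])
  p <- p[o, , drop = FALSE]
  for (a in seq_len(nrow(p) - 1L)) {
    for (b in (a + 1L):nrow(p)) {
      if (p[b, 1] < p[a, 2] && p[a, 2] < p[b, 2]) return(TRUE)
    }
  }
  FALSE
}

#' Construct a SecondaryStructure
#'
#' @param sequence RNA sequence (character; \code{T} converted to \code{U});
#'   \code{""} allowed.
#' @param pairs two-column matrix (or data.frame) of 1-based indices; rows
#'   are normalized so that i < j and sorted by i.
#' @param pseudoknot logical; autodetected from crossings when \code{NA}.
#' @param domains optional \code{data.frame(name, start, end)}.
#' @return a validated \linkS4class{SecondaryStructure}.
#' @examples
#' s <- secondaryStructure("GGAACC", cbind(c(1, 2), c(6, 5)))
#' basePairs(s)
#' @export
secondaryStructure <- function(sequence = "", pairs = NULL, pseudoknot = NA,
                               domains = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    pairs <- t(apply(pairs, 1L, range))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  if (is.na(pseudoknot)) pseudoknot <- hasCrossingPairs(pairs)
  if (is.null(domains)) {
    domains <- data.frame(name = character(0), start = integer(0),
      end = integer(0), stringsAsFactors = FALSE)
  }
  sequence <- chartr("Tt", "Uu", toupper(as.character(sequence)))
  new("SecondaryStructure", sequence = sequence, pairs = pairs,
    pseudoknot = isTRUE(pseudoknot), domains = as.data.frame(domains))
}

#' @describeIn secondaryStructure the pair matrix (columns i, j).
#' @param x a \code{SecondaryStructure}.
#' @export
basePairs <- function(x) x@pairs

#' @describeIn secondaryStructure the (possibly empty) RNA sequence.
#' @export
structureSequence <- function(x) x@sequence

#' @describeIn secondaryStructure domain interval table.
#' @export
structureDomains <- function(x) x@domains

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d pairs%s%s\n",
    nchar(object@sequence), nrow(object@pairs),
    if (object@pseudoknot) ", pseudoknotted" else "",
    if (nrow(object@domains)) sprintf(", %d domains", nrow(object@domains))
      else ""))
})

#' Gapped RNA multiple alignment
#'
#' A rectangular multiple alignment over \{A, C, G, U, -\}; the substrate
#' for column-pair covariation statistics.  Stored internally as a
#' character matrix (rows = sequences, columns = alignment columns).
#'
#' @slot ids row identifiers.
#' @slot mat character matrix of single letters.
#'
#' @seealso [rnaAlignment()], [covariationMatrix()]
#' @export
setClass("RnaAlignment",
  representation(ids = "character", mat = "matrix")
)

setValidity("RnaAlignment", function(object) {
  msgs <- character(0)
  if (nrow(object@mat) < 2L) msgs <- c(msgs, "alignment needs >= 2 rows")
  if (length(object@ids) != nrow(object@mat)) {
    msgs <- c(msgs, "ids length must equal row count")
  }
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate row ids")
  bad <- setdiff(unique(as.vector(object@mat)), c("A", "C", "G", "U", "-"))
  if (length(bad)) {
    msgs <- c(msgs, paste0("letters outside {A,C,G,U,-}: ",
      paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RnaAlignment from gapped sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (DNA input is converted to RNA).
#' @return an \linkS4class{RnaAlignment}.
#' @examples
#' aln <- rnaAlignment(c(s1 = "AU-G", s2 = "AUCG"))
#' alignmentWidth(aln)
#' @export
rnaAlignment <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- chartr("Tt", "Uu", toupper(seqs))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all aligned sequences must have equal length")
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
    nrow = length(seqs), ncol = w, byrow = TRUE)
  new("RnaAlignment", ids = names(seqs), mat = mat)
}

#' @describeIn rnaAlignment number of alignment columns.
#' @param x an \code{RnaAlignment}.
#' @export
alignmentWidth <- function(x) ncol(x@mat)

#' @describeIn rnaAlignment number of sequences.
#' @export
alignmentDepth <- function(x) nrow(x@mat)

#' @describeIn rnaAlignment the letter matrix.
#' @export
alignmentMatrix <- function(x) {
  m <- x@mat
  rownames(m) <- x@ids
  m
}

#' @describeIn rnaAlignment gapped sequences as a named character vector.
#' @export
alignmentSequences <- function(x) {
  stats::setNames(apply(x@mat, 1L, paste, collapse = ""), x@ids)
}

setMethod("show", "RnaAlignment", function(object) {
  cat(sprintf("RnaAlignment: %d sequences x %d columns\n",
    nrow(object@mat), ncol(object@mat)))
})
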