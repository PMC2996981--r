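#' Read a (multi-record) FASTA file
#'
#' Thin validating wrapper around \code{Biostrings::readBStringSet}.
#' Sequences are uppercased; malformed input is rejected rather than
#' repaired.
#'
#' @param path FASTA file.
#' @param alphabet \code{"DNA"} (U converted to T), \code{"RNA"} (T
#'   converted to U) or \code{"asis"}.
#' @param allowGaps permit \code{-} characters (aligned FASTA).
#' @return named character vector of sequences, in file order.
#' @export
readFasta <- function(path, alphabet = c("DNA", "RNA", "asis"),
                      allowGaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0L) stop(sprintf("empty FASTA file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no records in FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup),
      collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  if (alphabet == "RNA") seqs <- chartr("T", "U", seqs)
  legal <- switch(alphabet,
    DNA = DNA_ALPHABET_STRICT, RNA = RNA_ALPHABET_STRICT,
    asis = c(DNA_ALPHABET_STRICT, "U"))
  if (allowGaps) legal <- c(legal, "-")
  for (k in seq_along(seqs)) {
    ch <- strsplit(seqs[k], "")[[1]]
    bad <- which(!ch %in% legal)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
        ch[bad[1]], bad[1], ids[k]))
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @return invisibly, the path.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

gffKindFromType <- function(type) {
  ifelse(type == "tRNA", "tRNA",
    ifelse(type %in% c("rRNA_fragment", "rRNA"), "rRNA_fragment",
      ifelse(type == "CDS", "CDS", "other")))
}

#' Read gene features from a GFF3 file
#'
#' Parses the 9-column tab format directly (GRanges-based readers cannot
#' represent this package's origin-spanning circular features, encoded as
#' \code{start > end}).  Coordinates are validated against the genome.
#'
#' @param path GFF3 file.
#' @param genome a \linkS4class{CircularGenome}, or a genome length.
#' @param circular used when \code{genome} is a bare length.
#' @return feature \code{data.frame(name, start, end, strand, kind)}.
#' @export
readGff3 <- function(path, genome = NULL, circular = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no feature lines in GFF3 file")
  if (is(genome, "CircularGenome")) {
    L <- genomeLength(genome)
    circular <- isCircularGenome(genome)
  } else {
    L <- if (is.null(genome)) NA_integer_ else as.integer(genome)
  }
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop(sprintf("GFF3 line %d has %d columns, expected 9", k, length(f)))
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("GFF3 line %d: non-numeric coordinates", k))
    }
    if (!is.na(L) && (start > L || end > L || start < 1L || end < 1L)) {
      stop(sprintf("GFF3 line %d: coordinates outside [1, %d]", k, L))
    }
    if (start > end && !isTRUE(circular)) {
      stop(sprintf("GFF3 line %d: start > end on a linear genome", k))
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) strand <- "+"
    name <- sub("^.*(?:ID|Name)=([^;]+).*$", "\\1", f[9], perl = TRUE)
    if (identical(name, f[9])) name <- sprintf("feature%d", k)
    data.frame(name = name, start = start, end = end, strand = strand,
      kind = gffKindFromType(f[3]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a feature table as GFF3
#' @param features feature \code{data.frame} (see
#'   \linkS4class{CircularGenome}).
#' @param seqid sequence id for column 1.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGff3 <- function(features, seqid, path) {
  typeFromKind <- c(tRNA = "tRNA", rRNA_fragment = "rRNA_fragment",
    CDS = "CDS", other = "region")
  lines <- c("##gff-version 3", vapply(seq_len(nrow(features)), function(k) {
    paste(seqid, "rRNAfrag", typeFromKind[[features$kind[k]]],
      features$start[k], features$end[k], ".", features$strand[k], ".",
      sprintf("ID=%s", features$name[k]), sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a dot-bracket secondary structure
#'
#' \code{()} encodes nested pairs; \code{[]} one pseudoknot layer.
#'
#' @param text dot-bracket string (may contain \code{.}, \code{()},
#'   \code{[]}).
#' @param sequence optional RNA sequence of the same length.
#' @return a \linkS4class{SecondaryStructure}.
#' @examples
#' basePairs(readDotBracket("((..))"))
#' @export
readDotBracket <- function(text, sequence = "") {
  ch <- strsplit(text, "")[[1]]
  bad <- which(!ch %in% c(".", "(", ")", "[", "]"))
  if (length(bad)) {
    stop(sprintf("illegal structure character '%s' at position %d",
      ch[bad[1]], bad[1]))
  }
  pairs <- matrix(integer(0), ncol = 2L)
  pk <- FALSE
  for (br in list(c("(", ")"), c("[", "]"))) {
    stack <- integer(0)
    for (k in seq_along(ch)) {
      if (ch[k] == br[1]) {
        stack <- c(stack, k)
      } else if (ch[k] == br[2]) {
        if (!length(stack)) {
          stop(sprintf("unmatched '%s' at position %d", br[2], k))
        }
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        if (br[1] == "[") pk <- TRUE
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) {
      stop(sprintf("unmatched '%s' at position %d", br[1],
        stack[length(stack)]))
    }
  }
  if (nzchar(sequence) && nchar(sequence) != length(ch)) {
    stop("sequence and structure lengths differ")
  }
  s <- secondaryStructure(sequence, pairs, pseudoknot = NA)
  if (nrow(basePairs(s)) && !s@pseudoknot && pk) {
    # bracket layers used but no crossing: still a plain nested structure
    pk <- FALSE
  }
  s
}

#' Render a SecondaryStructure as dot-bracket
#' @param structure a \linkS4class{SecondaryStructure}.
#' @return dot-bracket string (second layer as \code{[]} if needed).
#' @export
writeDotBracket <- function(structure) {
  n <- nchar(structureSequence(structure))
  p <- basePairs(structure)
  if (n == 0L) n <- if (nrow(p)) max(p) else 0L
  out <- rep(".", n)
  if (!nrow(p)) return(paste(out, collapse = ""))
  # greedy layering: first nested layer in (), leftovers in []
  layer1 <- logical(nrow(p))
  taken <- matrix(integer(0), ncol = 2L)
  for (k in order(p[, 1])) {
    cand <- rbind(taken, p[k, ])
    if (!hasCrossingPairs(cand)) {
      layer1[k] <- TRUE
      taken <- cand
    }
  }
  out[p[layer1, 1]] <- "("; out[p[layer1, 2]] <- ")"
  rest <- p[!layer1, , drop = FALSE]
  if (nrow(rest)) {
    if (hasCrossingPairs(rest)) {
      stop("structure needs more than two bracket layers")
    }
    out[rest[, 1]] <- "["; out[rest[, 2]] <- "]"
  }
  paste(out, collapse = "")
}

#' Read a connectivity-table (CT) secondary-structure file
#'
#' Zuker dialect: a header line \code{"N  title"} followed by N rows of
#' six columns (index, base, prev, next, pairing partner or 0, index).
#' Inconsistent pairing columns are rejected.
#'
#' @param path CT file.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
readCt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file")
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head[1]))
  if (is.na(n)) stop("CT header must start with the sequence length")
  if (length(lines) - 1L < n) stop("CT file truncated")
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  base <- vapply(rows, `[`, character(1), 2L)
  partner <- vapply(rows, function(r) as.integer(r[5]), integer(1))
  idx <- vapply(rows, function(r) as.integer(r[1]), integer(1))
  if (!identical(idx, seq_len(n))) stop("CT rows not consecutively numbered")
  if (any(partner < 0L | partner > n)) stop("CT pairing index out of range")
  for (k in seq_len(n)) {
    j <- partner[k]
    if (j != 0L && partner[j] != k) {
      stop(sprintf("inconsistent CT pairing: row %d pairs %d but row %d pairs %d",
        k, j, j, partner[j]))
    }
  }
  pr <- which(partner > seq_len(n))
  pairs <- cbind(pr, partner[pr])
  secondaryStructure(paste(base, collapse = ""), pairs, pseudoknot = NA)
}

#' Write a SecondaryStructure as a CT file
#' @param structure a \linkS4class{SecondaryStructure} with a sequence.
#' @param path output file.
#' @param title header title.
#' @return invisibly, the path.
#' @export
writeCt <- function(structure, path, title = "structure") {
  seq <- structureSequence(structure)
  n <- nchar(seq)
  if (n == 0L) stop("cannot write CT without a sequence")
  partner <- integer(n)
  p <- basePairs(structure)
  if (nrow(p)) {
    partner[p[, 1]] <- p[, 2]
    partner[p[, 2]] <- p[, 1]
  }
  b <- strsplit(seq, "")[[1]]
  lines <- c(sprintf("%d  %s", n, title),
    vapply(seq_len(n), function(k) {
      sprintf("%d %s %d %d %d %d", k, b[k], k - 1L,
        if (k == n) 0L else k + 1L, partner[k], k)
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
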