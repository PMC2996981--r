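#' In-silico PCR with IUPAC-degenerate primers
#'
#' Scans circular or linear DNA templates for primer binding sites
#' (degenerate codes matched set-wise), predicts amplicons between
#' forward and reverse sites, and implements the splicing-test decision
#' rule: if two gene fragments are transcribed separately, both
#' fragment-internal products amplify from cDNA while a fragment-spanning
#' product amplifies from neither cDNA nor the (fragmented) genomic DNA.
#'
#' @name insilico-pcr
NULL

IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Construct a validated primer
#' @param name primer name.
#' @param sequence IUPAC oligonucleotide (5'->3'), length >= 10.
#' @param role \code{"forward"} or \code{"reverse"}.
#' @return list of class \code{Primer}.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- chartr("U", "T", toupper(sequence))
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d of primer %s",
      ch[bad[1]], bad[1], name))
  }
  if (length(ch) < 10L) stop("primer must be at least 10 nt")
  structure(list(name = name, sequence = sequence, role = role),
    class = "Primer")
}

#' Compare a primer window with a template window
#'
#' A template base matches a primer IUPAC code iff it belongs to the
#' code's base set (W = \{A,T\}, K = \{G,T\}, M = \{A,C\}, Y = \{C,T\},
#' ...).  An ambiguous template base only matches when its set is
#' contained in the primer code's set.
#'
#' @param primerWindow,templateWindow equal-length DNA strings.
#' @param maxMismatch mismatch budget for the \code{matches} flag.
#' @return list with \code{matches} (logical) and \code{mismatches}
#'   (count).
#' @export
iupacMatch <- function(primerWindow, templateWindow, maxMismatch = 0L) {
  p <- strsplit(toupper(primerWindow), "")[[1]]
  t <- strsplit(toupper(templateWindow), "")[[1]]
  if (length(p) != length(t)) stop("window lengths differ")
  mm <- sum(!iupacPositionMatches(p, t))
  list(matches = mm <= maxMismatch, mismatches = mm)
}

iupacPositionMatches <- function(p, t) {
  bad <- which(!p %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("non-IUPAC primer character '%s'", p[bad[1]]))
  }
  bad <- which(!t %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("non-IUPAC template character '%s'", t[bad[1]]))
  }
  vapply(seq_along(p), function(k) {
    all(IUPAC_SETS[[t[k]]] %in% IUPAC_SETS[[p[k]]])
  }, logical(1))
}

revcompIupac <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

templateToScan <- function(template, primerLen) {
  if (is(template, "CircularGenome")) {
    seq <- genomeSequence(template)
    circ <- isCircularGenome(template)
  } else {
    seq <- chartr("U", "T", toupper(as.character(template)))
    circ <- isTRUE(attr(template, "circular"))
  }
  L <- nchar(seq)
  scan <- if (circ && L > 1L) {
    paste0(seq, substr(seq, 1L, min(primerLen - 1L, L)))
  } else seq
  list(seq = seq, scan = scan, L = L, circular = circ)
}

# 4-bit base-set encoding of the IUPAC codes (A=1, C=2, G=4, T=8)
IUPAC_BITS <- vapply(IUPAC_SETS, function(set) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[set])
}, integer(1))

iupacEncode <- function(chars, what) {
  code <- IUPAC_BITS[chars]
  if (anyNA(code)) {
    stop(sprintf("non-IUPAC %s character '%s'", what,
      chars[which(is.na(code))[1]]))
  }
  unname(code)
}

scanOneStrand <- function(scanChars, L, circular, oligo, maxMismatch,
                          threePrimeAt, end3Mismatch = 0L) {
  p <- iupacEncode(strsplit(oligo, "")[[1]], "primer")
  tcode <- iupacEncode(scanChars, "template")
  w <- length(p)
  nStart <- if (circular) L else (L - w + 1L)
  if (nStart < 1L || length(tcode) < w) {
    return(list(start = integer(0), mismatches = integer(0)))
  }
  starts <- seq_len(nStart)
  mm <- integer(nStart)
  mm3 <- integer(nStart)
  tailIdx <- if (threePrimeAt == "right") (w - 2L):w else 1:3
  for (k in seq_len(w)) {
    tk <- tcode[starts + k - 1L]
    miss <- bitwAnd(p[k], tk) != tk  # template set not within primer set
    mm <- mm + miss
    if (k %in% tailIdx) mm3 <- mm3 + miss
  }
  keep <- mm <= maxMismatch & mm3 <= end3Mismatch
  list(start = starts[keep], mismatches = mm[keep])
}

#' Find primer binding sites on a template
#'
#' Forward-role primers are scanned along the plus strand; reverse-role
#' primers are scanned as their reverse complement, still reported in
#' plus-strand coordinates with strand \code{"-"}.  Circular templates
#' are scanned across the origin.  Besides the overall mismatch budget,
#' the 3'-terminal \code{end3} bases of the primer must match exactly
#' (polymerase-extension realism).
#'
#' @param template a \linkS4class{CircularGenome}, or a character
#'   sequence (set \code{attr(x, "circular") <- TRUE} for circular).
#' @param primer a \code{\link{primer}} object.
#' @param maxMismatch total mismatch budget (default 2).
#' @param end3Mismatch mismatches tolerated in the primer's last 3
#'   bases (default 0).
#' @return \code{data.frame(position, strand, mismatches)};
#'   \code{position} is the 5'-most plus-strand coordinate of the
#'   footprint.
#' @export
findSites <- function(template, primer, maxMismatch = 2L,
                      end3Mismatch = 0L) {
  stopifnot(inherits(primer, "Primer"))
  tl <- templateToScan(template, nchar(primer$sequence))
  scanChars <- strsplit(tl$scan, "")[[1]]
  if (primer$role == "forward") {
    oligo <- primer$sequence
    threePrimeAt <- "right"
    strand <- "+"
  } else {
    oligo <- revcompIupac(primer$sequence)
    threePrimeAt <- "left"   # primer 3' end maps to footprint's left edge
    strand <- "-"
  }
  res <- scanOneStrand(scanChars, tl$L, tl$circular, oligo, maxMismatch,
    threePrimeAt, end3Mismatch)
  if (!length(res$start)) {
    return(data.frame(position = integer(0), strand = character(0),
      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(position = res$start, strand = strand,
    mismatches = res$mismatches, stringsAsFactors = FALSE)
}

#' Predict PCR amplicons on a template
#'
#' One amplicon is reported for every (forward site, reverse site)
#' ordered pair whose product length, measured from the forward
#' footprint's 5' start to the reverse footprint's 3' end (inclusive,
#' wrapping the origin on circular templates), is at least the two
#' primer footprints and at most \code{maxLen}.
#'
#' @inheritParams findSites
#' @param fwd,rev \code{\link{primer}} objects (roles forward/reverse).
#' @param maxLen maximum product length (default 5000; guards against
#'   spurious giant circular products).
#' @return \code{data.frame(fwd_start, rev_end, length, fwd_mismatches,
#'   rev_mismatches)}; zero rows means "no product".
#' @export
amplify <- function(template, fwd, rev, maxMismatch = 2L, maxLen = 5000L,
                    end3Mismatch = 0L) {
  tl <- templateToScan(template, 1L)
  fSites <- findSites(template, fwd, maxMismatch, end3Mismatch)
  rSites <- findSites(template, rev, maxMismatch, end3Mismatch)
  out <- data.frame(fwd_start = integer(0), rev_end = integer(0),
    length = integer(0), fwd_mismatches = integer(0),
    rev_mismatches = integer(0), stringsAsFactors = FALSE)
  if (!nrow(fSites) || !nrow(rSites)) return(out)
  wR <- nchar(rev$sequence)
  minLen <- nchar(fwd$sequence) + wR
  for (a in seq_len(nrow(fSites))) {
    for (b in seq_len(nrow(rSites))) {
      fStart <- fSites$position[a]
      rEnd <- rSites$position[b] + wR - 1L
      if (tl$circular) {
        len <- ((rEnd - fStart) %% tl$L) + 1L
      } else {
        if (rEnd > tl$L || rEnd < fStart) next
        len <- rEnd - fStart + 1L
      }
      if (len < minLen || len > maxLen) next
      out <- rbind(out, data.frame(fwd_start = fStart,
        rev_end = ((rEnd - 1L) %% tl$L) + 1L, length = len,
        fwd_mismatches = fSites$mismatches[a],
        rev_mismatches = rSites$mismatches[b],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Build cDNA templates from transcripts
#'
#' cDNA synthesis is modeled as a change of alphabet only: the poly(A)
#' tail is retained and each transcript yields one template; fragment
#' transcripts are never joined.
#'
#' @param transcripts named character vector of RNA (or DNA) sequences.
#' @return named character vector of DNA templates.
#' @export
buildCdna <- function(transcripts) {
  if (!length(transcripts)) stop("empty transcript set")
  toupper(chartr("Uu", "Tt", transcripts))
}

#' Splicing verdict from an amplification-evidence table
#'
#' The documented truth table: the verdict is
#' \code{"spliced_or_contiguous"} whenever the fragment-spanning product
#' amplifies from cDNA; \code{"not_spliced"} when both fragment-internal
#' products amplify from cDNA while the spanning product amplifies from
#' neither cDNA nor genomic DNA; anything else (failed controls, or a
#' spanning product only on genomic DNA) is \code{"inconclusive"}.
#'
#' @param internal5Cdna,internal3Cdna,spanningCdna,spanningGenomic
#'   logical presence/absence of each amplicon class.
#' @return one of \code{"spliced_or_contiguous"}, \code{"not_spliced"},
#'   \code{"inconclusive"}.
#' @export
splicingVerdict <- function(internal5Cdna, internal3Cdna, spanningCdna,
                            spanningGenomic) {
  if (isTRUE(spanningCdna)) return("spliced_or_contiguous")
  if (isTRUE(internal5Cdna) && isTRUE(internal3Cdna) &&
      !isTRUE(spanningGenomic)) {
    return("not_spliced")
  }
  "inconclusive"
}

#' Run the full in-silico splicing test
#'
#' Amplifies three primer sets (internal to the 5' fragment, internal to
#' the 3' fragment, and fragment-spanning) on the genomic template and
#' on every cDNA template, assembles the evidence table, and applies
#' \code{\link{splicingVerdict}}.
#'
#' @param genomicTemplate a \linkS4class{CircularGenome} or character
#'   template.
#' @param cdnaTemplates named character vector of cDNA templates (see
#'   \code{\link{buildCdna}}).
#' @param primerSets named list with elements \code{internal5},
#'   \code{internal3}, \code{spanning}; each a
#'   \code{list(fwd = , rev = )} of \code{\link{primer}} objects.
#' @param maxMismatch,maxLen,end3Mismatch passed to
#'   \code{\link{amplify}}.
#' @return list with \code{verdict}, logical \code{evidence}, and the
#'   per-template amplicon tables in \code{amplicons}.
#' @export
splicingTest <- function(genomicTemplate, cdnaTemplates, primerSets,
                         maxMismatch = 2L, maxLen = 5000L,
                         end3Mismatch = 0L) {
  need <- c("internal5", "internal3", "spanning")
  miss <- setdiff(need, names(primerSets))
  if (length(miss)) {
    stop(sprintf("missing primer set(s): %s", paste(miss, collapse = ", ")))
  }
  ampOnCdna <- function(set) {
    res <- lapply(cdnaTemplates, function(tmpl) {
      amplify(tmpl, set$fwd, set$rev, maxMismatch, maxLen, end3Mismatch)
    })
    do.call(rbind, res)
  }
  g <- lapply(primerSets[need], function(set) {
    amplify(genomicTemplate, set$fwd, set$rev, maxMismatch, maxLen,
      end3Mismatch)
  })
  cd <- lapply(primerSets[need], ampOnCdna)
  evidence <- c(
    internal5_cdna = nrow(cd$internal5) > 0L,
    internal3_cdna = nrow(cd$internal3) > 0L,
    spanning_cdna = nrow(cd$spanning) > 0L,
    spanning_genomic = nrow(g$spanning) > 0L,
    internal5_genomic = nrow(g$internal5) > 0L,
    internal3_genomic = nrow(g$internal3) > 0L)
  verdict <- splicingVerdict(evidence[["internal5_cdna"]],
    evidence[["internal3_cdna"]], evidence[["spanning_cdna"]],
    evidence[["spanning_genomic"]])
  list(verdict = verdict, evidence = evidence,
    amplicons = list(genomic = g, cdna = cd))
}

#' Read a primer table (TSV)
#'
#' Columns: region, name, sequence, role, expected_length,
#' annealing_temp; the last two are informational only.
#'
#' @param path TSV file.
#' @return list of \code{\link{primer}} objects, named by primer name,
#'   with the raw table in \code{attr(, "table")}.
#' @export
readPrimerTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
    comment.char = "#")
  need <- c("name", "sequence", "role")
  if (!all(need %in% names(tab))) {
    stop("primer TSV needs columns name, sequence, role")
  }
  ps <- lapply(seq_len(nrow(tab)), function(k) {
    primer(tab$name[k], tab$sequence[k], tab$role[k])
  })
  names(ps) <- tab$name
  attr(ps, "table") <- tab
  ps
}
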