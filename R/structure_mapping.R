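#' Template-based secondary-structure mapping
#'
#' New rRNA structure models are not folded de novo: the template model
#' of the closest-sequence relative is transferred through a pairwise
#' alignment, and a template pair survives only if both of its positions
#' map to the target and the target letters can still form a canonical
#' (Watson-Crick or GU) pair.  Per-domain retention fractions then drive
#' qualitative presence calls, e.g. the complete loss of LSU domain III
#' in the oyster mitochondrial models.
#'
#' @name structure-mapping
NULL

degap <- function(s) gsub("-", "", s)

#' Position map template -> target from a 2-row gapped alignment
#'
#' @param templateGapped,targetGapped equal-length gapped sequences (the
#'   two rows of a pairwise alignment).
#' @return integer vector over ungapped template positions; entry k is
#'   the ungapped target position aligned to template position k, or
#'   \code{NA} where the target is gapped.  The map is strictly
#'   increasing over its non-NA entries.
#' @export
alignmentPositionMap <- function(templateGapped, targetGapped) {
  a <- strsplit(toupper(templateGapped), "")[[1]]
  b <- strsplit(toupper(targetGapped), "")[[1]]
  if (length(a) != length(b)) stop("alignment rows differ in length")
  ti <- cumsum(a != "-")
  qi <- cumsum(b != "-")
  keep <- a != "-"
  map <- ifelse(b[keep] == "-", NA_integer_, qi[keep])
  as.integer(map)
}

canonicalPair <- function(x, y) paste0(x, y) %in% CANONICAL_PAIRS

#' Map a template structure onto a target sequence
#'
#' @param template a \linkS4class{SecondaryStructure} whose sequence
#'   length matches the ungapped template side of the alignment.
#' @param alignment either a 2-element character vector (gapped
#'   template, gapped target), a path to a 2-row aligned FASTA, or an
#'   integer position map as from \code{\link{alignmentPositionMap}}.
#' @param targetSeq target sequence; derived from the alignment when
#'   omitted.
#' @return \code{list(structure = SecondaryStructure on the target,
#'   report = list(retained, dropped, perDomainRetention))}.  The report
#'   partitions template pairs exactly: \code{nrow(retained) +
#'   nrow(dropped) = nrow(basePairs(template))}.  Each pair is assigned
#'   to the template domain containing its 5' endpoint.
#' @export
mapTemplate <- function(template, alignment, targetSeq = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    rows <- readFasta(alignment, alphabet = "RNA", allowGaps = TRUE)
    if (length(rows) != 2L) stop("aligned FASTA must have exactly 2 rows")
    alignment <- unname(rows)
  }
  if (is.character(alignment)) {
    map <- alignmentPositionMap(alignment[1], alignment[2])
    if (is.null(targetSeq)) targetSeq <- degap(alignment[2])
  } else {
    map <- as.integer(alignment)
    if (is.null(targetSeq)) stop("targetSeq required with a bare map")
  }
  tlen <- nchar(structureSequence(template))
  if (tlen > 0L && length(map) != tlen) {
    stop(sprintf("template length %d does not match alignment (%d)",
      tlen, length(map)))
  }
  mm <- map[!is.na(map)]
  if (length(mm) > 1L && any(diff(mm) <= 0L)) {
    stop("position map must be strictly increasing")
  }
  targetSeq <- chartr("Tt", "Uu", toupper(targetSeq))
  tchars <- strsplit(targetSeq, "")[[1]]
  p <- basePairs(template)
  retained <- matrix(integer(0), ncol = 4L,
    dimnames = list(NULL, c("i", "j", "ti", "tj")))
  dropped <- data.frame(i = integer(0), j = integer(0),
    reason = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1]; j <- p[k, 2]
    ti <- map[i]; tj <- map[j]
    if (is.na(ti)) {
      dropped <- rbind(dropped, data.frame(i = i, j = j,
        reason = "unmapped_i"))
    } else if (is.na(tj)) {
      dropped <- rbind(dropped, data.frame(i = i, j = j,
        reason = "unmapped_j"))
    } else if (!canonicalPair(tchars[ti], tchars[tj])) {
      dropped <- rbind(dropped, data.frame(i = i, j = j,
        reason = "non_canonical"))
    } else {
      retained <- rbind(retained, c(i, j, ti, tj))
    }
  }
  targetPairs <- retained[, c("ti", "tj"), drop = FALSE]
  structure <- secondaryStructure(targetSeq, targetPairs, pseudoknot = NA)
  perDomain <- NULL
  dom <- structureDomains(template)
  if (nrow(dom)) {
    perDomain <- vapply(seq_len(nrow(dom)), function(d) {
      inDom <- p[, 1] >= dom$start[d] & p[, 1] <= dom$end[d]
      if (!any(inDom)) return(NA_real_)
      kept <- if (nrow(retained)) {
        sum(retained[, "i"] >= dom$start[d] & retained[, "i"] <= dom$end[d])
      } else 0L
      kept / sum(inDom)
    }, numeric(1))
    names(perDomain) <- dom$name
  }
  list(structure = structure,
    report = list(retained = retained, dropped = dropped,
      perDomainRetention = perDomain,
      nTemplatePairs = nrow(p)))
}

checkDomainMap <- function(domainMap) {
  need <- c("name", "start", "end")
  if (!all(need %in% names(domainMap))) {
    stop("domain map needs columns name, start, end")
  }
  dm <- domainMap[order(domainMap$start), , drop = FALSE]
  if (nrow(dm) > 1L && any(dm$start[-1] <= dm$end[-nrow(dm)])) {
    stop("overlapping domain intervals in domain map")
  }
  invisible(domainMap)
}

#' Call per-domain presence from retention fractions
#'
#' A domain is called \code{absent} when its retention fraction is 0 or
#' below \code{absentBelow}, \code{present} when it is 1 or above
#' \code{presentAbove}, otherwise \code{partial}.
#'
#' @param x a mapping report from \code{\link{mapTemplate}} or a named
#'   numeric vector of per-domain retention fractions.
#' @param domainMap optional \code{data.frame(name, start, end)}; when
#'   given, intervals are validated (no overlap) and attached to the
#'   result.
#' @param absentBelow,presentAbove call thresholds (defaults 0.1 / 0.9).
#' @return \code{data.frame(name, retention, call)} (plus
#'   \code{start}/\code{end} when a domain map is supplied).
#' @export
domainPresence <- function(x, domainMap = NULL, absentBelow = 0.1,
                           presentAbove = 0.9) {
  ret <- if (is.list(x) && !is.null(x$perDomainRetention)) {
    x$perDomainRetention
  } else if (is.list(x) && !is.null(x$report)) {
    x$report$perDomainRetention
  } else x
  if (is.null(ret)) stop("no per-domain retention available")
  call <- ifelse(ret == 0 | ret < absentBelow, "absent",
    ifelse(ret == 1 | ret > presentAbove, "present", "partial"))
  out <- data.frame(name = names(ret), retention = as.numeric(ret),
    call = call, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(domainMap)) {
    checkDomainMap(domainMap)
    out <- merge(out, domainMap[, c("name", "start", "end")], by = "name",
      sort = FALSE)
  }
  out
}

#' Report named regions against domain presence calls
#'
#' For each region (e.g. a peptide-exit-tunnel segment on template
#' coordinates) lists the domains it intersects and whether any of them
#' is called absent.
#'
#' @param domainCalls output of \code{\link{domainPresence}} including
#'   \code{start}/\code{end} columns (i.e. called with a domain map).
#' @param regionMap \code{data.frame(name, start, end)} on the same
#'   template coordinate system.
#' @return \code{data.frame(region, domains, any_absent)}.
#' @export
regionOverlapReport <- function(domainCalls, regionMap) {
  if (!all(c("start", "end") %in% names(domainCalls))) {
    stop("domainCalls must carry start/end (call domainPresence with a domain map)")
  }
  rows <- lapply(seq_len(nrow(regionMap)), function(k) {
    rs <- regionMap$start[k]; re <- regionMap$end[k]
    hit <- which(domainCalls$start <= re & domainCalls$end >= rs)
    data.frame(region = regionMap$name[k],
      domains = paste(domainCalls$name[hit], collapse = ","),
      any_absent = any(domainCalls$call[hit] == "absent"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check that a fragmentation site falls between domains II and IV
#'
#' The break is the open region between the 5' fragment's last position
#' and the 3' fragment's first position (template coordinates).  The
#' verdict is \code{TRUE} only when that region lies strictly after the
#' end of domain II and strictly before the start of domain IV.
#'
#' @param frag5Interval,frag3Interval \code{c(start, end)} intervals of
#'   the two fragments on template coordinates.
#' @param domainMap \code{data.frame(name, start, end)} containing
#'   domains \code{"II"} and \code{"IV"}.
#' @return logical verdict.
#' @export
fragmentationSiteCheck <- function(frag5Interval, frag3Interval, domainMap) {
  checkDomainMap(domainMap)
  d2 <- domainMap[domainMap$name == "II", , drop = FALSE]
  d4 <- domainMap[domainMap$name == "IV", , drop = FALSE]
  if (!nrow(d2) || !nrow(d4)) {
    stop("domain map must contain domains II and IV")
  }
  b5 <- frag5Interval[2]; b3 <- frag3Interval[1]
  lo <- b5 + 1L; hi <- b3 - 1L
  if (lo > hi) {
    b5 >= d2$end[1] && b3 <= d4$start[1]
  } else {
    lo > d2$end[1] && hi < d4$start[1]
  }
}
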