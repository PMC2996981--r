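#' Simulation configuration for a fragmented-rRNA mitochondrial genome
#'
#' Defaults emulate the *C. virginica* arrangement: a circular molecule of
#' 17,244 nt whose LSU rRNA gene is split into a 5' fragment at
#' 8250..8997 and a 3' fragment at 1712..2430, the two halves separated
#' by tRNA and protein-coding spacer genes, with a tRNA ending
#' immediately upstream of the 5' fragment and a CDS ending immediately
#' upstream of the 3' fragment (their polyadenylated transcripts bound
#' the rRNA fragments, as real EST data show).
#'
#' @param genomeLength circular genome size (nt).
#' @param frag5,frag3 \code{c(start, end)} intervals of the two rRNA
#'   fragments (1-based inclusive, plus strand).
#' @param spacerFeatures \code{data.frame(kind, length)} of genes packed
#'   5'->3' into the region between \code{frag5} end and \code{frag3}
#'   start; default 10 tRNAs (68 nt) and 8 CDS (800 nt).
#' @param estCount number of ESTs to simulate per gene.
#' @param truncGeometricP per-base probability governing the geometric 5'
#'   truncation of each EST.
#' @param errorRate per-base substitution (sequencing-error) probability.
#' @param polyaMean mean non-templated poly(A) tail length (Poisson).
#' @param atContent genome A+T fraction (mitochondrial genomes are
#'   AT-rich).
#' @param seed integer seed; every emission is reproducible from
#'   (config, seed).
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(genomeLength = 17244L,
                      frag5 = c(8250L, 8997L),
                      frag3 = c(1712L, 2430L),
                      spacerFeatures = NULL,
                      estCount = 200L,
                      truncGeometricP = 0.01,
                      errorRate = 0.005,
                      polyaMean = 30,
                      atContent = 0.65,
                      seed = 1L) {
  if (is.null(spacerFeatures)) {
    spacerFeatures <- data.frame(
      kind = rep(c("tRNA", "CDS"), c(10L, 8L)),
      length = rep(c(68L, 800L), c(10L, 8L)),
      stringsAsFactors = FALSE)
  }
  cfg <- list(genomeLength = as.integer(genomeLength),
    frag5 = as.integer(frag5), frag3 = as.integer(frag3),
    spacerFeatures = spacerFeatures, estCount = as.integer(estCount),
    truncGeometricP = truncGeometricP, errorRate = errorRate,
    polyaMean = polyaMean, atContent = atContent, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  L <- cfg$genomeLength
  if (L < 100L) stop("genomeLength too small to place features")
  for (nm in c("frag5", "frag3")) {
    iv <- cfg[[nm]]
    if (length(iv) != 2L || any(iv < 1L) || any(iv > L)) {
      stop(sprintf("%s interval outside [1, %d]", nm, L))
    }
  }
  p5 <- intervalPositions(cfg$frag5[1], cfg$frag5[2], L)
  p3 <- intervalPositions(cfg$frag3[1], cfg$frag3[2], L)
  if (length(intersect(p5, p3))) stop("frag5 and frag3 intervals overlap")
  probs <- c(cfg$truncGeometricP, cfg$errorRate, cfg$atContent)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0,1]")
  if (cfg$polyaMean < 0) stop("polyaMean must be >= 0")
  invisible(cfg)
}

randomDna <- function(n, atContent = 0.65) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
    prob = c(atContent / 2, atContent / 2, (1 - atContent) / 2,
      (1 - atContent) / 2)), collapse = "")
}

#' Simulate a circular genome carrying a two-fragment rRNA gene
#'
#' Places the configured 5' and 3' rRNA fragment intervals on a random
#' AT-rich circular sequence, packs the configured spacer genes into the
#' region between the fragment halves, and anchors a tRNA directly
#' upstream of the 5' fragment and a CDS directly upstream of the 3'
#' fragment.  The last templated base of each fragment is forced to be a
#' non-A so the polyadenylation site is identifiable downstream.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return \code{list(genome = CircularGenome, truth = list(...))}; the
#'   truth records the fragment intervals and their sequences.
#' @export
simulateGenome <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  L <- config$genomeLength
  seq <- strsplit(randomDna(L, config$atContent), "")[[1]]
  # polyadenylation-site identifiability: a templated A-run abutting the
  # gene end is operationally indistinguishable from the tail, so the two
  # terminal gene bases are forced non-A
  for (iv in list(config$frag5, config$frag3)) {
    if (seq[iv[2]] == "A") seq[iv[2]] <- "G"
    if (seq[iv[2] - 1L] == "A") seq[iv[2] - 1L] <- "C"
  }
  feats <- data.frame(
    name = c("LSU_frag5", "LSU_frag3"),
    start = c(config$frag5[1], config$frag3[1]),
    end = c(config$frag5[2], config$frag3[2]),
    strand = "+", kind = "rRNA_fragment", stringsAsFactors = FALSE)
  wrap1 <- function(p) ((p - 1L) %% L) + 1L
  # upstream anchors (mirroring trnD before the 5' half, cox1 before the 3'),
  # clamped so they fit the available inter-fragment gaps on small genomes
  sep <- fragmentSeparation(L, config$frag5, config$frag3)
  up5len <- min(70L, sep[["gap_b"]])
  up3len <- min(800L, sep[["gap_a"]])
  anchors <- data.frame(
    name = c("trnU5", "cdsU3"),
    start = c(wrap1(config$frag5[1] - up5len),
      wrap1(config$frag3[1] - up3len)),
    end = c(wrap1(config$frag5[1] - 1L), wrap1(config$frag3[1] - 1L)),
    strand = "+", kind = c("tRNA", "CDS"), stringsAsFactors = FALSE)
  feats <- rbind(feats, anchors[c(up5len, up3len) > 0L, , drop = FALSE])
  # spacer genes packed forward from the 5'-fragment end
  cursor <- wrap1(config$frag5[2] + 2L)
  sp <- config$spacerFeatures
  for (k in seq_len(nrow(sp))) {
    s <- cursor
    e <- wrap1(s + sp$length[k] - 1L)
    feats <- rbind(feats, data.frame(
      name = sprintf("spacer_%s_%d", sp$kind[k], k),
      start = s, end = e, strand = "+", kind = sp$kind[k],
      stringsAsFactors = FALSE))
    cursor <- wrap1(e + 2L)
  }
  fragPos <- c(intervalPositions(config$frag5[1], config$frag5[2], L),
    intervalPositions(config$frag3[1], config$frag3[2], L))
  for (k in which(feats$kind != "rRNA_fragment")) {
    if (length(intersect(intervalPositions(feats$start[k], feats$end[k], L),
        fragPos))) {
      stop(sprintf("spacer feature '%s' overlaps an rRNA fragment; %s",
        feats$name[k], "reduce spacer lengths or enlarge the genome"))
    }
  }
  genome <- circularGenome("synthetic_mt", paste(seq, collapse = ""),
    circular = TRUE, features = feats)
  truth <- list(
    frag5 = config$frag5, frag3 = config$frag3,
    frag5Sequence = extractInterval(genome, config$frag5[1], config$frag5[2]),
    frag3Sequence = extractInterval(genome, config$frag3[1], config$frag3[2]),
    genomeLength = L, seed = config$seed)
  list(genome = genome, truth = truth)
}

#' Simulate polyadenylated ESTs from a gene interval
#'
#' Each EST is the gene sequence truncated at a geometric random 5'
#' point, substituted base-by-base at the configured error rate, with a
#' Poisson-length non-templated poly(A) tail appended.
#'
#' @param genome a \linkS4class{CircularGenome}.
#' @param geneInterval \code{c(start, end)} on the plus strand, or a
#'   feature name.
#' @param config a \code{\link{simConfig}}; uses \code{estCount},
#'   \code{truncGeometricP}, \code{errorRate}, \code{polyaMean},
#'   \code{seed}.
#' @return \code{list(ests = named character vector, truth = data.frame(
#'   id, trueStart, trueEnd, tailLength, offset))}; genomic coordinates
#'   are 1-based plus-strand.
#' @export
simulateEsts <- function(genome, geneInterval, config) {
  if (config$estCount <= 0L) stop("estCount must be positive")
  if (is.character(geneInterval)) {
    fi <- featureInterval(genome, geneInterval)
    geneInterval <- c(fi$start, fi$end)
  }
  set.seed(config$seed + 1L)
  pos <- intervalPositions(geneInterval[1], geneInterval[2],
    genomeLength(genome), isCircularGenome(genome))
  gene <- strsplit(extractInterval(genome, geneInterval[1],
    geneInterval[2]), "")[[1]]
  n <- length(gene)
  bases <- c("A", "C", "G", "T")
  ests <- character(config$estCount)
  truth <- data.frame(id = sprintf("est%03d", seq_len(config$estCount)),
    trueStart = NA_integer_, trueEnd = NA_integer_,
    tailLength = NA_integer_, offset = NA_integer_,
    stringsAsFactors = FALSE)
  for (k in seq_len(config$estCount)) {
    off <- if (config$truncGeometricP > 0) {
      stats::rgeom(1L, config$truncGeometricP)
    } else 0L
    off <- min(off, n - 20L)  # keep a mappable templated core
    body <- gene[(off + 1L):n]
    err <- stats::runif(length(body)) < config$errorRate
    if (any(err)) {
      body[err] <- vapply(body[err], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
    }
    tail <- if (config$polyaMean > 0) stats::rpois(1L, config$polyaMean)
      else 0L
    ests[k] <- paste0(paste(body, collapse = ""),
      strrep("A", tail))
    truth$trueStart[k] <- pos[off + 1L]
    truth$trueEnd[k] <- pos[n]
    truth$tailLength[k] <- tail
    truth$offset[k] <- off
  }
  names(ests) <- truth$id
  list(ests = ests, truth = truth)
}

#' Simulate an alignment with compensatory covariation
#'
#' Star-phylogeny sampling from a root sequence: every sequence is an
#' independent draw in which each base pair of the template structure is
#' jointly resampled from the six canonical pair types
#' \{AU, UA, GC, CG, GU, UG\} with probability \code{pairSubRate}
#' (compensatory double substitution), and each unpaired position is
#' independently replaced by one of the three other bases with
#' probability \code{bgSubRate}.
#'
#' @param structure a \linkS4class{SecondaryStructure}; if its sequence
#'   is empty a random canonical-compatible root is generated.
#' @param nSeqs number of sequences (>= 2).
#' @param pairSubRate per-sequence probability of resampling each pair.
#' @param bgSubRate per-sequence per-position background substitution
#'   probability at unpaired columns.
#' @param seed integer seed.
#' @return an \linkS4class{RnaAlignment}; the template's pair set is the
#'   ground truth for pair prediction.
#' @export
simulateStructuredAlignment <- function(structure, nSeqs, pairSubRate,
                                        bgSubRate, seed = 1L) {
  if (nSeqs < 2L) stop("nSeqs must be >= 2")
  if (pairSubRate < 0 || pairSubRate > 1 || bgSubRate < 0 || bgSubRate > 1) {
    stop("substitution rates must be in [0,1]")
  }
  p <- basePairs(structure)
  if (isTRUE(structure@pseudoknot)) stop("nested structure required")
  set.seed(seed)
  seq <- structureSequence(structure)
  n <- if (nzchar(seq)) nchar(seq) else if (nrow(p)) max(p) else
    stop("structure has neither sequence nor pairs")
  root <- if (nzchar(seq)) strsplit(seq, "")[[1]] else {
    r <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    if (nrow(p)) for (k in seq_len(nrow(p))) {
      pt <- strsplit(sample(CANONICAL_PAIRS, 1L), "")[[1]]
      r[p[k, 1]] <- pt[1]; r[p[k, 2]] <- pt[2]
    }
    r
  }
  paired <- if (nrow(p)) sort(as.vector(p)) else integer(0)
  unpaired <- setdiff(seq_len(n), paired)
  rna <- c("A", "C", "G", "U")
  rows <- matrix(rep(root, nSeqs), nrow = nSeqs, byrow = TRUE)
  for (s in seq_len(nSeqs)) {
    if (nrow(p)) {
      resample <- stats::runif(nrow(p)) < pairSubRate
      if (any(resample)) {
        types <- sample(CANONICAL_PAIRS, sum(resample), replace = TRUE)
        ii <- p[resample, 1]; jj <- p[resample, 2]
        rows[s, ii] <- substr(types, 1L, 1L)
        rows[s, jj] <- substr(types, 2L, 2L)
      }
    }
    if (length(unpaired) && bgSubRate > 0) {
      hit <- unpaired[stats::runif(length(unpaired)) < bgSubRate]
      if (length(hit)) {
        rows[s, hit] <- vapply(rows[s, hit], function(b) {
          sample(setdiff(rna, b), 1L)
        }, character(1))
      }
    }
  }
  seqs <- apply(rows, 1L, paste, collapse = "")
  names(seqs) <- sprintf("sim%03d", seq_len(nSeqs))
  rnaAlignment(seqs)
}
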