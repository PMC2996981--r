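#' Published fragment coordinates and primer fixtures
#'
#' The package ships two small plain-text fixtures: the published
#' GenBank coordinates of the oyster LSU rRNA fragments (with the
#' documented genome length where the record's total length is needed
#' for circular arithmetic) and the six splicing-test primers.  Genome
#' sequences themselves are not redistributed; sequence-level statistics
#' require user-supplied FASTA files (see \code{\link{accessionSequence}}).
#'
#' @name fixtures
NULL

#' Published fragment coordinate table
#' @return \code{data.frame} with one row per accession: species,
#'   accession, fragment coordinates, genome length (NA when not
#'   recorded here).
#' @export
publishedFragments <- function() {
  utils::read.delim(system.file("extdata", "published_fragments.tsv",
    package = "rRNAfrag"), stringsAsFactors = FALSE, comment.char = "#")
}

#' Splicing-test primer fixtures
#' @return list of \code{\link{primer}} objects (see
#'   \code{\link{readPrimerTsv}}).
#' @export
splicingPrimers <- function() {
  readPrimerTsv(system.file("extdata", "table1_primers.tsv",
    package = "rRNAfrag"))
}

#' Load a user-supplied accession sequence
#'
#' Looks for \code{<accession>.fasta} under \code{dir} (default: the
#' \code{rRNAfrag.genbankDir} option, falling back to
#' \code{inst/extdata/genbank/}).  GenBank sequences are not shipped
#' with the package; download the accession FASTA yourself and drop it
#' in that directory to enable accession-based statistics.
#'
#' @param accession GenBank accession, e.g. \code{"AY905542"}.
#' @param dir directory holding \code{<accession>.fasta} files.
#' @return the genome as a \linkS4class{CircularGenome}.
#' @export
accessionSequence <- function(accession,
                              dir = getOption("rRNAfrag.genbankDir",
                                system.file("extdata", "genbank",
                                  package = "rRNAfrag"))) {
  path <- if (nzchar(dir)) file.path(dir, paste0(accession, ".fasta")) else ""
  if (!nzchar(dir) || !file.exists(path)) {
    stop(sprintf(paste0(
      "sequence for accession %s not available: place %s.fasta under a ",
      "directory given by options(rRNAfrag.genbankDir = ...)"),
      accession, accession))
  }
  seqs <- readFasta(path, alphabet = "DNA")
  circularGenome(accession, seqs[[1]], circular = TRUE)
}
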