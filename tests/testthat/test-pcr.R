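randomTemplate <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

plantAt <- function(template, oligo, at) {
  paste0(substr(template, 1, at - 1), oligo,
    substr(template, at + nchar(oligo), nchar(template)))
}

test_that("IUPAC codes match set-wise", {
  expect_true(iupacMatch("W", "A")$matches)
  expect_identical(iupacMatch("W", "G")$mismatches, 1L)
  expect_true(iupacMatch("K", "T")$matches)
  expect_true(iupacMatch("M", "C")$matches)
  expect_true(iupacMatch("N", "G")$matches)
  # the degenerate spanning primer matches a realization exactly
  degenerate <- "CTTTWGCAKMATGGCYTTWTGAG"
  realized <- "CTTTTGCAGAATGGCCTTTTGAG"  # W->T, K->G, M->A, Y->C, W->T
  expect_identical(iupacMatch(degenerate, realized)$mismatches, 0L)
  expect_error(iupacMatch("AZ", "AA"), "non-IUPAC")
})

test_that("primer validation rejects malformed oligos", {
  expect_error(primer("p", "ACGTACGTZC", "forward"), "non-IUPAC")
  expect_error(primer("p", "ACGTACG", "forward"), "at least 10")
  p <- primer("p", "acguacguacgu", "reverse")
  expect_identical(p$sequence, "ACGTACGTACGT")
})

test_that("site finding locates planted primers, including across the origin", {
  tmpl <- randomTemplate(1000, seed = 42)
  fwd <- primer("f", "GGATCCTTAAGGCCAT", "forward")
  planted <- plantAt(tmpl, fwd$sequence, 42)
  hits <- findSites(planted, fwd)
  expect_true(any(hits$position == 42 & hits$mismatches == 0))

  expect_identical(nrow(findSites(randomTemplate(400, seed = 9),
    primer("x", "GGGGGGCCCCCCAAAAAT", "forward"))), 0L)

  # origin-spanning site on a circular template
  L <- 200L
  circ <- randomTemplate(L, seed = 7)
  at <- L - 10L
  w <- nchar(fwd$sequence)
  head <- substr(fwd$sequence, 1, L - at + 1L)
  tail <- substr(fwd$sequence, L - at + 2L, w)
  circ <- paste0(substr(circ, 1, at - 1), head)
  circ <- paste0(tail, substr(circ, nchar(tail) + 1L, L))
  attr(circ, "circular") <- TRUE
  hits <- findSites(circ, fwd)
  expect_true(any(hits$position == at & hits$mismatches == 0))
  # the same template scanned as linear misses the wrapped site
  lin <- circ
  attr(lin, "circular") <- FALSE
  expect_false(any(findSites(lin, fwd)$position == at))
})

test_that("reverse primers are matched as their reverse complement", {
  tmpl <- randomTemplate(600, seed = 3)
  site <- "ACCGGTTACAGGTCCA"   # plus-strand footprint
  tmpl <- plantAt(tmpl, site, 301)
  rev <- primer("r", rRNAfrag:::revcompIupac(site), "reverse")
  hits <- findSites(tmpl, rev)
  expect_true(any(hits$position == 301 & hits$strand == "-" &
    hits$mismatches == 0))
})

test_that("amplification length equals the planted inter-primer span", {
  tmpl <- randomTemplate(800, seed = 13)
  fwdSeq <- "GGATCCTTAAGGCCAT"
  revFoot <- "ACCGGTTACAGGTCCA"
  tmpl <- plantAt(tmpl, fwdSeq, 101)
  # outer coordinates 101..200: product length 100
  tmpl <- plantAt(tmpl, revFoot, 200 - nchar(revFoot) + 1L)
  fwd <- primer("f", fwdSeq, "forward")
  rev <- primer("r", rRNAfrag:::revcompIupac(revFoot), "reverse")
  amps <- amplify(tmpl, fwd, rev)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, 100L)

  # no product when primers are absent
  expect_identical(nrow(amplify(randomTemplate(500, 1), fwd, rev)), 0L)
})

test_that("circular products wrap the origin with exact arithmetic", {
  # footprints 86..95 (fwd) and 11..20 (rev) on a 100-nt circle:
  # positions 86..100 plus 1..20 = 35 nt
  L <- 100L
  base <- randomTemplate(L, seed = 23)
  fwdSeq <- "GGTTCCAAGG"
  revFoot <- "CCAATTGGCC"
  tmpl <- plantAt(base, fwdSeq, 86)
  tmpl <- plantAt(tmpl, revFoot, 11)
  attr(tmpl, "circular") <- TRUE
  fwd <- primer("f", fwdSeq, "forward")
  rev <- primer("r", rRNAfrag:::revcompIupac(revFoot), "reverse")
  amps <- amplify(tmpl, fwd, rev, maxLen = 60L)
  expect_true(any(amps$length == 35L))
})

test_that("linearizing a circular template away from sites preserves products", {
  L <- 300L
  base <- randomTemplate(L, seed = 29)
  fwdSeq <- "GGATCCTTAAGGCCAT"
  revFoot <- "ACCGGTTACAGGTCCA"
  tmpl <- plantAt(base, fwdSeq, 40)
  tmpl <- plantAt(tmpl, revFoot, 120)
  circ <- tmpl
  attr(circ, "circular") <- TRUE
  fwd <- primer("f", fwdSeq, "forward")
  rev <- primer("r", rRNAfrag:::revcompIupac(revFoot), "reverse")
  ref <- sort(amplify(circ, fwd, rev)$length)
  set.seed(31)
  # cut points outside both footprints and the product interval
  for (cut in sample(150:295, 6)) {
    lin <- paste0(substr(tmpl, cut + 1, L), substr(tmpl, 1, cut))
    expect_identical(sort(amplify(lin, fwd, rev)$length), ref)
  }
})

test_that("cDNA construction keeps fragments separate", {
  expect_identical(unname(buildCdna(c(x = "ACGUAAAA"))), "ACGTAAAA")
  two <- buildCdna(c(f5 = "ACGU", f3 = "GGCC"))
  expect_identical(length(two), 2L)
  ligated <- buildCdna(c(full = paste0("ACGU", "GGCC")))
  expect_identical(unname(ligated), "ACGTGGCC")
  expect_error(buildCdna(character(0)), "empty")
})

test_that("the splicing verdict matches its truth table on all 16 inputs", {
  for (i5 in c(TRUE, FALSE)) for (i3 in c(TRUE, FALSE)) {
    for (sc in c(TRUE, FALSE)) for (sg in c(TRUE, FALSE)) {
      # independent restatement of the documented decision rule
      expected <- if (sc) {
        "spliced_or_contiguous"
      } else if (i5 && i3 && !sg) {
        "not_spliced"
      } else {
        "inconclusive"
      }
      expect_identical(splicingVerdict(i5, i3, sc, sg), expected)
    }
  }
})

test_that("the end-to-end splicing test separates the two gene architectures", {
  demo <- spliceTestDemo(seed = 6L)
  expect_identical(demo$fragmented$verdict, "not_spliced")
  expect_true(demo$fragmented$evidence[["internal5_cdna"]])
  expect_true(demo$fragmented$evidence[["internal3_cdna"]])
  expect_false(demo$fragmented$evidence[["spanning_cdna"]])
  expect_false(demo$fragmented$evidence[["spanning_genomic"]])
  expect_identical(demo$contiguous$verdict, "spliced_or_contiguous")
  expect_true(demo$contiguous$evidence[["spanning_genomic"]])

  # failed internal control: inconclusive
  sets <- demo$primerSets
  sets$internal5$fwd <- primer("none", "GGGGGGCCCCCCAAAAAT", "forward")
  res <- splicingTest(demo$genome,
    buildCdna(c(t5 = extractInterval(demo$genome, 501, 900))),
    sets, maxLen = 1000L)
  expect_identical(res$verdict, "inconclusive")

  expect_error(splicingTest(demo$genome, c(x = "ACGTACGT"),
    demo$primerSets[c("internal5", "internal3")]),
    "missing primer set")
})
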