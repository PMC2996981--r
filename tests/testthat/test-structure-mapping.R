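templateWithDomains <- function() {
  # 30-nt template, three helices, one per "domain"
  s <- secondaryStructure("GGGGAAAACCCCGGGAAACCCGGGAAACCC",
    rbind(cbind(1:4, 12:9), cbind(13:15, 21:19), cbind(22:24, 30:28)))
  s@domains <- data.frame(name = c("II", "III", "IV"),
    start = c(1L, 13L, 22L), end = c(12L, 21L, 30L),
    stringsAsFactors = FALSE)
  s
}

test_that("identity alignment maps a structure onto itself", {
  tpl <- templateWithDomains()
  seq <- structureSequence(tpl)
  res <- mapTemplate(tpl, c(seq, seq))
  expect_identical(basePairs(res$structure), basePairs(tpl))
  expect_identical(nrow(res$report$dropped), 0L)
  expect_true(all(res$report$perDomainRetention == 1))
  # idempotence: mapping the result again changes nothing
  res2 <- mapTemplate(res$structure, c(seq, seq))
  expect_identical(basePairs(res2$structure), basePairs(tpl))
})

test_that("non-canonical target letters drop the affected pair", {
  tpl <- secondaryStructure("GGAACC", cbind(c(1, 2), c(6, 5)))
  # target has A opposite the template's paired C at position 5
  res <- mapTemplate(tpl, c("GGAACC", "GGAAAC"))
  expect_identical(res$report$dropped$reason, "non_canonical")
  expect_identical(res$report$dropped$i, 2L)
  expect_identical(unname(basePairs(res$structure)),
    matrix(c(1L, 6L), ncol = 2))
})

test_that("a deleted domain loses all its pairs as unmapped", {
  tpl <- templateWithDomains()
  seq <- structureSequence(tpl)
  # delete the whole domain-III interval (13..21) from the target
  gapped <- paste0(substr(seq, 1, 12), strrep("-", 9), substr(seq, 22, 30))
  target <- paste0(substr(seq, 1, 12), substr(seq, 22, 30))
  res <- mapTemplate(tpl, c(seq, gapped), target)
  expect_true(all(grepl("^unmapped", res$report$dropped$reason)))
  expect_identical(res$report$perDomainRetention[["III"]], 0)
  expect_identical(res$report$perDomainRetention[["II"]], 1)

  calls <- domainPresence(res, domainMap = structureDomains(tpl))
  expect_identical(calls$call[calls$name == "III"], "absent")
  expect_identical(calls$call[calls$name == "II"], "present")
})

test_that("the mapping report partitions template pairs exactly", {
  tpl <- templateWithDomains()
  seq <- structureSequence(tpl)
  set.seed(31)
  for (rep in 1:6) {
    keep <- sort(sample(30, sample(12:28, 1L)))
    gapped <- strsplit(seq, "")[[1]]
    gapped[-keep] <- "-"
    res <- mapTemplate(tpl, c(seq, paste(gapped, collapse = "")))
    expect_identical(nrow(res$report$retained) + nrow(res$report$dropped),
      res$report$nTemplatePairs)
  }
})

test_that("retained pairs decrease monotonically under nested deletions", {
  tpl <- templateWithDomains()
  seq <- structureSequence(tpl)
  kept <- integer(0)
  for (ndel in c(0, 3, 6, 9)) {
    gapped <- strsplit(seq, "")[[1]]
    if (ndel > 0) gapped[13:(12 + ndel)] <- "-"
    res <- mapTemplate(tpl, c(seq, paste(gapped, collapse = "")))
    kept <- c(kept, nrow(res$report$retained))
  }
  expect_true(all(diff(kept) <= 0))
})

test_that("domain presence calls follow the two thresholds", {
  ret <- c(II = 0, III = 0.5, IV = 1)
  calls <- domainPresence(ret, absentBelow = 0.1, presentAbove = 0.9)
  expect_identical(calls$call, c("absent", "partial", "present"))
  overlapping <- data.frame(name = c("II", "III"), start = c(1L, 10L),
    end = c(12L, 20L))
  expect_error(domainPresence(ret, domainMap = overlapping), "overlapping")
})

test_that("region overlap reporting flags absent domains", {
  calls <- data.frame(name = c("II", "III", "IV"),
    retention = c(1, 0, 1), call = c("present", "absent", "present"),
    start = c(1L, 13L, 22L), end = c(12L, 21L, 30L),
    stringsAsFactors = FALSE)
  regions <- data.frame(name = c("PET_a", "PET_b", "PET_c"),
    start = c(14L, 2L, 10L), end = c(20L, 8L, 16L),
    stringsAsFactors = FALSE)
  rep <- regionOverlapReport(calls, regions)
  expect_identical(rep$any_absent, c(TRUE, FALSE, TRUE))
  expect_identical(rep$domains, c("III", "II", "II,III"))
})

test_that("fragmentation-site verdict is strict about domain bounds", {
  dm <- data.frame(name = c("II", "IV"), start = c(1L, 40L),
    end = c(20L, 60L), stringsAsFactors = FALSE)
  # break in the open region between II and IV
  expect_true(fragmentationSiteCheck(c(1L, 24L), c(26L, 60L), dm))
  # break inside a downstream domain
  expect_false(fragmentationSiteCheck(c(1L, 45L), c(47L, 60L), dm))
  # break exactly at domain II's last position: strict, so false
  expect_false(fragmentationSiteCheck(c(1L, 19L), c(21L, 60L), dm))
  # adjacent fragments: break point at the junction
  expect_true(fragmentationSiteCheck(c(1L, 25L), c(26L, 60L), dm))
  expect_error(fragmentationSiteCheck(c(1L, 24L), c(26L, 60L),
    data.frame(name = "II", start = 1L, end = 20L)), "II and IV")
})
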