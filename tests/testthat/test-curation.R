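# Report-level curation: version dedup, non-ADR filtering, pair
# aggregation, literature union.

rec <- function(case, ver, cmm = "h1", pt = "Nausea", nd = 1L) {
  data.frame(case_id = case, case_version = ver, cmm_id = cmm, pt = pt,
             n_drugs_in_report = nd, stringsAsFactors = FALSE)
}

test_that("dedupLatestVersion keeps the max version per case", {
  records <- rbind(rec("c1", 1), rec("c1", 2, pt = "Rash"), rec("c2", 1))
  out <- dedupLatestVersion(records)
  # independent oracle: per-case max version
  oracle <- tapply(records$case_version, records$case_id, max)
  expect_equal(nrow(out), 2L)
  expect_equal(out$case_version, as.numeric(oracle[out$case_id]))
  expect_equal(out$pt[out$case_id == "c1"], "Rash")

  expect_equal(nrow(dedupLatestVersion(records[0, ])), 0L)
  expect_equal(dedupLatestVersion(rec("c9", 3)), rec("c9", 3))
  # idempotence
  expect_equal(dedupLatestVersion(out), out)
})

test_that("dedupLatestVersion rejects duplicate (case, version) records", {
  expect_error(dedupLatestVersion(rbind(rec("c1", 1), rec("c1", 1))),
               "duplicate")
  messy <- data.frame(case_id = c("c1", "c1"), case_version = c(2, 2),
                      cmm_id = "h", pt = c("A", "B"))
  expect_error(dedupLatestVersion(messy), "duplicate")
})

test_that("filterNonAdr removes exactly the blacklisted terms", {
  records <- rbind(rec("c1", 1), rec("c2", 1, pt = "Product issues"),
                   rec("c3", 1), rec("c4", 1, pt = "Product issues"),
                   rec("c5", 1, pt = "Rash"))
  out <- filterNonAdr(records, c("Product issues"))
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$removed, 2L)
  expect_false(any(out$records$pt == "Product issues"))

  expect_equal(filterNonAdr(records, character(0))$records, records)
  allBl <- filterNonAdr(records, unique(records$pt))
  expect_equal(nrow(allBl$records), 0L)
  expect_equal(allBl$removed, 5L)
})

test_that("aggregatePairs counts records per (cmm, pt) and conserves totals", {
  records <- rbind(rec("c1", 1, cmm = "h1", pt = "A"),
                   rec("c2", 1, cmm = "h1", pt = "A"),
                   rec("c3", 1, cmm = "h2", pt = "B"))
  out <- aggregatePairs(records)
  expect_equal(nrow(out), 2L)
  expect_equal(out$report_count[out$cmm_id == "h1" & out$pt == "A"], 2L)
  expect_equal(out$report_count[out$cmm_id == "h2" & out$pt == "B"], 1L)
  expect_true(all(out$provenance == "faers"))
  # conservation: counts sum to record count (property over a random table)
  set.seed(3)
  rand <- data.frame(
    case_id = sprintf("c%d", 1:200), case_version = 1L,
    cmm_id = sample(sprintf("h%d", 1:8), 200, TRUE),
    pt = sample(LETTERS[1:5], 200, TRUE)
  )
  expect_equal(sum(aggregatePairs(rand)$report_count), 200L)

  expect_equal(nrow(aggregatePairs(records[0, ])), 0L)
  distinct <- rbind(rec("c1", 1, pt = "A"), rec("c2", 1, pt = "B"),
                    rec("c3", 1, pt = "C"))
  expect_true(all(aggregatePairs(distinct)$report_count == 1L))
})

test_that("unionWithLiterature keeps FAERS counts on overlap and sizes add up", {
  faers <- data.frame(cmm_id = c("h1", "h2"), pt = c("A", "B"),
                      report_count = c(4L, 2L), provenance = "faers")
  lit <- data.frame(cmm_id = c("h2", "h3"), pt = c("B", "C"))
  out <- unionWithLiterature(faers, lit)
  expect_equal(nrow(out), 3L) # |faers| + |lit-only|
  ov <- out[out$cmm_id == "h2" & out$pt == "B", ]
  expect_equal(ov$provenance, "faers")
  expect_equal(ov$report_count, 2L)
  litOnly <- out[out$cmm_id == "h3", ]
  expect_equal(litOnly$provenance, "literature")
  expect_equal(litOnly$report_count, 0L)

  # identical single pair in both -> one row, faers wins
  one <- unionWithLiterature(faers[1, ], data.frame(cmm_id = "h1", pt = "A"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$provenance, "faers")
  # both empty
  expect_equal(nrow(unionWithLiterature(faers[0, ], lit[0, ])), 0L)

  # union size identity against brute-force set union on random tables
  set.seed(9)
  f2 <- unique(data.frame(cmm_id = sample(letters[1:6], 40, TRUE),
                          pt = sample(LETTERS[1:6], 40, TRUE)))
  f2$report_count <- 1L
  f2$provenance <- "faers"
  l2 <- unique(data.frame(cmm_id = sample(letters[1:6], 40, TRUE),
                          pt = sample(LETTERS[1:6], 40, TRUE)))
  got <- nrow(unionWithLiterature(f2, l2))
  want <- length(union(paste(f2$cmm_id, f2$pt), paste(l2$cmm_id, l2$pt)))
  expect_equal(got, want)
})

test_that("monotherapySubset keeps exactly the single-drug reports", {
  records <- rbind(rec("c1", 1, nd = 1L), rec("c2", 1, nd = 2L),
                   rec("c3", 1, nd = 1L))
  expect_equal(nrow(monotherapySubset(records)), 2L)
  expect_equal(nrow(monotherapySubset(rec("c1", 1, nd = 3L))), 0L)
  expect_equal(monotherapySubset(records[records$n_drugs_in_report == 1, ]),
               records[records$n_drugs_in_report == 1, ])
})

test_that("curation round-trips the synthetic association table", {
  dat <- smallSynth()
  recs <- generateReportRecords(dat$pairs, seed = 5)
  cur <- curateReports(recs, blacklist = "Product issues")
  faersPairs <- dat$pairs[dat$pairs$provenance == "faers", ]
  got <- cur$associations
  expect_equal(nrow(got), nrow(faersPairs))
  key <- paste(got$cmm_id, got$pt)
  wantKey <- paste(faersPairs$cmm_id, faersPairs$adr_id)
  expect_setequal(key, wantKey)
  expect_equal(got$report_count[match(wantKey, key)], faersPairs$report_count)

  # with contamination and stale versions the round-trip still holds
  recs2 <- generateReportRecords(dat$pairs, versionDupFraction = 0.2,
                                 contamination = 10, seed = 6)
  cur2 <- curateReports(recs2, blacklist = "Product issues")
  got2 <- cur2$associations
  expect_gt(cur2$removed, 0L)
  expect_equal(sort(paste(got2$cmm_id, got2$pt)), sort(wantKey))
  expect_equal(got2$report_count[match(wantKey, paste(got2$cmm_id, got2$pt))],
               faersPairs$report_count)

  # everything blacklisted -> empty curated table
  all_bl <- curateReports(recs, blacklist = unique(recs$pt))
  expect_equal(nrow(all_bl$associations), 0L)
})
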