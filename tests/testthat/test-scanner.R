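test_that("candidate enumeration is exhaustive, ordered and window-length aware", {
  cfg <- scanConfig(windowLengths = 6)
  cands <- enumerateCandidates(paste(rep("ACGTA", 2), collapse = ""), cfg)
  expect_equal(nrow(cands), 5)                     # 10 - 6 + 1
  expect_equal(cands$start, 0:4)
  expect_equal(cands$seq[1], "ACGTAA")
  long <- paste(rep("ACGT", 250), collapse = "")
  both <- enumerateCandidates(long, scanConfig(windowLengths = c(6, 8)))
  expect_equal(nrow(both), 995 + 993)
  expect_equal(nrow(enumerateCandidates(long, scanConfig(windowLengths = integer()))), 0)
  # deterministic order: by position, then length, then strand
  expect_true(!is.unsorted(order(both$start, both$end - both$start)))
  # N windows are dropped
  withN <- enumerateCandidates("ACGTANACGTACGT", scanConfig(windowLengths = 6))
  expect_false(any(grepl("N", withN$seq)))
  expect_equal(nrow(withN), 9 - 6)
  # both-strand mode adds reverse-complement candidates at the same coordinates
  rc <- enumerateCandidates("ACGTACGTAC", scanConfig(windowLengths = 6, strands = "both"))
  expect_equal(sum(rc$strand == "-"), sum(rc$strand == "+"))
  minus <- rc[rc$strand == "-" & rc$start == 0, "seq"]
  expect_equal(minus, "GTACGT")
})

test_that("windows beyond the promoter window are not scanned", {
  cfg <- scanConfig(windowLengths = 6, promoterWindow = 100)
  prom <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  cands <- enumerateCandidates(prom, cfg)
  expect_true(all(400 - cands$start <= 100))
})

test_that("scanning is deterministic and respects interval bounds", {
  w <- engineeredWorld()
  mdl <- defaultFusionModel()
  r1 <- scanPromoters(w$promoter, mdl, w$ref)
  r2 <- scanPromoters(w$promoter, mdl, w$ref)
  expect_identical(scanCandidates(r1), scanCandidates(r2))
  df <- scanCandidates(r1)
  expect_true(all(df$start >= 0 & df$end <= nchar(w$promoter)))
  expect_true(all(df$end > df$start))
  expect_true(all(df$credibility >= 0 & df$credibility <= 1))
  expect_false(is.unsorted(rev(df$credibility)))
  # every candidate is either scored or reported as a conflict reject
  expect_equal(nrow(df) + nrow(scanRejects(r1)), 995 + 993)
})

test_that("hits are monotone in the threshold and exhaustive at threshold zero", {
  w <- engineeredWorld()
  mdl <- defaultFusionModel()
  res <- scanPromoters(w$promoter, mdl, w$ref)
  df <- scanCandidates(res)
  key <- function(d) paste(d$promoter_id, d$start, d$end, d$strand)
  hi <- df[df$credibility >= 0.9, ]
  lo <- df[df$credibility >= 0.5, ]
  expect_true(all(key(hi) %in% key(lo)))
  res0 <- scanPromoters(w$promoter, mdl, w$ref, scanConfig(threshold = 0))
  expect_true(all(scanCandidates(res0)$is_hit))
})

test_that("an engineered AuxRE scans to credibility 1 and an engineered non-AuxRE to 0", {
  w <- engineeredWorld()
  mdl <- defaultFusionModel()
  res <- scanPromoters(w$promoter, mdl, w$ref)
  df <- scanCandidates(res)
  pos <- df[df$start == 292 & df$end == 300, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$credibility, 1, tolerance = 1e-9)
  expect_true(pos$is_hit)
  neg <- df[df$start == 900 & df$end == 908, ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$credibility, 0, tolerance = 1e-9)
  expect_false(neg$is_hit)
})

test_that("a model that dismisses everything yields no hits on a uniform promoter", {
  allH2 <- function(n1, n2) matrix("P4(H2)", n1, n2)
  mdl <- defaultFusionModel()
  dismiss <- new("FusionModel",
                 tablePosSc = regionMassTable("sp", mdl@tablePosSc@axis1,
                                              mdl@tablePosSc@axis2, allH2(3, 4)),
                 tableOD = regionMassTable("od", mdl@tableOD@axis1,
                                           mdl@tableOD@axis2, allH2(4, 3)),
                 tableF1F2 = regionMassTable("ff", mdl@tableF1F2@axis1,
                                             mdl@tableF1F2@axis2, allH2(4, 3)),
                 lda = mdl@lda, threshold = 0.9)
  ref <- makeMiniCollection(10, 300, NULL, responsive = 1:3, seed = 2)$collection
  res <- scanPromoters(c(p = strrep("A", 200)), dismiss, ref)
  expect_equal(nrow(scanHits(res)), 0)
  expect_true(all(scanCandidates(res)$credibility == 0))
})

test_that("scan output writers produce the documented columns", {
  w <- engineeredWorld()
  res <- scanPromoters(w$promoter, defaultFusionModel(), w$ref)
  tsv <- tempfile(fileext = ".tsv")
  writeScanTSV(res, tsv)
  back <- read.delim(tsv)
  expect_equal(ncol(back), 20)
  expect_equal(names(back)[1:5], c("promoter_id", "start", "end", "strand", "seq"))
  bed <- tempfile(fileext = ".bed")
  writeScanBED(res, bed)
  bb <- read.delim(bed, header = FALSE)
  expect_equal(ncol(bb), 6)
  expect_true(all(bb$V5 >= 0 & bb$V5 <= 1000))
})

test_that("the greedy non-overlap filter keeps the best hit of an overlapping run", {
  hits <- data.frame(promoter_id = "p", start = c(0, 2, 10), end = c(8, 10, 18),
                     credibility = c(0.95, 0.99, 0.92))
  kept <- nonOverlappingHits(hits)
  expect_equal(kept$start, c(2, 10))
})
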