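toyCollection <- function() {
  promoterCollection(
    c(p1 = "AAATGTCTCAAA", p2 = "CCCCCCCCCCCC", p3 = "AAATGTCTCGGG"),
    responsive = "p1"
  )
}

test_that("position from the ATG follows the 1-based distance convention", {
  expect_equal(positionFromATG(0, 1000), 1000)   # farthest upstream window
  expect_equal(positionFromATG(994, 1000), 6)    # 6-mer abutting the ATG
  expect_equal(positionFromATG(500, 1000), 500)
  expect_error(positionFromATG(1000, 1000), "start")
  expect_error(positionFromATG(-1, 1000), "start")
})

test_that("Z-curve parameters match hand counts and stay in [-1, 1]", {
  expect_equal(unname(zcurveParams("ACGT")), c(0, 0, 0))
  expect_equal(unname(zcurveParams("AAAA")), c(1, 1, 1))
  expect_equal(unname(zcurveParams("TGTCTC")), c(-2 / 3, -1 / 3, 0))
  expect_error(zcurveParams(""), "nonempty")
  expect_error(zcurveParams("ACGU"), "uppercase")
  # N is excluded from the frequencies
  expect_equal(zcurveParams("ACGTN"), zcurveParams("ACGT"))
  set.seed(9)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    expect_true(all(abs(zcurveParams(s)) <= 1))
  }
})

test_that("reverse complement negates x1 and y1 and preserves z1", {
  set.seed(21)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    z <- zcurveParams(s); zr <- zcurveParams(rc)
    expect_equal(unname(zr), unname(c(-z["x1"], -z["y1"], z["z1"])), tolerance = 1e-12)
    expect_equal(gcContent(s), gcContent(rc))
  }
})

test_that("GC content counts strong bases over ACGT positions", {
  expect_equal(gcContent("GGCC"), 1)
  expect_equal(gcContent("AATT"), 0)
  expect_equal(gcContent("TGTCTC"), 0.5)
  expect_equal(gcContent("GCNNN"), 1)
})

test_that("occurrence counts exact overlapping matches and is additive", {
  coll <- promoterCollection(c(a = "AAAATT", b = "TTTTTT"))
  expect_equal(motifOccurrence("AAAA", coll), 1)
  coll2 <- promoterCollection(c(a = "AAAAAA"))
  expect_equal(motifOccurrence("AAAA", coll2), 3)  # overlapping matches
  expect_equal(motifOccurrence("GGGG", coll2), 0)
  tc <- toyCollection()
  total <- motifOccurrence("TGTCTC", tc)
  parts <- motifOccurrence("TGTCTC", tc, ids = c("p1", "p2")) +
    motifOccurrence("TGTCTC", tc, ids = "p3")
  expect_equal(total, parts)
  # reverse-complement mode adds GAGACA matches
  collRC <- promoterCollection(c(a = "AAGAGACAAA"))
  expect_equal(motifOccurrence("TGTCTC", collRC), 0)
  expect_equal(motifOccurrence("TGTCTC", collRC, bothStrands = TRUE), 1)
  # N never matches
  collN <- promoterCollection(c(a = "AANAAA"))
  expect_equal(motifOccurrence("AAAA", collN), 0)
})

test_that("density is the responsive share of matches, with a 0/0 sentinel", {
  tc <- toyCollection()
  expect_equal(motifDensity("TGTCTC", tc), 0.5)   # one match in p1, one in p3
  expect_equal(motifDensity("CTCAAA", tc), 1)     # only in the responsive p1
  expect_true(is.na(motifDensity("GGGGTT", tc)))  # absent: undefined
  # duplicating every promoter leaves the density unchanged
  seqs <- as.character(promoters(tc))
  dup <- promoterCollection(setNames(rep(seqs, 2), paste0("x", 1:6)),
                            responsive = c("x1", "x4"))
  expect_equal(motifDensity("TGTCTC", dup), motifDensity("TGTCTC", tc))
})

test_that("the overrepresentation z-score matches its closed form", {
  coll <- promoterCollection(c(a = paste(rep("ACGT", 25), collapse = ""),
                               b = paste(rep("TGCA", 25), collapse = "")))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  e <- (2 * 97) * 0.25^4
  expect_equal(significanceScore("AAAA", coll, bg, observed = round(e)),
               (round(e) - e) / sqrt(e), tolerance = 1e-12)
  expect_equal(significanceScore("AAAA", coll, bg, observed = 0), -sqrt(e))
  # monotone in the observed count
  s1 <- significanceScore("AAAA", coll, bg, observed = 3)
  s2 <- significanceScore("AAAA", coll, bg, observed = 4)
  expect_gt(s2, s1)
  # planted enrichment: recompute observed and expected by brute force
  plant <- makeMiniCollection(10, 200,
                              data.frame(motif = "TGTCTCAA", promoter = 1:5, offset = 10),
                              responsive = 1:3, seed = 4)
  obs <- sum(Biostrings::vcountPattern("TGTCTCAA", promoters(plant$collection)))
  bgE <- backgroundFrequencies(plant$collection)
  eBrute <- sum(Biostrings::width(promoters(plant$collection)) - 8 + 1) *
    prod(bgE[c("T", "G", "T", "C", "T", "C", "A", "A")])
  expect_equal(significanceScore("TGTCTCAA", plant$collection),
               (obs - eBrute) / sqrt(eBrute), tolerance = 1e-9)
})

test_that("bulk k-mer statistics agree with direct pattern counting", {
  ref <- makeMiniCollection(8, 300, NULL, responsive = 1:2, seed = 6)$collection
  st <- AuxREfusion:::.kmerStats(ref, 6)
  for (w in c("ACGTAC", "TTTTTT", "TGTCTC")) {
    expect_equal(st[w, "count"], motifOccurrence(w, ref))
    expect_equal(st[w, "respCount"],
                 motifOccurrence(w, ref, ids = responsiveIds(ref)))
  }
  known <- st$count > 0
  expect_equal(st$density[known], st$respCount[known] / st$count[known])
  expect_true(all(is.na(st$density[!known])))
})

test_that("promoter collections validate names, alphabet and responsive ids", {
  expect_error(promoterCollection(c("ACGT", "ACGT")), "unique")
  expect_error(promoterCollection(c(a = "ACGT"), responsive = "zz"), "subset")
  # lowercase input is normalized to uppercase by the sequence container
  expect_equal(as.character(promoters(promoterCollection(c(a = "acgt")))),
               c(a = "ACGT"))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "ACGTACGT", ">p2", "TTTTACGT"), fa)
  ids <- tempfile()
  writeLines("p1", ids)
  coll <- readPromoterCollection(fa, ids)
  expect_equal(names(promoters(coll)), c("p1", "p2"))
  expect_equal(responsiveIds(coll), "p1")
})
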