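## Synthetic stand-ins for the unpublished training data: a 64-element
## training table with the documented class structure and per-region class
## proportions, and planted promoter collections for occurrence/density
## work. These emulate the published summary structure (class counts, region
## percentages); they are not reconstructions of the original measurements.

#' The 14 AuxRE spike variants
#'
#' TGTCTC-family cores with single A/T flanking bases, used by the
#' gold-standard benchmark and the planted reference collection.
#'
#' @return character vector of 14 distinct 8-mers.
#' @export
auxreVariants <- function() {
  c("ATGTCTCA", "ATGTCTCT", "TTGTCTCA", "TTGTCTCT",
    "ATGTCCCA", "ATGTCCCT", "TTGTCCCA", "TTGTCCCT",
    "ATGTCACA", "ATGTCACT", "TTGTCACA", "TTGTCACT",
    "ATGTCGCA", "TTGTCGCT")
}

## class -> example sequences used to give training rows realistic motifs
.CLASS_SEQS <- list(
  AuxRE  = NULL, # drawn from auxreVariants()
  ABRE   = c("TACGTGGC", "CACGTGGC", "TACGTGTC", "CACGTGTC"),
  TATA   = c("TATAAATA", "TATATATA", "CTATAAAT", "TTATAAAT"),
  Ypatch = c("CTTCTTCC", "TCTTCTTC", "CCTTCTTC", "TTCTTCTC"),
  DRE    = c("TACCGACA", "AGCCGACA", "TGCCGACT", "TACCGACT")
)

.CLASS_COUNTS <- c(AuxRE = 16L, ABRE = 12L, TATA = 16L, Ypatch = 11L, DRE = 9L)

## Per-graph cell assignments: for each class, how many of its motifs fall in
## each grid cell. Counts invert the printed per-region class proportions
## (e.g. cell R23 is 80% AuxRE: 4 AuxRE + 1 other).
.G1_CELLS <- list(
  AuxRE  = c(R11 = 1, R12 = 1, R23 = 4, R21 = 2, R22 = 2, R31 = 2, R32 = 2, R33 = 2),
  ABRE   = c(R13 = 6, R14 = 2, R24 = 2, R34 = 2),
  TATA   = c(R11 = 9, R14 = 3, R24 = 2, R34 = 2),
  Ypatch = c(R11 = 4, R12 = 3, R23 = 1, R14 = 1, R24 = 1, R34 = 1),
  DRE    = c(R13 = 4, R14 = 1, R24 = 2, R34 = 2)
)
.G2_CELLS <- list(
  AuxRE  = c(D11 = 3, D12 = 1, D22 = 10, D41 = 2),
  ABRE   = c(D13 = 5, D23 = 5, D42 = 2),
  TATA   = c(D11 = 4, D21 = 5, D31 = 5, D42 = 2),
  Ypatch = c(D12 = 7, D22 = 1, D43 = 3),
  DRE    = c(D32 = 4, D33 = 4, D43 = 1)
)
## graph-3 class footprints are kept compact (adjacent cells) so the fixture's
## within-class scatter stays small relative to the class-mean separation and
## a discriminant refit recovers the construction axes
.G3_CELLS <- list(
  AuxRE  = c(Q22 = 14, Q31 = 2),
  ABRE   = c(Q11 = 3, Q12 = 5, Q13 = 4),
  TATA   = c(Q31 = 13, Q32 = 3),
  Ypatch = c(Q21 = 1, Q22 = 6, Q23 = 4),
  DRE    = c(Q32 = 2, Q33 = 1, Q42 = 2, Q43 = 4)
)

## Sampling boxes: for each axis, the interval (inside the set's plateau,
## with a safety margin off the transition bands) that fixture values are
## drawn from, per set index.
.FIX_BOX <- list(
  position   = list(c(30, 180), c(270, 430), c(580, 950)),
  score      = list(c(-1, 1.8), c(5.2, 6.3), c(8.5, 13.5), c(19, 30)),
  occurrence = list(c(1, 4), c(10, 36), c(55, 140), c(230, 400)),
  density    = list(c(0.02, 0.23), c(0.38, 0.62), c(0.78, 0.98)),
  f1         = list(c(-1.24, -1.15), c(-0.62, -0.32), c(0.18, 0.38), c(0.64, 0.95)),
  f2         = list(c(-0.45, -0.24), c(0.05, 0.25), c(0.52, 0.80))
)

.cellIdx <- function(cell) {
  c(i = as.integer(substr(cell, 2L, 2L)), j = as.integer(substr(cell, 3L, 3L)))
}

.expandCells <- function(cellTable) {
  unlist(lapply(names(cellTable), function(cls) {
    rep(names(cellTable[[cls]]), cellTable[[cls]])
  }))
}

#' Generate the synthetic 64-motif training fixture
#'
#' Emulates the training set behind the region tables: 64 cis-elements over
#' five classes (AuxRE 16, ABRE 12, TATA 16, Ypatch 11, DRE 9), with feature
#' values drawn per class so that, binned by the default fuzzy grids, each
#' confidence region reproduces its documented AuxRE proportion. Composition
#' features (x1, y1, z1, gc) are constructed by placing target (f1, f2)
#' scores in the designated discriminant-graph cells along the reference
#' axes, plus isotropic noise.
#'
#' @param seed integer seed; the fixture is fully determined by it.
#' @param noiseSd standard deviation of the composition noise.
#' @return data.frame with one row per motif: motif_id, seq, class,
#'   cell_g1/g2/g3 (designated grid cells), P, Sc, O, D, x1, y1, z1, gc,
#'   f1, f2 (projections of the constructed composition on the reference
#'   axes).
#' @export
makeTrainingFixture <- function(seed = 1L, noiseSd = 0.06) {
  set.seed(seed)
  classes <- rep(names(.CLASS_COUNTS), .CLASS_COUNTS)
  n <- length(classes)
  g1 <- .expandCells(.G1_CELLS)
  g2 <- .expandCells(.G2_CELLS)
  g3 <- .expandCells(.G3_CELLS)
  stopifnot(length(g1) == n, length(g2) == n, length(g3) == n)

  drawBox <- function(axis, k) {
    b <- .FIX_BOX[[axis]][[k]]
    runif(1L, b[1L], b[2L])
  }
  P <- Sc <- O <- D <- f1t <- f2t <- numeric(n)
  for (m in seq_len(n)) {
    i1 <- .cellIdx(g1[m]); i2 <- .cellIdx(g2[m]); i3 <- .cellIdx(g3[m])
    P[m] <- drawBox("position", i1["i"])
    ## R-cell labels enumerate score columns from the highest band down
    Sc[m] <- drawBox("score", 5L - i1[["j"]])
    O[m] <- round(drawBox("occurrence", i2["i"]))
    D[m] <- drawBox("density", i2["j"])
    f1t[m] <- drawBox("f1", i3["i"])
    f2t[m] <- drawBox("f2", i3["j"])
  }

  lda <- .referenceAxes()
  W <- lda@discriminants
  X <- matrix(rep(lda@center, each = n), n, 4L)
  X <- X + outer(f1t, W[, 1L]) + outer(f2t, W[, 2L]) +
    matrix(rnorm(4L * n, 0, noiseSd), n, 4L)
  X[, 1:3] <- pmin(pmax(X[, 1:3], -1), 1)
  X[, 4L] <- pmin(pmax(X[, 4L], 0.01), 0.99)
  colnames(X) <- c("x1", "y1", "z1", "gc")
  f <- ldaProject(lda, X[, 1L], X[, 2L], X[, 3L], X[, 4L])

  seqs <- vapply(seq_len(n), function(m) {
    cls <- classes[m]
    pool <- if (cls == "AuxRE") auxreVariants() else .CLASS_SEQS[[cls]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))

  data.frame(motif_id = sprintf("m%02d", seq_len(n)), seq = seqs,
             class = classes, cell_g1 = g1, cell_g2 = g2, cell_g3 = g3,
             P = P, Sc = Sc, O = O, D = D,
             x1 = X[, 1L], y1 = X[, 2L], z1 = X[, 3L], gc = X[, 4L],
             f1 = f[, 1L], f2 = f[, 2L])
}

## the reference discriminant axes used both by the fixture construction and
## the shipped default config
.referenceAxes <- function() {
  referenceLda(c(0.8, 0.6, 0, 0), c(0, 0, 0.9, -sqrt(1 - 0.81)),
               c(0, 0, 0, 0.5))
}

.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Build a promoter collection with planted motifs
#'
#' Uniform-ACGT promoters with the requested motifs overwritten at the
#' requested (non-overlapping) offsets. The plant list is returned so tests
#' can verify occurrences against it.
#'
#' @param nPromoters number of promoters.
#' @param lenBp length of each promoter.
#' @param planted data.frame with columns motif, promoter (1-based index),
#'   offset (0-based); may be empty.
#' @param responsive 1-based indices of auxin-responsive promoters.
#' @param seed integer seed.
#' @param prefix promoter id prefix.
#' @return list with elements `collection` (a [PromoterCollection-class]) and
#'   `plants` (the planted data.frame with promoter ids and end offsets).
#' @export
makeMiniCollection <- function(nPromoters, lenBp, planted = NULL,
                               responsive = integer(), seed = 1L,
                               prefix = "prom") {
  set.seed(seed)
  ids <- sprintf("%s%03d", prefix, seq_len(nPromoters))
  seqs <- vapply(seq_len(nPromoters), function(i) .randomSeq(lenBp), character(1))
  if (is.null(planted) || nrow(planted) == 0L) {
    planted <- data.frame(motif = character(), promoter = integer(),
                          offset = integer())
  }
  if (nrow(planted)) {
    planted$end <- planted$offset + nchar(planted$motif)
    if (any(planted$offset < 0) || any(planted$end > lenBp)) {
      stop("planted intervals must lie within promoter bounds")
    }
    for (p in unique(planted$promoter)) {
      pl <- planted[planted$promoter == p, , drop = FALSE]
      pl <- pl[order(pl$offset), , drop = FALSE]
      if (nrow(pl) > 1L && any(pl$offset[-1L] < pl$end[-nrow(pl)])) {
        stop("planted intervals overlap in promoter ", p)
      }
    }
    for (r in seq_len(nrow(planted))) {
      i <- planted$promoter[r]
      substr(seqs[i], planted$offset[r] + 1L, planted$end[r]) <- planted$motif[r]
    }
  }
  names(seqs) <- ids
  planted$promoter_id <- ids[planted$promoter]
  list(collection = promoterCollection(seqs, ids[responsive]),
       plants = planted)
}

#' The planted reference promoter collection
#'
#' The background collection that occurrence, density and significance score
#' are computed against when no genome-scale collection is supplied: random
#' promoters in which every AuxRE spike variant is planted a fixed number of
#' times, split between auxin-responsive and other promoters so that variant
#' densities sit in the mid band of the density partition.
#'
#' @param seed integer seed.
#' @param nPromoters,lenBp collection dimensions.
#' @param nResponsive number of auxin-responsive promoters (the first ids).
#' @param plantsPerVariant total plants of each of the 14 variants.
#' @param responsivePlants how many of those go into responsive promoters.
#' @return list with `collection` and `plants` as in [makeMiniCollection()].
#' @export
makeReferenceCollection <- function(seed = 1L, nPromoters = 120L, lenBp = 1000L,
                                    nResponsive = 30L, plantsPerVariant = 14L,
                                    responsivePlants = 7L) {
  set.seed(seed)
  variants <- auxreVariants()
  k <- nchar(variants[1L])
  ## lay plants on a per-promoter slot grid so they can never overlap
  slotW <- 2L * k
  nSlots <- lenBp %/% slotW
  free <- matrix(TRUE, nPromoters, nSlots)
  rows <- list()
  for (v in variants) {
    grp <- c(sample.int(nResponsive, responsivePlants),
             nResponsive + sample.int(nPromoters - nResponsive,
                                      plantsPerVariant - responsivePlants))
    for (p in grp) {
      open <- which(free[p, ])
      if (!length(open)) stop("no free slot left in promoter ", p)
      s <- open[sample.int(length(open), 1L)]
      free[p, s] <- FALSE
      offset <- (s - 1L) * slotW + sample.int(slotW - k + 1L, 1L) - 1L
      rows[[length(rows) + 1L]] <- data.frame(motif = v, promoter = p,
                                              offset = offset)
    }
  }
  planted <- do.call(rbind, rows)
  makeMiniCollection(nPromoters, lenBp, planted,
                     responsive = seq_len(nResponsive),
                     seed = seed + 1000L, prefix = "ref")
}

#' Write fixture files to a directory
#'
#' Writes training.tsv (the 64-motif table), promoters.fasta, responsive.txt
#' and plants.tsv for the reference collection.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  train <- makeTrainingFixture(seed)
  write.table(train, file.path(dir, "training.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ref <- makeReferenceCollection(seed)
  writeXStringSet(ref$collection@promoters, file.path(dir, "promoters.fasta"))
  writeLines(ref$collection@responsive, file.path(dir, "responsive.txt"))
  write.table(ref$plants, file.path(dir, "plants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
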