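## Candidate-motif features: position from the ATG, Z-curve composition, GC
## fraction, occurrence/density over a promoter collection, and an
## overrepresentation z-score standing in for the Weeder significance score.

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   vcountPattern reverseComplement oligonucleotideFrequency
#'   letterFrequency letterFrequencyInSlidingView width subseq DNAString
NULL

#' Create a promoter collection
#'
#' @param promoters named character vector or [Biostrings::DNAStringSet] of
#'   uppercase promoter sequences (A, C, G, T; N tolerated). Each sequence is
#'   the upstream region ending immediately 5' of the ATG.
#' @param responsive ids of promoters of 2-fold auxin-responsive genes.
#' @return a [PromoterCollection-class].
#' @export
promoterCollection <- function(promoters, responsive = character()) {
  if (!is(promoters, "DNAStringSet")) promoters <- DNAStringSet(promoters)
  new("PromoterCollection", promoters = promoters,
      responsive = as.character(responsive))
}

#' Read a promoter collection from FASTA plus a responsive-id sidecar
#'
#' @param fasta path to a FASTA file; record ids are promoter ids.
#' @param responsiveFile optional text file with one responsive promoter id
#'   per line.
#' @return a [PromoterCollection-class].
#' @export
readPromoterCollection <- function(fasta, responsiveFile = NULL) {
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  resp <- character()
  if (!is.null(responsiveFile)) {
    resp <- readLines(responsiveFile)
    resp <- resp[nzchar(resp)]
    missing <- setdiff(resp, names(seqs))
    if (length(missing)) {
      stop("responsive ids absent from FASTA: ", paste(missing, collapse = ", "))
    }
  }
  promoterCollection(seqs, resp)
}

#' @describeIn promoterCollection the promoter sequences.
#' @param x a [PromoterCollection-class].
#' @export
promoters <- function(x) {
  stopifnot(is(x, "PromoterCollection"))
  x@promoters
}

#' @describeIn promoterCollection ids flagged auxin-responsive.
#' @export
responsiveIds <- function(x) {
  stopifnot(is(x, "PromoterCollection"))
  x@responsive
}

setMethod("show", "PromoterCollection", function(object) {
  cat(sprintf("PromoterCollection: %d promoters (%d auxin-responsive), widths %d..%d\n",
              length(object@promoters), length(object@responsive),
              min(width(object@promoters)), max(width(object@promoters))))
})

## ---- single-candidate features -------------------------------------------

#' Position of a candidate window relative to the ATG
#'
#' Promoter sequences end immediately 5' of the translational start, so the
#' distance from a window's 5' end to the ATG is `promoterLen - start` with a
#' 0-based window start (1-based distance convention: the window abutting the
#' ATG at its 3' side has P equal to its own length).
#'
#' @param start 0-based offset of the window within the promoter.
#' @param promoterLen promoter length in bp.
#' @return distance in bp (positive integer).
#' @export
positionFromATG <- function(start, promoterLen) {
  if (any(start < 0) || any(start >= promoterLen)) {
    stop("start must satisfy 0 <= start < promoterLen")
  }
  promoterLen - start
}

.baseCounts <- function(seq) {
  if (!nzchar(seq)) stop("sequence must be nonempty")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be uppercase over A, C, G, T (N tolerated)")
  s <- strsplit(seq, "")[[1L]]
  cnt <- c(A = sum(s == "A"), C = sum(s == "C"), G = sum(s == "G"), T = sum(s == "T"))
  if (sum(cnt) == 0L) stop("sequence contains no A/C/G/T bases")
  cnt
}

#' Z-curve composition parameters of a DNA sequence
#'
#' With a1, c1, g1, t1 the base frequencies: x1 = (a1+g1) - (c1+t1) separates
#' purines from pyrimidines, y1 = (a1+c1) - (g1+t1) amino from keto bases and
#' z1 = (a1+t1) - (g1+c1) weak from strong pairings. N bases are excluded
#' from the frequencies (renormalized over A/C/G/T counts).
#'
#' @param seq uppercase DNA string.
#' @return named numeric vector (x1, y1, z1), each in [-1, 1].
#' @examples
#' zcurveParams("TGTCTC")  # c(-2/3, -1/3, 0)
#' @export
zcurveParams <- function(seq) {
  f <- .baseCounts(seq)
  f <- f / sum(f)
  c(x1 = unname((f["A"] + f["G"]) - (f["C"] + f["T"])),
    y1 = unname((f["A"] + f["C"]) - (f["G"] + f["T"])),
    z1 = unname((f["A"] + f["T"]) - (f["G"] + f["C"])))
}

#' GC fraction of a DNA sequence
#'
#' @param seq uppercase DNA string; N bases are excluded from the denominator.
#' @return fraction in [0, 1].
#' @export
gcContent <- function(seq) {
  f <- .baseCounts(seq)
  unname((f["G"] + f["C"]) / sum(f))
}

#' Occurrence of a motif in a promoter collection
#'
#' Total number of exact matches of `motif` across all promoters; overlapping
#' matches are counted and N in a promoter never matches. Forward strand by
#' default; `bothStrands = TRUE` adds reverse-complement matches.
#'
#' @param motif uppercase DNA string (length >= 4).
#' @param coll a [PromoterCollection-class].
#' @param bothStrands also count matches of the reverse complement.
#' @param ids restrict counting to these promoter ids (default: all).
#' @return non-negative integer count.
#' @export
motifOccurrence <- function(motif, coll, bothStrands = FALSE, ids = NULL) {
  stopifnot(is(coll, "PromoterCollection"), nchar(motif) >= 4L)
  seqs <- coll@promoters
  if (!is.null(ids)) seqs <- seqs[ids]
  n <- sum(vcountPattern(motif, seqs))
  if (bothStrands) {
    rc <- as.character(reverseComplement(DNAString(motif)))
    if (rc != motif) n <- n + sum(vcountPattern(rc, seqs))
  }
  n
}

#' Density of a motif over auxin-responsive promoters
#'
#' The fraction of the motif's promoter matches that fall in promoters
#' flagged 2-fold auxin-responsive. A motif absent from the whole collection
#' has an undefined density (0/0); `NA` is returned as the ignorance sentinel
#' which the fusion model maps to a vacuous mass.
#'
#' @inheritParams motifOccurrence
#' @return fraction in [0, 1], or `NA` when the motif never occurs.
#' @export
motifDensity <- function(motif, coll, bothStrands = FALSE) {
  total <- motifOccurrence(motif, coll, bothStrands)
  if (total == 0L) return(NA_real_)
  inResp <- motifOccurrence(motif, coll, bothStrands, ids = coll@responsive)
  inResp / total
}

#' Overrepresentation z-score of a motif
#'
#' Stand-in significance score: compares the observed occurrence with its
#' expectation under an i.i.d. base background,
#' `z = (observed - expected) / sqrt(expected)` with
#' `expected = sum_promoters (len - |motif| + 1) * prod_b bg(b)`.
#' Monotone increasing in the observed count.
#'
#' @inheritParams motifOccurrence
#' @param bg named base frequencies (A, C, G, T); defaults to the empirical
#'   base composition of the collection.
#' @param observed optional precomputed occurrence (skips recounting).
#' @return the z-score (unitless).
#' @export
significanceScore <- function(motif, coll, bg = NULL, observed = NULL) {
  stopifnot(is(coll, "PromoterCollection"), nchar(motif) >= 4L)
  if (is.null(bg)) bg <- backgroundFrequencies(coll)
  bg <- bg[c("A", "C", "G", "T")]
  if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-6) {
    stop("bg must be named frequencies for A, C, G, T summing to 1")
  }
  k <- nchar(motif)
  nwin <- sum(pmax(width(coll@promoters) - k + 1L, 0L))
  pmotif <- prod(bg[strsplit(motif, "")[[1L]]])
  expected <- nwin * pmotif
  if (expected <= 0) stop("expected count is zero under this background")
  if (is.null(observed)) observed <- motifOccurrence(motif, coll)
  (observed - expected) / sqrt(expected)
}

#' @describeIn significanceScore empirical A/C/G/T frequencies of a collection.
#' @export
backgroundFrequencies <- function(coll) {
  stopifnot(is(coll, "PromoterCollection"))
  cnt <- colSums(letterFrequency(coll@promoters, c("A", "C", "G", "T")))
  cnt / sum(cnt)
}

## ---- bulk k-mer statistics for the scanner --------------------------------

## Counts every k-mer of the collection once so a scan can look features up
## by word instead of re-matching per candidate. Words containing N are not
## counted (consistent with N never matching a motif).
.kmerStats <- function(coll, k, bg = NULL) {
  if (is.null(bg)) bg <- backgroundFrequencies(coll)
  counts <- colSums(oligonucleotideFrequency(coll@promoters, width = k))
  respSet <- coll@promoters[names(coll@promoters) %in% coll@responsive]
  respCounts <- if (length(respSet)) {
    colSums(oligonucleotideFrequency(respSet, width = k))
  } else {
    setNames(numeric(length(counts)), names(counts))
  }
  nwin <- sum(pmax(width(coll@promoters) - k + 1L, 0L))
  logp <- log(bg[c("A", "C", "G", "T")])
  ## expected count of each word under the iid background
  lettersOf <- strsplit(names(counts), "")
  lp <- vapply(lettersOf, function(b) sum(logp[b]), numeric(1))
  expected <- nwin * exp(lp)
  z <- (counts - expected) / sqrt(expected)
  density <- ifelse(counts > 0, respCounts / counts, NA_real_)
  data.frame(word = names(counts), count = as.numeric(counts),
             respCount = as.numeric(respCounts), expected = expected,
             z = z, density = density, row.names = names(counts))
}
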