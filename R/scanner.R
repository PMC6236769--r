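## Promoter scanning: enumerate candidate windows, batch-compute features
## against a reference promoter collection, fuse the three evidence sources
## and emit ranked AuxRE calls.

#' Scan configuration
#'
#' @param windowLengths candidate window lengths in bp (each >= 4).
#' @param threshold credibility threshold; `NULL` uses the model's.
#' @param strands "forward" or "both" (adds reverse-complement windows).
#' @param promoterWindow only windows whose distance from the ATG is at most
#'   this many bp are scanned (the features are calibrated on -1000 bp
#'   upstream regions).
#' @return a list with class "ScanConfig".
#' @export
scanConfig <- function(windowLengths = c(6L, 8L), threshold = NULL,
                       strands = c("forward", "both"), promoterWindow = 1000L) {
  if (length(windowLengths) && any(windowLengths < 4L)) {
    stop("window lengths must be >= 4")
  }
  if (!is.null(threshold) && (threshold < 0 || threshold > 1)) {
    stop("threshold must be in [0, 1]")
  }
  structure(list(windowLengths = as.integer(windowLengths),
                 threshold = threshold,
                 strands = match.arg(strands),
                 promoterWindow = as.integer(promoterWindow)),
            class = "ScanConfig")
}

#' Enumerate candidate windows of a promoter
#'
#' All windows of each configured length at every offset, in deterministic
#' order (position, then length, then strand). Windows containing N are
#' dropped (an ambiguous base is not a motif candidate); windows farther
#' from the ATG than `promoterWindow` are not enumerated.
#'
#' @param promoter promoter sequence (character scalar or DNAString).
#' @param cfg a [scanConfig()] list.
#' @return data.frame with columns start (0-based), end (half-open), strand,
#'   seq.
#' @export
enumerateCandidates <- function(promoter, cfg = scanConfig()) {
  promoter <- as.character(promoter)
  L <- nchar(promoter)
  if (length(cfg$windowLengths) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), seq = character()))
  }
  if (L < max(cfg$windowLengths)) stop("promoter shorter than the largest window")
  rows <- list()
  minStart <- max(0L, L - cfg$promoterWindow)
  for (k in sort(cfg$windowLengths)) {
    starts <- minStart:(L - k)
    seqs <- substring(promoter, starts + 1L, starts + k)
    keep <- !grepl("N", seqs, fixed = TRUE)
    df <- data.frame(start = starts[keep], end = starts[keep] + k,
                     strand = "+", seq = seqs[keep])
    rows[[length(rows) + 1L]] <- df
    if (cfg$strands == "both") {
      rc <- as.character(reverseComplement(DNAStringSet(seqs[keep])))
      rows[[length(rows) + 1L]] <- data.frame(start = starts[keep],
                                              end = starts[keep] + k,
                                              strand = "-", seq = rc)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end - out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Batch feature computation for all candidates of a set of scanned
## sequences. kstats is a list of .kmerStats() tables keyed by window length.
.candidateFeatures <- function(cands, promoterLen, model, kstats) {
  k <- cands$end - cands$start
  P <- promoterLen - cands$start
  ## window lengths may be mixed: resolve lookups per length
  O <- Sc <- D <- rep(NA_real_, nrow(cands))
  for (kk in unique(k)) {
    sel <- k == kk
    st <- kstats[[as.character(kk)]]
    i <- match(cands$seq[sel], st$word)
    O[sel] <- st$count[i]
    Sc[sel] <- st$z[i]
    D[sel] <- st$density[i]
  }
  cnt <- letterFrequency(DNAStringSet(cands$seq), c("A", "C", "G", "T"))
  comp <- cnt / rowSums(cnt)
  x1 <- (comp[, 1L] + comp[, 3L]) - (comp[, 2L] + comp[, 4L])
  y1 <- (comp[, 1L] + comp[, 2L]) - (comp[, 3L] + comp[, 4L])
  z1 <- (comp[, 1L] + comp[, 4L]) - (comp[, 3L] + comp[, 2L])
  gc <- comp[, 2L] + comp[, 3L]
  f <- ldaProject(model@lda, x1, y1, z1, gc)
  data.frame(P = P, Sc = Sc, O = O, D = D, gc = gc,
             x1 = x1, y1 = y1, z1 = z1, f1 = f[, 1L], f2 = f[, 2L])
}

#' Scan promoters for AuxREs with a fusion model
#'
#' Enumerates candidate windows of every scanned sequence, computes the
#' seven-feature description of each window against the reference promoter
#' collection, fuses the three learning-graph masses and calls windows whose
#' credibility (fused belief in the AuxRE hypothesis) reaches the threshold.
#' Candidates whose evidence is totally conflicting (K = 1) are returned in
#' the rejects slot, not silently dropped.
#'
#' @param x sequences to scan: FASTA path, named character vector,
#'   [Biostrings::DNAStringSet] or [PromoterCollection-class].
#' @param model a [FusionModel-class].
#' @param coll reference [PromoterCollection-class] for occurrence, density
#'   and significance score (the scanned sequences themselves are not added
#'   to it).
#' @param cfg a [scanConfig()].
#' @return a [ScanResult-class]; candidates are sorted by credibility,
#'   descending.
#' @export
scanPromoters <- function(x, model, coll, cfg = scanConfig()) {
  stopifnot(is(model, "FusionModel"), is(coll, "PromoterCollection"))
  seqs <- if (is(x, "PromoterCollection")) {
    x@promoters
  } else if (is(x, "DNAStringSet")) {
    x
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !grepl("^[ACGTN]+$", x)) {
    readDNAStringSet(x)
  } else {
    DNAStringSet(x)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  thr <- if (is.null(cfg$threshold)) model@threshold else cfg$threshold

  bg <- backgroundFrequencies(coll)
  kstats <- list()
  for (k in unique(cfg$windowLengths)) {
    kstats[[as.character(k)]] <- .kmerStats(coll, k, bg)
  }

  allCands <- list()
  for (id in names(seqs)) {
    s <- as.character(seqs[[id]])
    cands <- enumerateCandidates(s, cfg)
    if (nrow(cands) == 0L) next
    feats <- .candidateFeatures(cands, nchar(s), model, kstats)
    allCands[[id]] <- cbind(promoter_id = id, cands, feats)
  }
  if (length(allCands) == 0L) {
    empty <- data.frame()
    return(new("ScanResult", candidates = empty, rejects = empty, threshold = thr))
  }
  df <- do.call(rbind, allCands)
  rownames(df) <- NULL

  fz <- .fuseVec(model, df$P, df$Sc, df$O, df$D, df$f1, df$f2)
  df$m_h1 <- fz$fused$h1
  df$m_h2 <- fz$fused$h2
  df$m_theta <- fz$fused$theta
  df$credibility <- fz$fused$h1
  ## per-method credibilities kept for before/after-fusion comparisons
  df$cred_m1 <- fz$m1$h1
  df$cred_m2 <- fz$g3$h1
  conflicted <- fz$conflict
  rejects <- df[conflicted, setdiff(names(df), c("m_h1", "m_h2", "m_theta",
                                                 "credibility")), drop = FALSE]
  out <- df[!conflicted, , drop = FALSE]
  out$is_hit <- out$credibility >= thr
  ord <- order(-out$credibility, out$promoter_id, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- rownames(rejects) <- NULL
  new("ScanResult", candidates = out, rejects = rejects, threshold = thr)
}

#' @describeIn scanPromoters all scored candidates of a scan (sorted by
#'   credibility).
#' @param result a [ScanResult-class].
#' @export
scanCandidates <- function(result) {
  stopifnot(is(result, "ScanResult"))
  result@candidates
}

#' @describeIn scanPromoters only the candidates called as AuxREs.
#' @export
scanHits <- function(result) {
  stopifnot(is(result, "ScanResult"))
  result@candidates[result@candidates$is_hit, , drop = FALSE]
}

#' @describeIn scanPromoters candidates rejected for total evidence conflict.
#' @export
scanRejects <- function(result) {
  stopifnot(is(result, "ScanResult"))
  result@rejects
}

setMethod("show", "ScanResult", function(object) {
  n <- nrow(object@candidates)
  cat(sprintf("ScanResult: %d candidates, %d hits at threshold %.2f, %d conflict rejects\n",
              n, sum(object@candidates$is_hit), object@threshold,
              nrow(object@rejects)))
})

#' Write scan output as TSV / BED
#'
#' The TSV carries the full per-candidate record (coordinates, features,
#' masses, credibility, hit flag); P is the 1-based distance from the ATG.
#' The BED6 file is 0-based half-open on the promoter with the credibility
#' scaled to 0-1000 in the score column.
#'
#' @param result a [ScanResult-class].
#' @param path output file path.
#' @param hitsOnly write only called hits (default) or all candidates.
#' @return `path`, invisibly.
#' @export
writeScanTSV <- function(result, path, hitsOnly = FALSE) {
  df <- if (hitsOnly) scanHits(result) else scanCandidates(result)
  cols <- c("promoter_id", "start", "end", "strand", "seq", "P", "Sc", "O",
            "D", "gc", "x1", "y1", "z1", "f1", "f2", "m_h1", "m_h2",
            "m_theta", "credibility", "is_hit")
  write.table(df[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScanTSV
#' @export
writeScanBED <- function(result, path, hitsOnly = TRUE) {
  df <- if (hitsOnly) scanHits(result) else scanCandidates(result)
  bed <- data.frame(chrom = df$promoter_id, start = df$start, end = df$end,
                    name = df$seq, score = round(1000 * df$credibility),
                    strand = df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Greedy non-overlap filter on scan hits
#'
#' Optionally thin overlapping hits: keep the highest-credibility hit, drop
#' hits overlapping it, repeat. Off by default in all pipelines.
#'
#' @param hits data.frame of hits (as from [scanHits()]).
#' @return filtered data.frame.
#' @export
nonOverlappingHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(-hits$credibility), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- keep & hits$promoter_id == hits$promoter_id[i]
    keep[i] <- !any(hits$start[sel] < hits$end[i] & hits$end[sel] > hits$start[i])
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
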