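## Gold-standard evaluation: spiked random sequences with exact truth
## labels, a confusion-table metric panel, threshold sweeps and the
## before/after-fusion comparison.

#' Generate the spike-in gold standard
#'
#' A library of random uniform-ACGT sequences; each receives exactly one
#' AuxRE variant, drawn uniformly from the spike set and overwritten at a
#' uniform random valid offset. Fully determined by the seed.
#'
#' @param nSeqs number of sequences (default 100).
#' @param seqLen sequence length in bp (default 1000).
#' @param auxreSet spike motifs (default the 14 packaged variants).
#' @param seed integer seed.
#' @return list with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame seq_id, motif, start, end; 0-based half-open).
#' @export
generateGoldStandard <- function(nSeqs = 100L, seqLen = 1000L,
                                 auxreSet = auxreVariants(), seed = 1L) {
  if (!length(auxreSet)) stop("auxreSet must be nonempty")
  if (seqLen <= max(nchar(auxreSet))) stop("seqLen too short for the spike set")
  set.seed(seed)
  ids <- sprintf("gold%03d", seq_len(nSeqs))
  seqs <- character(nSeqs)
  motif <- character(nSeqs)
  start <- integer(nSeqs)
  for (i in seq_len(nSeqs)) {
    s <- .randomSeq(seqLen)
    m <- auxreSet[sample.int(length(auxreSet), 1L)]
    at <- sample.int(seqLen - nchar(m) + 1L, 1L) - 1L
    substr(s, at + 1L, at + nchar(m)) <- m
    seqs[i] <- s; motif[i] <- m; start[i] <- at
  }
  names(seqs) <- ids
  list(sequences = DNAStringSet(seqs),
       truth = data.frame(seq_id = ids, motif = motif, start = start,
                          end = start + nchar(motif)))
}

#' Write a gold standard to disk
#'
#' @param gold a list from [generateGoldStandard()].
#' @param dir output directory; writes gold.fasta and truth.tsv.
#' @return `dir`, invisibly.
#' @export
writeGoldStandard <- function(gold, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(gold$sequences, file.path(dir, "gold.fasta"))
  write.table(gold$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Metric panel of a 2x2 confusion table
#'
#' Percent-scale sensitivity, specificity, predictive values, the Youden
#' index, Yule's Q and the Pearson chi-square statistic. Following the
#' evaluation convention of the source tables, FPR and FNR are the
#' complements of PPV and NPV (100 - PPV and 100 - NPV), not the textbook
#' fall-out and miss rates. Metrics with an empty denominator are `NA`
#' (undefined, not 0).
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return named list: tp, fp, fn, tn, sn, sp, ppv, npv, fpr, fnr, yi, qcy,
#'   chi2.
#' @export
metricsPanel <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sn <- frac(tp, tp + fn)
  sp <- frac(tn, tn + fp)
  ppv <- frac(tp, tp + fp)
  npv <- frac(tn, tn + fn)
  yi <- if (!is.na(sn) && !is.na(sp)) sn / 100 + sp / 100 - 1 else NA_real_
  qden <- tp * tn + fp * fn
  qcy <- if (qden > 0) (tp * tn - fp * fn) / qden else NA_real_
  n <- tp + fp + fn + tn
  m <- (tp + fp) * (fn + tn) * (tp + fn) * (fp + tn)
  chi2 <- if (m > 0) n * (tp * tn - fp * fn)^2 / m else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn, sn = sn, sp = sp, ppv = ppv,
       npv = npv, fpr = if (is.na(ppv)) NA_real_ else 100 - ppv,
       fnr = if (is.na(npv)) NA_real_ else 100 - npv,
       yi = yi, qcy = qcy, chi2 = chi2)
}

## which predicted intervals qualify against the truth intervals
.qualifies <- function(hits, truth, rule, frac) {
  if (nrow(hits) == 0L) return(list(q = logical(0), tIdx = integer(0)))
  needFor <- function(w) switch(rule, exact = w, any = pmin(1, w), fraction = frac * w)
  if (!anyDuplicated(truth$seq_id)) {
    ## gold standards carry exactly one element per sequence: vectorized path
    m <- match(hits$promoter_id, truth$seq_id)
    ts <- truth$start[m]; te <- truth$end[m]
    ov <- pmin(hits$end, te) - pmax(hits$start, ts)
    q <- !is.na(ov) & ov > 0 & ov >= needFor(te - ts)
    return(list(q = q, tIdx = ifelse(q, truth$row[m], 0L)))
  }
  q <- logical(nrow(hits))
  tIdx <- integer(nrow(hits))
  tr <- split(truth, truth$seq_id)
  for (i in seq_len(nrow(hits))) {
    tt <- tr[[hits$promoter_id[i]]]
    if (is.null(tt)) next
    ov <- pmin(hits$end[i], tt$end) - pmax(hits$start[i], tt$start)
    j <- which(ov > 0 & ov >= needFor(tt$end - tt$start))
    if (length(j)) { q[i] <- TRUE; tIdx[i] <- tt$row[j[1L]] }
  }
  list(q = q, tIdx = tIdx)
}

#' Score predictions against the gold-standard truth
#'
#' A predicted hit is a true positive when its interval overlaps a truth
#' interval on the same sequence by at least `overlapFrac` of the truth
#' length (configurable to exact or any-overlap matching). True positives
#' are counted at the element level: each truth element counts once however
#' many windows detect it, and surplus detections of an already-detected
#' element are excluded from the evaluated candidate universe (they are
#' correct calls, not errors). A truth element with no qualifying hit is a
#' false negative; remaining candidates are true negatives.
#'
#' @param hits data.frame of predicted hits (needs promoter_id, start, end).
#' @param truth truth data.frame (seq_id, start, end).
#' @param allCandidates total number of evaluated candidate windows.
#' @param overlapRule "fraction" (default), "exact" or "any".
#' @param overlapFrac minimum overlap as a fraction of the truth length.
#' @return list: counts (tp, fp, fn, tn), metrics ([metricsPanel()] list) and
#'   allCandidates (the evaluated universe after removing surplus
#'   detections).
#' @export
evaluatePredictions <- function(hits, truth, allCandidates,
                                overlapRule = c("fraction", "exact", "any"),
                                overlapFrac = 0.5) {
  overlapRule <- match.arg(overlapRule)
  truth$row <- seq_len(nrow(truth))
  qq <- .qualifies(hits, truth, overlapRule, overlapFrac)
  detected <- unique(qq$tIdx[qq$tIdx > 0L])
  tp <- length(detected)
  fn <- nrow(truth) - tp
  fp <- sum(!qq$q)
  dup <- sum(qq$q) - tp
  universe <- allCandidates - dup
  tn <- universe - tp - fp - fn
  if (tn < 0) stop("allCandidates too small for the supplied hits/truth")
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  list(counts = counts, metrics = metricsPanel(tp, fp, fn, tn),
       allCandidates = universe)
}

.credMatrix <- function(result) {
  take <- function(df) {
    data.frame(promoter_id = df$promoter_id, start = df$start, end = df$end,
               fusion = if (is.null(df$credibility)) NA_real_ else df$credibility,
               method1 = df$cred_m1, method2 = df$cred_m2)
  }
  rbind(take(result@candidates),
        if (nrow(result@rejects)) take(result@rejects))
}

#' Threshold sweep of the metric panel
#'
#' Re-thresholds a single scan at each credibility cutoff (scan once, decide
#' many) and computes the metric panel per cutoff. Conflict-rejected
#' candidates count as non-hits at every cutoff.
#'
#' @param result a [ScanResult-class] over the gold sequences.
#' @param truth gold-standard truth data.frame.
#' @param thresholds ascending credibility cutoffs.
#' @param ... passed to [evaluatePredictions()].
#' @return data.frame: one row per threshold with the confusion counts and
#'   metric panel.
#' @export
thresholdSweep <- function(result, truth, thresholds = seq(0.1, 0.9, by = 0.1),
                           ...) {
  cred <- .credMatrix(result)
  universe <- nrow(cred)
  rows <- lapply(thresholds, function(t) {
    hits <- cred[!is.na(cred$fusion) & cred$fusion >= t, , drop = FALSE]
    ev <- evaluatePredictions(hits, truth, universe, ...)
    cbind(data.frame(threshold = t), as.data.frame(ev$metrics))
  })
  do.call(rbind, rows)
}

#' @describeIn thresholdSweep the cutoff with the best positive predictive
#'   value (ties resolved to the lowest cutoff; `NA` PPVs skipped).
#' @param sweep a data.frame from `thresholdSweep`.
#' @export
argmaxPPV <- function(sweep) {
  ok <- !is.na(sweep$ppv)
  if (!any(ok)) return(NA_real_)
  sweep$threshold[ok][which.max(sweep$ppv[ok])]
}

#' Compare method 1, method 2 and the fusion on a gold standard
#'
#' Scores every candidate three ways: the combined overrepresentation mass
#' (method 1), the discriminant-graph mass alone (method 2) and the full
#' fusion, then tabulates TP/FP and TPR/FPR across cutoffs and summarizes
#' each ROC by its trapezoidal AUC.
#'
#' @param result a [ScanResult-class] over the gold sequences.
#' @param truth gold-standard truth data.frame.
#' @param thresholds cutoffs for the count table.
#' @param rocThresholds denser grid for the ROC/AUC summary.
#' @param ... passed to [evaluatePredictions()].
#' @return list: `table` (method, threshold, tp, fp, tpr, fpr, ppv) and
#'   `auc` (named numeric).
#' @export
compareMethods <- function(result, truth, thresholds = seq(0.1, 0.9, by = 0.1),
                           rocThresholds = seq(0, 1, by = 0.05), ...) {
  cred <- .credMatrix(result)
  universe <- nrow(cred)
  methods <- c("method1", "method2", "fusion")
  evalAt <- function(m, t) {
    v <- cred[[m]]
    hits <- cred[!is.na(v) & v >= t, , drop = FALSE]
    evaluatePredictions(hits, truth, universe, ...)
  }
  tab <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(thresholds, function(t) {
      ev <- evalAt(m, t)
      with(as.list(ev$counts), data.frame(
        method = m, threshold = t, tp = tp, fp = fp,
        tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
        ppv = ev$metrics$ppv))
    }))
  }))
  auc <- vapply(methods, function(m) {
    pts <- do.call(rbind, lapply(rocThresholds, function(t) {
      ev <- evalAt(m, t)
      with(as.list(ev$counts),
           c(fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
             tpr = if (tp + fn > 0) tp / (tp + fn) else 0))
    }))
    pts <- rbind(c(0, 0), pts[order(pts[, "fpr"], pts[, "tpr"]), ], c(1, 1))
    sum(diff(pts[, 1L]) * (pts[-1L, 2L] + pts[-nrow(pts), 2L]) / 2)
  }, numeric(1))
  list(table = tab, auc = auc)
}

#' Run the full gold-standard benchmark
#'
#' Generates a spiked library, scans it with the model against the planted
#' reference collection, sweeps the credibility cutoffs and compares the
#' single methods with the fusion.
#'
#' @param model a [FusionModel-class] (default the packaged model).
#' @param seed seed for the gold-standard library.
#' @param nSeqs,seqLen library dimensions.
#' @param thresholds sweep cutoffs.
#' @param reference optional reference collection list (as returned by
#'   [makeReferenceCollection()]); by default the packaged reference
#'   collection (its own fixed seed) is used, playing the role of the
#'   genome-scale background.
#' @param cfg a [scanConfig()].
#' @return list: gold, result ([ScanResult-class]), sweep, bestThreshold,
#'   comparison.
#' @export
runBenchmark <- function(model = defaultFusionModel(), seed = 1L,
                         nSeqs = 100L, seqLen = 1000L,
                         thresholds = seq(0.1, 0.9, by = 0.1),
                         reference = NULL, cfg = scanConfig()) {
  gold <- generateGoldStandard(nSeqs, seqLen, seed = seed)
  if (is.null(reference)) reference <- makeReferenceCollection()
  res <- scanPromoters(gold$sequences, model, reference$collection, cfg)
  sweep <- thresholdSweep(res, gold$truth, thresholds)
  cmp <- compareMethods(res, gold$truth, thresholds)
  list(gold = gold, result = res, sweep = sweep,
       bestThreshold = argmaxPPV(sweep), comparison = cmp)
}
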