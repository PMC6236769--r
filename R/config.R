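## Model configuration: YAML in, FusionModel out, and back again. The shipped
## default transcribes the three region tables, the proposition-mass mapping
## and the graded-doubt propositions into one file so every breakpoint and
## cell assignment is overridable without touching code.

.parsePartition <- function(axisName, entries) {
  sets <- lapply(entries, function(e) {
    fuzzySet(e$name, e$a, e$b, e$c, e$d)
  })
  fuzzyPartition(axisName, sets)
}

.parseTable <- function(tableName, spec, partitions) {
  ax1 <- partitions[[spec$axis1]]
  ax2 <- partitions[[spec$axis2]]
  if (is.null(ax1) || is.null(ax2)) {
    stop("table '", tableName, "' references an undeclared partition")
  }
  n1 <- length(ax1@sets); n2 <- length(ax2@sets)
  props <- labels <- matrix(NA_character_, n1, n2)
  prefix <- substr(names(spec$cells)[1L], 1L, 1L)
  ## label digit j may enumerate axis-2 columns in descending axis order when
  ## the source table was drawn with its second axis reversed
  descend <- identical(spec$axis2_label_order, "descending")
  for (cell in names(spec$cells)) {
    m <- regmatches(cell, regexec("^[A-Za-z]([0-9])([0-9])$", cell))[[1L]]
    if (length(m) == 0L) stop("bad cell label '", cell, "' in table '", tableName, "'")
    i <- as.integer(m[2L]); j <- as.integer(m[3L])
    if (i > n1 || j > n2) {
      stop(sprintf("cell %s out of range for a %d x %d grid (table '%s')",
                   cell, n1, n2, tableName))
    }
    gj <- if (descend) n2 + 1L - j else j
    props[i, gj] <- spec$cells[[cell]]
    labels[i, gj] <- cell
  }
  if (any(is.na(labels))) {
    miss <- which(is.na(labels), arr.ind = TRUE)
    labels[miss] <- sprintf("%s%d%d", prefix, miss[, 1L],
                            if (descend) n2 + 1L - miss[, 2L] else miss[, 2L])
  }
  regionMassTable(tableName, ax1, ax2, props, labels = labels,
                  labelPrefix = prefix)
}

#' Read a fusion-model configuration file
#'
#' Parses a YAML model file (fuzzy partitions, per-cell region propositions,
#' reference discriminant axes, decision threshold) into a
#' [FusionModel-class]. Unknown proposition labels are rejected; cells left
#' unassigned fall back to total ignorance with a warning.
#'
#' @param path YAML file path.
#' @return a [FusionModel-class].
#' @seealso [defaultFusionModel()], [writeModelConfig()]
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  parts <- lapply(names(cfg$partitions), function(nm) {
    .parsePartition(nm, cfg$partitions[[nm]])
  })
  names(parts) <- names(cfg$partitions)
  tabs <- lapply(names(cfg$tables), function(nm) {
    .parseTable(nm, cfg$tables[[nm]], parts)
  })
  names(tabs) <- names(cfg$tables)
  need <- c("score_position", "occurrence_density", "f1_f2")
  if (!all(need %in% names(tabs))) {
    stop("config must define tables: ", paste(need, collapse = ", "))
  }
  lda <- referenceLda(unlist(cfg$lda$discriminant1),
                      unlist(cfg$lda$discriminant2),
                      unlist(cfg$lda$center),
                      unlist(cfg$lda$explained_variance))
  thr <- if (is.null(cfg$threshold)) 0.9 else as.numeric(cfg$threshold)
  new("FusionModel",
      tablePosSc = tabs[["score_position"]],
      tableOD = tabs[["occurrence_density"]],
      tableF1F2 = tabs[["f1_f2"]],
      lda = lda, threshold = thr)
}

#' The packaged default fusion model
#'
#' Loads the configuration shipped with the package: region propositions for
#' the three learning graphs, trapezoidal partitions for every feature axis,
#' the reference discriminant axes and the 0.9 credibility threshold.
#'
#' @return a [FusionModel-class].
#' @export
defaultFusionModel <- function() {
  readModelConfig(system.file("extdata", "default_model.yaml",
                              package = "AuxREfusion", mustWork = TRUE))
}

.partitionToList <- function(p) {
  lapply(p@sets, function(s) list(name = s@name, a = s@a, b = s@b, c = s@c, d = s@d))
}

.tableToList <- function(tab, prefix) {
  n2 <- ncol(tab@props)
  descend <- identical(unname(tab@labels[1L, 1L]),
                       sprintf("%s1%d", prefix, n2)) && n2 > 1L
  cells <- list()
  for (i in seq_len(nrow(tab@props))) {
    for (j in seq_len(n2)) {
      cells[[unname(tab@labels[i, j])]] <- unname(tab@props[i, j])
    }
  }
  out <- list(axis1 = tab@axis1@axisName, axis2 = tab@axis2@axisName,
              cells = cells[order(names(cells))])
  if (descend) out$axis2_label_order <- "descending"
  out
}

#' Write a fusion model back to a configuration file
#'
#' Serializes a model so that `readModelConfig()` reproduces it exactly
#' (same partitions, cell propositions, discriminant axes and threshold).
#'
#' @param model a [FusionModel-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeModelConfig <- function(model, path) {
  stopifnot(is(model, "FusionModel"))
  parts <- list()
  for (tab in list(model@tablePosSc, model@tableOD, model@tableF1F2)) {
    parts[[tab@axis1@axisName]] <- .partitionToList(tab@axis1)
    parts[[tab@axis2@axisName]] <- .partitionToList(tab@axis2)
  }
  cfg <- list(
    threshold = model@threshold,
    partitions = parts,
    tables = list(
      score_position = .tableToList(model@tablePosSc, "R"),
      occurrence_density = .tableToList(model@tableOD, "D"),
      f1_f2 = .tableToList(model@tableF1F2, "Q")
    ),
    lda = list(
      discriminant1 = unname(model@lda@discriminants[, 1L]),
      discriminant2 = unname(model@lda@discriminants[, 2L]),
      center = unname(model@lda@center),
      explained_variance = unname(model@lda@explainedVariance)
    )
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Dump the resolved per-cell masses of a model
#'
#' One row per grid cell of each learning graph: the cell label, its
#' proposition and the resolved basic probability assignment. Intended for
#' inspection and for verifying that a config round-trips unchanged.
#'
#' @param model a [FusionModel-class].
#' @param path optional TSV output path.
#' @return data.frame with columns table, cell, axis1_set, axis2_set,
#'   proposition, m_h1, m_h2, m_theta.
#' @export
dumpModelMasses <- function(model, path = NULL) {
  stopifnot(is(model, "FusionModel"))
  tabs <- list(score_position = list(model@tablePosSc, "R"),
               occurrence_density = list(model@tableOD, "D"),
               f1_f2 = list(model@tableF1F2, "Q"))
  rows <- list()
  for (nm in names(tabs)) {
    tab <- tabs[[nm]][[1L]]; prefix <- tabs[[nm]][[2L]]
    l1 <- setLabels(tab@axis1); l2 <- setLabels(tab@axis2)
    for (i in seq_along(l1)) {
      for (j in seq_along(l2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          table = nm, cell = unname(tab@labels[i, j]),
          axis1_set = l1[i], axis2_set = l2[j],
          proposition = unname(tab@props[i, j]),
          m_h1 = tab@h1[i, j], m_h2 = tab@h2[i, j], m_theta = tab@theta[i, j])
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

setMethod("show", "FusionModel", function(object) {
  cat("FusionModel\n")
  cat(sprintf("  threshold: %.2f\n", object@threshold))
  for (tab in list(object@tablePosSc, object@tableOD, object@tableF1F2)) {
    cat(sprintf("  table %-18s %s(%d) x %s(%d)\n", tab@tableName,
                tab@axis1@axisName, length(tab@axis1@sets),
                tab@axis2@axisName, length(tab@axis2@sets)))
  }
})
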