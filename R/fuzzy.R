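## Fuzzy partitions over feature axes and the fuzzified region-mass lookup.
## Region grids replace the hard confidence-region boundaries of the learning
## graphs with overlapping trapezoids, so the evidence attached to a point
## transitions smoothly between regions instead of jumping at a boundary.

#' Create a trapezoidal fuzzy set
#'
#' @param name set label.
#' @param a,b,c,d non-decreasing breakpoints: membership rises on [a, b],
#'   is 1 on [b, c], falls on [c, d]. Use `-Inf`/`Inf` for boundary sets.
#' @return a [FuzzySet-class].
#' @export
fuzzySet <- function(name, a, b, c, d) {
  new("FuzzySet", name = as.character(name),
      a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

#' Create a fuzzy partition from ordered sets
#'
#' The sets must tile the axis: the first extends to -Inf, the last to +Inf,
#' and each pair of neighbours shares a complementary transition band, which
#' guarantees the partition-of-unity property (memberships sum to one at
#' every point).
#'
#' @param axisName feature axis name.
#' @param sets list of [FuzzySet-class] objects in axis order.
#' @return a [FuzzyPartition-class].
#' @export
fuzzyPartition <- function(axisName, sets) {
  new("FuzzyPartition", axisName = axisName, sets = sets)
}

#' @describeIn fuzzyPartition set labels of a partition.
#' @param p a [FuzzyPartition-class].
#' @export
setLabels <- function(p) vapply(p@sets, function(s) s@name, character(1))

#' Trapezoidal membership degree
#'
#' @param fset a [FuzzySet-class].
#' @param x numeric vector of axis values (finite).
#' @return memberships in [0, 1], same length as `x`.
#' @export
membership <- function(fset, x) {
  stopifnot(is(fset, "FuzzySet"))
  if (any(!is.finite(x))) stop("x must be finite")
  a <- fset@a; b <- fset@b; cc <- fset@c; d <- fset@d
  out <- numeric(length(x))
  out[x >= b & x <= cc] <- 1
  rise <- x > a & x < b
  if (any(rise)) out[rise] <- (x[rise] - a) / (b - a)
  fall <- x > cc & x < d
  if (any(fall)) out[fall] <- (d - x[fall]) / (d - cc)
  out
}

## Memberships of every set at every value: returns length(x) x n_sets matrix.
## Values outside the finite plateau range of the partition are effectively
## clamped by the unbounded boundary sets; an explicit domain clamp (with a
## warning) is applied for declared-domain axes by the callers that need it.
.partitionMatrix <- function(p, x) {
  ms <- vapply(p@sets, membership, numeric(length(x)), x = x)
  if (length(x) == 1L) ms <- matrix(ms, nrow = 1L)
  colnames(ms) <- setLabels(p)
  ms
}

#' Membership vector of a point in a fuzzy partition
#'
#' Returns one membership per set; by construction the components sum to one
#' and at most two adjacent sets are nonzero. Non-finite values (e.g. an
#' undefined feature) are rejected.
#'
#' @param p a [FuzzyPartition-class].
#' @param x a single axis value.
#' @return named numeric vector of memberships.
#' @export
partitionMemberships <- function(p, x) {
  stopifnot(is(p, "FuzzyPartition"), length(x) == 1L)
  drop(.partitionMatrix(p, x))
}

setMethod("show", "FuzzyPartition", function(object) {
  cat(sprintf("FuzzyPartition '%s' with %d sets: %s\n", object@axisName,
              length(object@sets), paste(setLabels(object), collapse = ", ")))
})

## ---- region-mass tables ---------------------------------------------------

#' Build a region-mass table from per-cell proposition labels
#'
#' @param tableName label for the table.
#' @param axis1,axis2 the two [FuzzyPartition-class] axes.
#' @param props character matrix (|axis1| x |axis2|) of proposition labels
#'   such as "P4(H2)" or "P1"; `NA` cells fall back to P1 (total ignorance:
#'   absence of training evidence is ignorance) with a warning.
#' @param labels optional character matrix of cell labels at their grid
#'   positions (defaults to `<prefix>ij` built from grid indices).
#' @param labelPrefix single letter used to build default labels.
#' @return a [RegionMassTable-class].
#' @export
regionMassTable <- function(tableName, axis1, axis2, props, labels = NULL,
                            labelPrefix = "R") {
  n1 <- length(axis1@sets); n2 <- length(axis2@sets)
  props <- as.matrix(props)
  if (!all(dim(props) == c(n1, n2))) {
    stop(sprintf("props must be a %d x %d matrix of proposition labels", n1, n2))
  }
  if (any(is.na(props))) {
    warning(sprintf("table '%s': %d unassigned cell(s) set to P1 (total ignorance)",
                    tableName, sum(is.na(props))))
    props[is.na(props)] <- "P1"
  }
  if (is.null(labels)) {
    labels <- outer(seq_len(n1), seq_len(n2),
                    function(i, j) sprintf("%s%d%d", labelPrefix, i, j))
  }
  labels <- as.matrix(labels)
  h1 <- h2 <- th <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      m <- propositionMass(props[i, j])
      h1[i, j] <- m@h1; h2[i, j] <- m@h2; th[i, j] <- m@theta
    }
  }
  dn <- list(setLabels(axis1), setLabels(axis2))
  dimnames(h1) <- dimnames(h2) <- dimnames(th) <- dimnames(props) <-
    dimnames(labels) <- dn
  new("RegionMassTable", tableName = tableName, axis1 = axis1, axis2 = axis2,
      h1 = h1, h2 = h2, theta = th, props = props, labels = labels)
}

#' @describeIn regionMassTable the proposition assigned to a cell label
#'   (e.g. "R23"), independent of where the transcription places it on the
#'   grid.
#' @param label cell label string.
#' @export
propositionForCell <- function(x, label) {
  stopifnot(is(x, "RegionMassTable"))
  idx <- which(x@labels == label)
  if (!length(idx)) stop("no cell labelled '", label, "' in table ", x@tableName)
  unname(x@props[idx[1L]])
}

#' @describeIn regionMassTable the proposition-label matrix behind the cells.
#' @param x a [RegionMassTable-class].
#' @export
cellPropositions <- function(x) {
  stopifnot(is(x, "RegionMassTable"))
  x@props
}

#' @describeIn regionMassTable the mass function of one cell, by set indices.
#' @param i,j cell indices on axis1 and axis2.
#' @export
cellMass <- function(x, i, j) {
  stopifnot(is(x, "RegionMassTable"))
  massFunction(x@h1[i, j], x@h2[i, j], x@theta[i, j])
}

setMethod("show", "RegionMassTable", function(object) {
  cat(sprintf("RegionMassTable '%s' (%s x %s), %d x %d cells\n",
              object@tableName, object@axis1@axisName, object@axis2@axisName,
              nrow(object@props), ncol(object@props)))
  print(object@props, quote = FALSE)
})

## Vectorized fuzzified lookup: x, y are parallel vectors on axis1/axis2.
## m(S) = sum_ij mu_i(x) mu_j(y) m_Rij(S); bilinear weights sum to one and
## every cell is a valid mass function, so the output rows are valid masses.
.regionMassVec <- function(table, x, y) {
  U1 <- .partitionMatrix(table@axis1, x)
  U2 <- .partitionMatrix(table@axis2, y)
  list(h1 = rowSums((U1 %*% table@h1) * U2),
       h2 = rowSums((U1 %*% table@h2) * U2),
       theta = rowSums((U1 %*% table@theta) * U2))
}

#' Fuzzified region mass at a point of the feature plane
#'
#' Computes the membership-weighted mixture of the cell mass functions,
#' `m(S) = sum_ij mu_i(x) mu_j(y) m_Rij(S)`, which reduces to a plain cell
#' lookup when (x, y) lies on the plateaus of a single cell.
#'
#' @param table a [RegionMassTable-class].
#' @param x,y single values on axis1 and axis2.
#' @return a [MassFunction-class].
#' @export
fuzzyRegionMass <- function(table, x, y) {
  stopifnot(is(table, "RegionMassTable"), length(x) == 1L, length(y) == 1L)
  r <- .regionMassVec(table, x, y)
  massFunction(r$h1, r$h2, r$theta)
}
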