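#' @import methods
#' @importFrom stats rnorm runif setNames quantile
#' @importFrom utils read.delim write.table
NULL

.MASS_TOL <- 1e-9

#' MassFunction: a basic probability assignment on the two-hypothesis frame
#'
#' The frame of discernment holds two exclusive hypotheses, H1 ("this window
#' is an AuxRE") and H2 ("it is not"), plus their union THETA representing
#' ignorance. A `MassFunction` distributes unit belief over these three focal
#' sets; the empty set implicitly carries mass zero.
#'
#' @slot h1 mass assigned to H1 (AuxRE), in [0, 1].
#' @slot h2 mass assigned to H2 (not AuxRE), in [0, 1].
#' @slot theta mass assigned to H1 u H2 (ignorance), in [0, 1].
#' @seealso [massFunction()], [combineMasses()], [belief()], [plausibility()]
#' @export
setClass("MassFunction",
  representation(h1 = "numeric", h2 = "numeric", theta = "numeric"),
  prototype(h1 = 0, h2 = 0, theta = 1)
)

setValidity("MassFunction", function(object) {
  v <- c(object@h1, object@h2, object@theta)
  if (length(v) != 3L || any(!is.finite(v))) {
    return("masses must be three finite numbers")
  }
  if (any(v < -.MASS_TOL)) {
    return("masses must be non-negative")
  }
  if (abs(sum(v) - 1) > .MASS_TOL) {
    return(sprintf("masses must sum to 1 (got %.12f)", sum(v)))
  }
  TRUE
})

#' CombinationResult: an orthogonal sum together with its conflict
#'
#' @slot mass the combined [MassFunction].
#' @slot conflictK the conflict K between the two sources, in [0, 1).
#' @export
setClass("CombinationResult",
  representation(mass = "MassFunction", conflictK = "numeric")
)

setValidity("CombinationResult", function(object) {
  if (object@conflictK < 0 || object@conflictK >= 1) {
    return("conflictK must lie in [0, 1); total conflict is an error, not a result")
  }
  TRUE
})

#' FuzzySet: one trapezoidal membership function
#'
#' Membership is 0 below `a`, rises linearly on [a, b], is 1 on the plateau
#' [b, c], falls linearly on [c, d] and is 0 above `d`. Boundary sets use
#' `a = b = -Inf` or `c = d = Inf`.
#'
#' @slot name label of the set (e.g. "core", "small").
#' @slot a,b,c,d non-decreasing breakpoints on the feature axis.
#' @export
setClass("FuzzySet",
  representation(name = "character", a = "numeric", b = "numeric",
                 c = "numeric", d = "numeric")
)

setValidity("FuzzySet", function(object) {
  bp <- c(object@a, object@b, object@c, object@d)
  if (any(is.na(bp))) return("breakpoints must not be NA")
  if (is.unsorted(bp)) return("breakpoints must be non-decreasing (a <= b <= c <= d)")
  TRUE
})

#' FuzzyPartition: an ordered list of trapezoidal sets forming a partition of unity
#'
#' Adjacent sets share complementary transition bands (set i falls on exactly
#' the interval where set i+1 rises), the first set extends to -Inf and the
#' last to +Inf, so memberships sum to one everywhere on the axis.
#'
#' @slot axisName name of the feature axis (e.g. "position", "score").
#' @slot sets list of [FuzzySet] objects, ordered along the axis.
#' @export
setClass("FuzzyPartition",
  representation(axisName = "character", sets = "list")
)

setValidity("FuzzyPartition", function(object) {
  ss <- object@sets
  if (length(ss) < 2L) return("a partition needs at least two sets")
  if (!all(vapply(ss, is, logical(1), "FuzzySet"))) {
    return("sets must all be FuzzySet objects")
  }
  if (!identical(ss[[1L]]@a, -Inf) || !identical(ss[[1L]]@b, -Inf)) {
    return("first set must have a = b = -Inf")
  }
  n <- length(ss)
  if (!identical(ss[[n]]@c, Inf) || !identical(ss[[n]]@d, Inf)) {
    return("last set must have c = d = Inf")
  }
  for (i in seq_len(n - 1L)) {
    if (ss[[i]]@c != ss[[i + 1L]]@a || ss[[i]]@d != ss[[i + 1L]]@b) {
      return(sprintf(
        "sets %d and %d do not share a complementary transition band", i, i + 1L))
    }
  }
  TRUE
})

#' RegionMassTable: a fuzzified grid of mass functions over a 2-D feature space
#'
#' One grid per learning graph. Cell (i, j) pairs the i-th set of `axis1` with
#' the j-th set of `axis2` and holds the basic probability assignment derived
#' from the proposition assigned to that confidence region.
#'
#' @slot tableName label of the table (e.g. "score_position").
#' @slot axis1,axis2 the two [FuzzyPartition] objects.
#' @slot h1,h2,theta numeric matrices (|axis1| x |axis2|) of cell masses.
#' @slot props character matrix of the proposition label behind each cell,
#'   e.g. "P3(H1)".
#' @slot labels character matrix of cell labels (e.g. "R23") at their grid
#'   positions; label digit order may differ from grid order when a table is
#'   transcribed with descending columns.
#' @export
setClass("RegionMassTable",
  representation(tableName = "character",
                 axis1 = "FuzzyPartition", axis2 = "FuzzyPartition",
                 h1 = "matrix", h2 = "matrix", theta = "matrix",
                 props = "matrix", labels = "matrix")
)

setValidity("RegionMassTable", function(object) {
  n1 <- length(object@axis1@sets)
  n2 <- length(object@axis2@sets)
  dims <- list(object@h1, object@h2, object@theta, object@props, object@labels)
  for (m in dims) {
    if (!all(dim(m) == c(n1, n2))) {
      return(sprintf("cell grids must be %d x %d", n1, n2))
    }
  }
  tot <- object@h1 + object@h2 + object@theta
  if (any(abs(tot - 1) > .MASS_TOL) ||
      any(object@h1 < 0) || any(object@h2 < 0) || any(object@theta < 0)) {
    return("every cell must hold a valid mass function")
  }
  TRUE
})

#' LdaModel: a fitted (or reference) Fisher discriminant model
#'
#' Two discriminant axes over the composition features (x1, y1, z1, gc).
#' Projections are dot products of the centered feature vector with the two
#' unit-norm discriminant vectors.
#'
#' @slot center global mean of (x1, y1, z1, gc) used for centering.
#' @slot discriminants 4 x 2 matrix; columns are the two discriminant vectors.
#' @slot explainedVariance eigenvalue fractions of the two axes, non-increasing.
#' @slot classMeans class-by-feature matrix of training class means (may have
#'   zero rows for a reference model shipped in a config).
#' @export
setClass("LdaModel",
  representation(center = "numeric", discriminants = "matrix",
                 explainedVariance = "numeric", classMeans = "matrix")
)

setValidity("LdaModel", function(object) {
  if (length(object@center) != 4L) return("center must have length 4 (x1, y1, z1, gc)")
  if (!all(dim(object@discriminants) == c(4L, 2L))) {
    return("discriminants must be a 4 x 2 matrix")
  }
  if (any(colSums(object@discriminants^2) == 0)) {
    return("discriminant vectors must be nonzero")
  }
  ev <- object@explainedVariance
  if (length(ev) != 2L || any(ev < -1e-12) || any(ev > 1 + 1e-12) || ev[1] < ev[2] - 1e-12) {
    return("explainedVariance must be two non-increasing fractions in [0, 1]")
  }
  TRUE
})

#' PromoterCollection: promoter sequences plus the auxin-responsive subset
#'
#' Promoters are upstream regions whose 3' end abuts the translational start
#' (ATG). `responsive` flags the promoters of 2-fold auxin-responsive genes;
#' it drives the density feature.
#'
#' @slot promoters a [Biostrings::DNAStringSet]; names are promoter ids.
#' @slot responsive character vector of responsive promoter ids (a subset of
#'   the promoter names).
#' @export
setClass("PromoterCollection",
  representation(promoters = "DNAStringSet", responsive = "character")
)

setValidity("PromoterCollection", function(object) {
  nm <- names(object@promoters)
  if (is.null(nm) || anyDuplicated(nm)) {
    return("promoters must have unique names")
  }
  if (!all(object@responsive %in% nm)) {
    return("responsive ids must be a subset of promoter names")
  }
  bad <- grepl("[^ACGTN]", as.character(object@promoters))
  if (any(bad)) return("promoter sequences must be uppercase over A, C, G, T, N")
  TRUE
})

#' FusionModel: the three fuzzified region-mass tables plus decision threshold
#'
#' @slot tablePosSc [RegionMassTable] over (position, significance score).
#' @slot tableOD [RegionMassTable] over (occurrence, density).
#' @slot tableF1F2 [RegionMassTable] over the two discriminant scores.
#' @slot lda [LdaModel] providing f1/f2 projections.
#' @slot threshold credibility threshold for calling an AuxRE (default 0.9).
#' @export
setClass("FusionModel",
  representation(tablePosSc = "RegionMassTable", tableOD = "RegionMassTable",
                 tableF1F2 = "RegionMassTable", lda = "LdaModel",
                 threshold = "numeric")
)

setValidity("FusionModel", function(object) {
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1) {
    return("threshold must be a single value in [0, 1]")
  }
  TRUE
})

#' ScanResult: all scored candidate windows of a promoter scan
#'
#' @slot candidates data.frame with one row per scored candidate window,
#'   sorted by credibility (descending): promoter_id, start, end, strand, seq,
#'   P, Sc, O, D, gc, x1, y1, z1, f1, f2, m_h1, m_h2, m_theta, credibility,
#'   is_hit.
#' @slot rejects data.frame of candidates whose evidence was totally
#'   conflicting (K = 1); same coordinate/feature columns, no masses.
#' @slot threshold the credibility threshold the `is_hit` column used.
#' @export
setClass("ScanResult",
  representation(candidates = "data.frame", rejects = "data.frame",
                 threshold = "numeric")
)
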