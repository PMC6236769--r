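## Dempster-Shafer algebra on the frame {H1 = AuxRE, H2 = not AuxRE}.
## Focal sets are H1, H2 and THETA = H1 u H2; the empty set carries no mass.

.FOCAL_LEVELS <- c("H1", "H2", "THETA")

#' Create a mass function
#'
#' Builds a [MassFunction-class] from its three components. Components must be
#' non-negative and sum to one within `1e-9`; anything further off is
#' rejected. Components are stored as given (tiny negative values are clamped
#' to zero), so printed table constants such as 0.67 survive bit-exactly.
#'
#' @param h1,h2,theta masses on H1 (AuxRE), H2 (not AuxRE) and the ignorance
#'   set H1 u H2.
#' @return a [MassFunction-class] object.
#' @examples
#' massFunction(0.67, 0, 0.33)
#' vacuousMass()  # total ignorance
#' @export
massFunction <- function(h1, h2, theta) {
  v <- c(h1, h2, theta)
  if (length(v) != 3L || any(!is.finite(v))) {
    stop("h1, h2 and theta must be single finite numbers")
  }
  if (any(v < -.MASS_TOL)) stop("masses must be non-negative")
  s <- sum(v)
  if (abs(s - 1) > .MASS_TOL) {
    stop(sprintf("masses must sum to 1 within %g (got %.12f)", .MASS_TOL, s))
  }
  v <- unname(pmax(v, 0))
  new("MassFunction", h1 = v[1L], h2 = v[2L], theta = v[3L])
}

#' @rdname massFunction
#' @export
vacuousMass <- function() new("MassFunction", h1 = 0, h2 = 0, theta = 1)

#' @describeIn massFunction the three masses as a named numeric vector.
#' @param x a [MassFunction-class].
#' @export
masses <- function(x) {
  stopifnot(is(x, "MassFunction"))
  c(h1 = x@h1, h2 = x@h2, theta = x@theta)
}

setMethod("show", "MassFunction", function(object) {
  cat(sprintf("MassFunction  m(H1)=%.4f  m(H2)=%.4f  m(Theta)=%.4f\n",
              object@h1, object@h2, object@theta))
})

## ---- proposition -> mass (Table of gradual doubt) -------------------------

## Preference level is encoded 0 / 0.33 / 0.67 / 1 for P1..P4, the residual
## doubt going to the ignorance set. Both columns are stored as the printed
## two-decimal constants (not computed as complements) so the mapping is
## bit-exact.
.PROP_PREF <- c(P1 = 0, P2 = 0.33, P3 = 0.67, P4 = 1)
.PROP_DOUBT <- c(P1 = 1, P2 = 0.67, P3 = 0.33, P4 = 0)

#' Map a doubt proposition to its basic probability assignment
#'
#' Four graded propositions express how strongly a confidence region points
#' at one hypothesis: P1 is total ignorance, P2 low preference with high
#' doubt, P3 strong preference with low doubt, P4 total confidence. The
#' preferred hypothesis receives 0, 0.33, 0.67 or 1 respectively and the
#' remainder goes to the ignorance set.
#'
#' @param level one of "P1", "P2", "P3", "P4".
#' @param preferred "H1" or "H2"; required for P2-P4, disallowed for P1.
#' @return a [MassFunction-class].
#' @examples
#' massFromProposition("P2", "H1")  # (0.33, 0, 0.67)
#' massFromProposition("P4", "H2")  # (0, 1, 0)
#' @export
massFromProposition <- function(level, preferred = NA_character_) {
  level <- match.arg(level, names(.PROP_PREF))
  if (level == "P1") {
    if (!is.na(preferred)) {
      stop("P1 expresses total ignorance and admits no preferred hypothesis")
    }
    return(vacuousMass())
  }
  if (is.na(preferred)) stop(level, " requires a preferred hypothesis (H1 or H2)")
  preferred <- match.arg(preferred, c("H1", "H2"))
  p <- .PROP_PREF[[level]]
  d <- .PROP_DOUBT[[level]]
  if (preferred == "H1") massFunction(p, 0, d) else massFunction(0, p, d)
}

#' Parse a proposition label such as "P3(H1)" or "P1"
#'
#' Labels follow the region tables: "P1" (no preference), or "Pk(Hi)" /
#' "Pk(Hi,Hj)" where the first hypothesis inside the parentheses is the
#' preferred one.
#'
#' @param label character scalar.
#' @return a [MassFunction-class].
#' @export
propositionMass <- function(label) {
  label <- gsub("\\s", "", label)
  m <- regmatches(label, regexec("^(P[1-4])(?:\\((H[12])(?:,H[12])?\\))?$", label))[[1L]]
  if (length(m) == 0L) stop("unrecognized proposition label: ", label)
  level <- m[2L]
  preferred <- if (nzchar(m[3L])) m[3L] else NA_character_
  massFromProposition(level, preferred)
}

## ---- combination ----------------------------------------------------------

## Vectorized orthogonal sum on parallel component vectors. Returns the
## combined components, the conflict K and a logical flag marking total
## conflict (those entries are NA in the masses). All scanner-scale fusion
## goes through here.
.combineVec <- function(h1a, h2a, ta, h1b, h2b, tb, tol = 1e-12) {
  K <- h1a * h2b + h2a * h1b
  conflict <- !is.na(K) & ((1 - K) <= tol)
  h1 <- h1a * h1b + h1a * tb + ta * h1b
  h2 <- h2a * h2b + h2a * tb + ta * h2b
  th <- ta * tb
  tot <- h1 + h2 + th
  h1 <- ifelse(conflict, NA_real_, h1 / tot)
  h2 <- ifelse(conflict, NA_real_, h2 / tot)
  th <- ifelse(conflict, NA_real_, th / tot)
  list(h1 = h1, h2 = h2, theta = th, K = K, conflict = conflict)
}

.conflictError <- function(K, what = "mass functions") {
  stop(errorCondition(
    sprintf("total conflict (K = %.6f): the two %s hold contradictory certainties and cannot be combined", K, what),
    class = c("auxref_conflict_error", "error", "condition")
  ))
}

#' Combine two mass functions with Dempster's orthogonal sum
#'
#' For each focal set A the combined mass sums the products m1(Ap) * m2(Aq)
#' over intersections Ap n Aq = A, normalized by 1 - K where
#' K = m1(H1) m2(H2) + m1(H2) m2(H1) is the conflict. Total conflict (K = 1,
#' i.e. two opposite certainties) raises an error of class
#' `"auxref_conflict_error"` rather than returning NaN.
#'
#' @param m1,m2 [MassFunction-class] objects.
#' @return a [CombinationResult-class] holding the combined mass and K.
#' @examples
#' r <- combineMasses(massFunction(0.67, 0, 0.33), massFunction(0.67, 0, 0.33))
#' combinedMass(r)   # (0.8911, 0, 0.1089)
#' conflictK(r)      # 0
#' @export
combineMasses <- function(m1, m2) {
  stopifnot(is(m1, "MassFunction"), is(m2, "MassFunction"))
  r <- .combineVec(m1@h1, m1@h2, m1@theta, m2@h1, m2@h2, m2@theta)
  if (r$conflict) .conflictError(r$K)
  new("CombinationResult",
      mass = massFunction(r$h1, r$h2, r$theta),
      conflictK = r$K)
}

#' @describeIn combineMasses the combined [MassFunction-class].
#' @param x a [CombinationResult-class].
#' @export
combinedMass <- function(x) {
  stopifnot(is(x, "CombinationResult"))
  x@mass
}

#' @describeIn combineMasses the conflict K in [0, 1).
#' @export
conflictK <- function(x) {
  stopifnot(is(x, "CombinationResult"))
  x@conflictK
}

setMethod("show", "CombinationResult", function(object) {
  cat(sprintf("CombinationResult  K=%.4f\n  ", object@conflictK))
  show(object@mass)
})

## ---- belief / plausibility ------------------------------------------------

#' Belief and plausibility of a focal set
#'
#' `belief` sums the masses of all subsets of `a`; `plausibility` sums the
#' masses of all focal sets intersecting `a`. They bound the probability of
#' `a` from below and above: Bel(a) <= Pls(a), and
#' Pls(a) = 1 - Bel(complement of a).
#'
#' @param m a [MassFunction-class].
#' @param a focal set: "H1", "H2" or "THETA".
#' @return a number in [0, 1].
#' @examples
#' m <- massFunction(0.67, 0, 0.33)
#' belief(m, "H1")        # 0.67
#' plausibility(m, "H1")  # 1
#' @export
belief <- function(m, a = c("H1", "H2", "THETA")) {
  stopifnot(is(m, "MassFunction"))
  switch(match.arg(a), H1 = m@h1, H2 = m@h2, THETA = m@h1 + m@h2 + m@theta)
}

#' @rdname belief
#' @export
plausibility <- function(m, a = c("H1", "H2", "THETA")) {
  stopifnot(is(m, "MassFunction"))
  switch(match.arg(a),
         H1 = m@h1 + m@theta,
         H2 = m@h2 + m@theta,
         THETA = m@h1 + m@h2 + m@theta)
}
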