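## The fusion pipeline on feature vectors: three fuzzified graph masses,
## two orthogonal sums, one credibility.

#' @describeIn fusedMass credibility threshold of a model.
#' @export
modelThreshold <- function(model) {
  stopifnot(is(model, "FusionModel"))
  model@threshold
}

#' @describeIn fusedMass replace the decision threshold.
#' @param value new threshold in [0, 1].
#' @export
`modelThreshold<-` <- function(model, value) {
  stopifnot(is(model, "FusionModel"))
  model@threshold <- as.numeric(value)
  validObject(model)
  model
}

## Vectorized three-graph fusion. p, sc, o, d, f1, f2 are parallel vectors;
## an NA density marks the undefined 0/0 case and turns the whole
## occurrence/density graph into a vacuous mass (ignorance, not evidence
## against). Returns per-candidate fused components plus the per-stage
## masses and conflict flags.
.fuseVec <- function(model, p, sc, o, d, f1, f2) {
  g1 <- .regionMassVec(model@tablePosSc, p, sc)
  dKnown <- !is.na(d)
  n <- length(p)
  g2 <- list(h1 = numeric(n), h2 = numeric(n), theta = rep(1, n))
  if (any(dKnown)) {
    gg <- .regionMassVec(model@tableOD, o[dKnown], d[dKnown])
    g2$h1[dKnown] <- gg$h1; g2$h2[dKnown] <- gg$h2; g2$theta[dKnown] <- gg$theta
  }
  g3 <- .regionMassVec(model@tableF1F2, f1, f2)
  m1 <- .combineVec(g1$h1, g1$h2, g1$theta, g2$h1, g2$h2, g2$theta)
  fused <- .combineVec(m1$h1, m1$h2, m1$theta, g3$h1, g3$h2, g3$theta)
  conflict <- m1$conflict | fused$conflict
  list(g1 = g1, g2 = g2, g3 = g3, m1 = m1, fused = fused, conflict = conflict)
}

.fvNumbers <- function(fv, fields) {
  v <- vapply(fields, function(f) {
    if (is.null(fv[[f]])) NA_real_ else as.numeric(fv[[f]])
  }, numeric(1))
  names(v) <- fields
  v
}

#' Fuse the evidence of a candidate's feature vector
#'
#' `method1Mass` combines the two overrepresentation graphs: the fuzzified
#' region mass at (P, Sc) on the position/score graph and at (O, D) on the
#' occurrence/density graph, merged with the orthogonal sum. `fusedMass`
#' further combines that with the discriminant graph mass at (f1, f2). An
#' undefined density (`NA`, the 0/0 sentinel) makes the occurrence/density
#' graph vacuous. Totally conflicting evidence raises an
#' `"auxref_conflict_error"`.
#'
#' @param model a [FusionModel-class].
#' @param fv named list or one-row data.frame of features: P, Sc, O, D for
#'   `method1Mass`; additionally f1, f2 for `fusedMass`.
#' @return a [MassFunction-class].
#' @examples
#' mdl <- defaultFusionModel()
#' fusedMass(mdl, list(P = 700, Sc = 10, O = 15, D = 0.5, f1 = -0.4, f2 = 0.1))
#' @export
method1Mass <- function(model, fv) {
  stopifnot(is(model, "FusionModel"))
  v <- .fvNumbers(fv, c("P", "Sc", "O", "D"))
  if (any(is.na(v[c("P", "Sc")]))) stop("fv must provide P and Sc")
  if (is.na(v["D"]) && is.na(v["O"])) v["O"] <- 0
  r <- .fuseVec(model, v["P"], v["Sc"], v["O"], v["D"], 0, 0)
  if (r$m1$conflict) .conflictError(r$m1$K, "learning graphs of method 1")
  massFunction(r$m1$h1, r$m1$h2, r$m1$theta)
}

#' @rdname method1Mass
#' @export
fusedMass <- function(model, fv) {
  stopifnot(is(model, "FusionModel"))
  v <- .fvNumbers(fv, c("P", "Sc", "O", "D", "f1", "f2"))
  if (any(is.na(v[c("P", "Sc", "f1", "f2")]))) {
    stop("fv must provide P, Sc, f1 and f2")
  }
  if (is.na(v["D"]) && is.na(v["O"])) v["O"] <- 0
  r <- .fuseVec(model, v["P"], v["Sc"], v["O"], v["D"], v["f1"], v["f2"])
  if (r$conflict) .conflictError(max(r$m1$K, r$fused$K, na.rm = TRUE))
  massFunction(r$fused$h1, r$fused$h2, r$fused$theta)
}

#' Decide whether a fused mass calls an AuxRE
#'
#' The credibility of a candidate is the fused belief in H1, which on this
#' frame equals the singleton mass m(H1). The decision is inclusive:
#' credibility >= threshold is a hit.
#'
#' @param model a [FusionModel-class].
#' @param mass a [MassFunction-class] (the fused mass) or a numeric
#'   credibility.
#' @return logical.
#' @export
decideHit <- function(model, mass) {
  stopifnot(is(model, "FusionModel"))
  cred <- if (is(mass, "MassFunction")) belief(mass, "H1") else as.numeric(mass)
  cred >= model@threshold
}
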