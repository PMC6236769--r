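## Fisher multi-class discriminant analysis on the composition features
## (x1, y1, z1, gc). The two leading eigenvectors of within^-1 x between
## define the discriminant plane in which AuxREs separate from the other
## cis-element families.

#' Fit a two-axis Fisher discriminant model
#'
#' Computes the within-class and between-class scatter of the four
#' composition features and keeps the two leading eigenvectors of
#' `solve(within) %*% between`. Discriminant vectors are scaled to unit norm
#' and signed so that their largest-magnitude component is positive, making
#' the f1/f2 orientation reproducible. A singular within-scatter is
#' ridge-regularized with `eps = 1e-6 * trace / 4` (with a warning).
#'
#' @param x numeric matrix (n x 4) of features, columns (x1, y1, z1, gc).
#' @param classes class label per row; at least two classes with at least two
#'   samples each.
#' @return an [LdaModel-class].
#' @export
fitLda <- function(x, classes) {
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop("x must have 4 columns: x1, y1, z1, gc")
  classes <- as.character(classes)
  if (length(classes) != nrow(x)) stop("length(classes) must match nrow(x)")
  tab <- table(classes)
  if (length(tab) < 2L) stop("need at least two classes")
  if (any(tab < 2L)) stop("need at least two samples per class")

  center <- colMeans(x)
  cls <- names(tab)
  classMeans <- t(vapply(cls, function(cl) colMeans(x[classes == cl, , drop = FALSE]),
                         numeric(4L)))
  Sw <- matrix(0, 4L, 4L)
  Sb <- matrix(0, 4L, 4L)
  for (cl in cls) {
    xi <- x[classes == cl, , drop = FALSE]
    d <- sweep(xi, 2L, classMeans[cl, ])
    Sw <- Sw + crossprod(d)
    dm <- classMeans[cl, ] - center
    Sb <- Sb + nrow(xi) * tcrossprod(dm)
  }

  SwInv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(SwInv) || kappa(Sw) > 1e12) {
    eps <- 1e-6 * sum(diag(Sw)) / 4
    if (eps == 0) eps <- 1e-12
    warning("within-class scatter is singular; ridge-regularizing with eps = ",
            format(eps))
    SwInv <- solve(Sw + diag(eps, 4L))
  }

  eg <- eigen(SwInv %*% Sb)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- pmax(Re(eg$values)[ord], 0)
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  if (sum(vals) <= 1e-12) {
    warning("between-class scatter is zero: classes share a common mean")
    ev <- c(0, 0)
  } else {
    ev <- vals[1:2] / sum(vals)
  }
  W <- vecs[, 1:2, drop = FALSE]
  for (j in 1:2) {
    w <- W[, j]
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      w <- rep(0.5, 4L) # degenerate axis; any unit vector, fixed for determinism
    } else {
      w <- w / nw
    }
    if (w[which.max(abs(w))] < 0) w <- -w
    W[, j] <- w
  }
  rownames(W) <- c("x1", "y1", "z1", "gc")
  colnames(W) <- c("f1", "f2")
  new("LdaModel", center = setNames(center, c("x1", "y1", "z1", "gc")),
      discriminants = W, explainedVariance = ev, classMeans = classMeans)
}

#' Project composition features onto the discriminant plane
#'
#' f1 and f2 are dot products of the centered (x1, y1, z1, gc) vector with
#' the two discriminant vectors; the global training mean projects to (0, 0).
#'
#' @param model an [LdaModel-class].
#' @param x1,y1,z1,gc numeric vectors (recycled to common length).
#' @return matrix with columns f1, f2.
#' @export
ldaProject <- function(model, x1, y1, z1, gc) {
  stopifnot(is(model, "LdaModel"))
  X <- cbind(x1 = x1, y1 = y1, z1 = z1, gc = gc)
  sweep(X, 2L, model@center) %*% model@discriminants
}

#' Construct a reference discriminant model from explicit axes
#'
#' Used by model configs that ship fixed projection axes rather than refitting
#' at load time.
#'
#' @param discriminant1,discriminant2 numeric length-4 vectors over
#'   (x1, y1, z1, gc); normalized to unit length.
#' @param center length-4 centering vector.
#' @param explainedVariance two non-increasing fractions.
#' @return an [LdaModel-class].
#' @export
referenceLda <- function(discriminant1, discriminant2, center,
                         explainedVariance = c(0.6, 0.32)) {
  W <- cbind(f1 = discriminant1 / sqrt(sum(discriminant1^2)),
             f2 = discriminant2 / sqrt(sum(discriminant2^2)))
  rownames(W) <- c("x1", "y1", "z1", "gc")
  new("LdaModel", center = setNames(as.numeric(center), c("x1", "y1", "z1", "gc")),
      discriminants = W, explainedVariance = as.numeric(explainedVariance),
      classMeans = matrix(numeric(0), 0L, 4L,
                          dimnames = list(NULL, c("x1", "y1", "z1", "gc"))))
}

setMethod("show", "LdaModel", function(object) {
  cat(sprintf("LdaModel: 2 discriminant axes over (x1, y1, z1, gc); explained variance %.1f%% / %.1f%%\n",
              100 * object@explainedVariance[1], 100 * object@explainedVariance[2]))
})

#' Principal angles between two discriminant subspaces
#'
#' Utility for comparing a fitted discriminant plane with a reference one
#' (e.g. simulation truth): returns the principal angles, in degrees, between
#' the column spaces of the two 4 x 2 matrices.
#'
#' @param W1,W2 4 x 2 matrices of basis vectors.
#' @return two angles in degrees, non-decreasing.
#' @export
principalAngles <- function(W1, W2) {
  Q1 <- qr.Q(qr(W1))
  Q2 <- qr.Q(qr(W2))
  sv <- svd(crossprod(Q1, Q2))$d
  sv <- pmin(pmax(sv, -1), 1)
  sort(acos(sv) * 180 / pi)
}
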