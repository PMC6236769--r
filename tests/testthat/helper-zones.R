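# Zone -> cell groupings of the three region tables and their documented
# AuxRE percentages, used to check fixture region proportions.
g1Zones <- list(Z1 = "R11", Z2 = "R12", Z3 = "R13", Z4 = c("R14", "R24", "R34"),
                Z5 = "R23", Z6 = c("R21", "R31", "R32", "R33", "R22"))
g1Target <- c(Z1 = 7, Z2 = 25, Z3 = 0, Z4 = 0, Z5 = 80, Z6 = 100)
g2Zones <- list(Z7 = "D11", Z8 = "D12", Z9 = "D22", Z10 = "D41",
                Z11 = c("D21", "D31"), Z12 = c("D13", "D23", "D32", "D33", "D42", "D43"))
g2Target <- c(Z7 = 43, Z8 = 13, Z9 = 91, Z10 = 100, Z11 = 0, Z12 = 0)
g3Zones <- list(Z11 = c("Q11", "Q21", "Q12"), Z12 = "Q22",
                Z13 = c("Q13", "Q23", "Q33"), Z14 = c("Q31", "Q32"),
                Z15 = c("Q41", "Q42", "Q43"))
g3Target <- c(Z11 = 0, Z12 = 70, Z13 = 0, Z14 = 10, Z15 = 0)

binCells <- function(tab, x, y, prefix) {
  i <- apply(AuxREfusion:::.partitionMatrix(tab@axis1, x), 1, which.max)
  j <- apply(AuxREfusion:::.partitionMatrix(tab@axis2, y), 1, which.max)
  mapply(function(ii, jj) tab@labels[ii, jj], i, j)
}

zonePct <- function(cells, classes, zones) {
  vapply(zones, function(z) 100 * mean(classes[cells %in% z] == "AuxRE"), numeric(1))
}

# Simulated five-class composition data with a known 2-D discriminant plane,
# used for subspace-recovery checks of the discriminant fitter.
simulate5Class <- function(nPerClass, seed = 1, noise = 0.08) {
  set.seed(seed)
  w1 <- c(0.8, 0.6, 0, 0)
  w2 <- c(0, 0, 0.9, -sqrt(1 - 0.81))
  centers <- list(c(-0.8, -0.3), c(0.7, -0.45), c(0, 0.6), c(-0.45, 0.5), c(0.8, 0.45))
  X <- NULL; cls <- NULL
  for (k in seq_along(centers)) {
    f1 <- rnorm(nPerClass, centers[[k]][1], 0.02)
    f2 <- rnorm(nPerClass, centers[[k]][2], 0.02)
    Xi <- cbind(0, 0, 0, 0.5)[rep(1, nPerClass), ] +
      outer(f1, w1) + outer(f2, w2) +
      matrix(rnorm(4 * nPerClass, 0, noise), nPerClass, 4)
    X <- rbind(X, Xi)
    cls <- c(cls, rep(paste0("c", k), nPerClass))
  }
  list(X = X, cls = cls, W = cbind(w1, w2))
}
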