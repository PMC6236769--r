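# Independent brute-force oracle for Dempster's rule: enumerate all nine
# focal-set products and bin them by set intersection. Kept deliberately
# naive and separate from the package's combination code path.
oracleCombine <- function(m1, m2) {
  focal <- c("H1", "H2", "THETA")
  intersectFocal <- function(a, b) {
    if (a == b) return(a)
    if (a == "THETA") return(b)
    if (b == "THETA") return(a)
    "EMPTY"
  }
  acc <- c(H1 = 0, H2 = 0, THETA = 0, EMPTY = 0)
  for (a in focal) {
    for (b in focal) {
      acc[intersectFocal(a, b)] <- acc[intersectFocal(a, b)] + m1[a] * m2[b]
    }
  }
  K <- unname(acc["EMPTY"])
  list(mass = acc[c("H1", "H2", "THETA")] / (1 - K), K = K)
}

randomMassVec <- function() {
  v <- runif(3)
  v <- v / sum(v)
  c(H1 = v[1], H2 = v[2], THETA = v[3])
}

massToVec <- function(m) {
  v <- masses(m)
  c(H1 = unname(v["h1"]), H2 = unname(v["h2"]), THETA = unname(v["theta"]))
}
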