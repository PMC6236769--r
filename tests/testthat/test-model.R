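latticeH1 <- list(c(0, 0, 1), c(0.33, 0, 0.67), c(0.67, 0, 0.33), c(1, 0, 0))

test_that("the default model resolves the printed region propositions", {
  mdl <- defaultFusionModel()
  # the all-AuxRE zone of the score/position graph is total confidence
  for (cell in c("R21", "R31", "R32", "R33", "R22")) {
    expect_equal(propositionForCell(mdl@tablePosSc, cell), "P4(H1)", label = cell)
  }
  expect_equal(propositionForCell(mdl@tablePosSc, "R23"), "P3(H1)")
  expect_equal(propositionForCell(mdl@tablePosSc, "R11"), "P4(H2)")
  expect_equal(propositionForCell(mdl@tablePosSc, "R12"), "P2(H2)")
  expect_equal(propositionForCell(mdl@tableOD, "D11"), "P1")
  expect_equal(propositionForCell(mdl@tableOD, "D41"), "P4(H1)")
  expect_equal(propositionForCell(mdl@tableOD, "D22"), "P3(H1)")
  expect_equal(propositionForCell(mdl@tableF1F2, "Q22"), "P3(H1)")
  for (cell in c("Q31", "Q32")) {
    expect_equal(propositionForCell(mdl@tableF1F2, cell), "P3(H2)")
  }
  # resolved masses follow the proposition mapping
  dump <- dumpModelMasses(mdl)
  z6 <- dump[dump$cell %in% c("R21", "R31", "R32", "R33", "R22"), ]
  expect_true(all(z6$m_h1 == 1 & z6$m_h2 == 0))
  d11 <- dump[dump$cell == "D11", ]
  expect_equal(unlist(d11[, c("m_h1", "m_h2", "m_theta")], use.names = FALSE), c(0, 0, 1))
  z14 <- dump[dump$cell %in% c("Q31", "Q32"), ]
  expect_true(all(z14$m_h2 == 0.67 & z14$m_theta == 0.33))
  expect_equal(modelThreshold(mdl), 0.9)
})

test_that("a model config round-trips through the parser unchanged", {
  mdl <- defaultFusionModel()
  path <- tempfile(fileext = ".yaml")
  writeModelConfig(mdl, path)
  back <- readModelConfig(path)
  expect_equal(dumpModelMasses(back), dumpModelMasses(mdl))
  expect_equal(back@threshold, mdl@threshold)
  expect_equal(back@lda@discriminants, mdl@lda@discriminants, tolerance = 1e-12)
  for (slot in c("tablePosSc", "tableOD", "tableF1F2")) {
    a <- slot(mdl, slot); b <- slot(back, slot)
    for (ax in c("axis1", "axis2")) {
      sa <- slot(a, ax)@sets; sb <- slot(b, ax)@sets
      expect_equal(lapply(sa, function(s) c(s@a, s@b, s@c, s@d)),
                   lapply(sb, function(s) c(s@a, s@b, s@c, s@d)))
    }
  }
})

test_that("unknown propositions are rejected and missing cells warn into ignorance", {
  cfgFile <- system.file("extdata", "default_model.yaml", package = "AuxREfusion")
  cfg <- yaml::read_yaml(cfgFile)
  bad <- cfg; bad$tables$f1_f2$cells$Q22 <- "P9(H1)"
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(readModelConfig(f), "unrecognized")
  sparse <- cfg; sparse$tables$f1_f2$cells$Q22 <- NULL
  f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(sparse, f2)
  expect_warning(m <- readModelConfig(f2), "ignorance")
  expect_equal(propositionForCell(m@tableF1F2, "Q22"), "P1")
})

test_that("method-1 fusion combines the two overrepresentation graphs", {
  mdl <- defaultFusionModel()
  # certainty (distal, high score) absorbs the ignorance of an undefined density
  m <- method1Mass(mdl, list(P = 700, Sc = 10, O = 0, D = NA))
  expect_equal(unname(masses(m)), c(1, 0, 0))
  # two strong-preference cells combine to 0.8911
  m2 <- method1Mass(mdl, list(P = 350, Sc = 5.8, O = 20, D = 0.5))
  expect_equal(unname(masses(m2)), c(0.8911, 0, 0.1089), tolerance = 1e-9)
  # opposite certainties across the graphs are a hard conflict
  expect_error(method1Mass(mdl, list(P = 700, Sc = 10, O = 20, D = 0.05)),
               class = "auxref_conflict_error")
})

test_that("the fused mass stacks the discriminant graph on method 1", {
  mdl <- defaultFusionModel()
  fv <- list(P = 350, Sc = 5.8, O = 20, D = 0.5, f1 = -0.45, f2 = 0.15)
  out <- fusedMass(mdl, fv)
  # triple strong preference: oracle-combined 0.8911 (+) 0.67
  ref <- oracleCombine(c(H1 = 0.8911, H2 = 0, THETA = 0.1089),
                       c(H1 = 0.67, H2 = 0, THETA = 0.33))
  expect_equal(massToVec(out), ref$mass, tolerance = 1e-9)
  expect_equal(belief(out, "H1"), 0.9640, tolerance = 1e-3)
  # certain non-AuxRE composition against certain-AuxRE method 1: hard conflict
  expect_error(fusedMass(mdl, list(P = 700, Sc = 10, O = 0, D = NA,
                                   f1 = -1.2, f2 = 0.65)),
               class = "auxref_conflict_error")
})

test_that("stronger single-graph AuxRE evidence never lowers fused credibility", {
  # over the proposition mass lattice: raise one graph's m(H1) with m(H2) = 0
  for (fixedA in latticeH1) {
    for (fixedB in latticeH1) {
      creds <- vapply(latticeH1, function(v) {
        m1 <- combineMasses(massFunction(v[1], v[2], v[3]),
                            massFunction(fixedA[1], fixedA[2], fixedA[3]))
        out <- combineMasses(combinedMass(m1),
                             massFunction(fixedB[1], fixedB[2], fixedB[3]))
        belief(combinedMass(out), "H1")
      }, numeric(1))
      expect_true(all(diff(creds) >= -1e-12))
    }
  }
})

test_that("pipeline-level combination is associative", {
  set.seed(13)
  for (i in 1:100) {
    vs <- replicate(3, randomMassVec(), simplify = FALSE)
    ms <- lapply(vs, function(v) massFunction(v["H1"], v["H2"], v["THETA"]))
    left <- combinedMass(combineMasses(combinedMass(combineMasses(ms[[1]], ms[[2]])), ms[[3]]))
    right <- combinedMass(combineMasses(ms[[1]], combinedMass(combineMasses(ms[[2]], ms[[3]]))))
    expect_equal(masses(left), masses(right), tolerance = 1e-9)
  }
})

test_that("the hit decision is inclusive at the threshold", {
  mdl <- defaultFusionModel()
  expect_true(decideHit(mdl, 0.95))
  expect_true(decideHit(mdl, 0.9))
  expect_false(decideHit(mdl, 0.899))
  expect_false(decideHit(mdl, 0))
  expect_true(decideHit(mdl, massFunction(0.95, 0, 0.05)))
})
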