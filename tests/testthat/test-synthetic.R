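test_that("geometry generation is deterministic and respects layout bounds", {
  expect_error(makeGeometry(3), "invalid argument")

  g4 <- makeGeometry(4, "grid", seed = 1)
  D <- regionDist(g4)
  expect_equal(dim(D), c(4, 4))
  expect_equal(diag(D), rep(0, 4))
  expect_true(all(D[upper.tri(D)] > 0))

  g7a <- makeGeometry(40, "sphere", seed = 7)
  g7b <- makeGeometry(40, "sphere", seed = 7)
  expect_identical(regionCoords(g7a), regionCoords(g7b))
  expect_identical(regionDist(g7a), regionDist(g7b))

  gs <- makeGeometry(200, "sphere", seed = 3)
  expect_lte(max(regionDist(gs)), 2.0)
  expect_equal(sqrt(rowSums(regionCoords(gs)^2)), rep(1, 200),
               tolerance = 1e-8)
})

test_that("expression fields have the requested spatial covariance structure", {
  g <- smallGeometry(40, seed = 2)
  expect_error(makeExpression(g, 10, autocorrScale = 0), "invalid argument")

  # white-noise limit: neighbouring regions decorrelate
  eWhite <- makeExpression(g, 1000, autocorrScale = 0.005, donorNoiseSd = 0,
                           seed = 5)
  E <- regionGeneMatrix(eWhite)
  D <- regionDist(g)
  nn <- apply(D + diag(Inf, 40), 1, which.min)
  adjCor <- mean(vapply(1:40, function(i) cor(E[i, ], E[nn[i], ]), numeric(1)))
  expect_lt(abs(adjCor), 0.1)

  # long-range limit: regions collapse onto a common field
  eSmooth <- makeExpression(g, 1000, autocorrScale = 200, donorNoiseSd = 0.1,
                            seed = 5)
  Es <- regionGeneMatrix(eSmooth)
  C <- cor(t(Es))
  expect_gt(mean(C[upper.tri(C)]), 0.9)

  # determinism
  e1 <- makeExpression(g, 20, autocorrScale = 0.5, seed = 9)
  e2 <- makeExpression(g, 20, autocorrScale = 0.5, seed = 9)
  expect_identical(regionGeneMatrix(e1), regionGeneMatrix(e2))
})

test_that("planted atrophy correlations follow the analytic attenuation", {
  g <- smallGeometry(60, seed = 3)
  expr <- makeExpression(g, 5, autocorrScale = 0.5, donorNoiseSd = 0, seed = 4)
  genes <- colnames(regionGeneMatrix(expr))

  noiseless <- makeAtrophy(g, expr, setNames(1, genes[1]), noiseSd = 0, seed = 1)
  expect_equal(unname(noiseless$truth$realizedR), 1.0, tolerance = 1e-10)

  neg <- makeAtrophy(g, expr, setNames(-1, genes[2]), noiseSd = 0, seed = 1)
  expect_equal(unname(neg$truth$realizedR), -1.0, tolerance = 1e-10)

  expect_error(makeAtrophy(g, expr, c(NOPE = 1)), "missing gene")

  # attenuation w / sqrt(w^2 + sd^2) recovered over Monte-Carlo replicates
  rs <- vapply(1:40, function(s)
    unname(makeAtrophy(g, expr, setNames(1, genes[1]), noiseSd = 1,
                       autocorrScale = 0.5, seed = s)$truth$realizedR),
    numeric(1))
  expect_equal(mean(abs(rs)), 1 / sqrt(2), tolerance = 0.08)
})

test_that("cohort generator plants recoverable covariate effects", {
  g <- smallGeometry(20, seed = 4)
  cov <- list(age = list(mean = 70, sd = 8, beta = -0.01))
  expect_error(makeCohort(g, 2, 0, cov), "underdetermined")

  # severity 0: patients indistinguishable from controls
  expr <- makeExpression(g, 3, autocorrScale = 0.5, seed = 1)
  atr <- makeAtrophy(g, expr, setNames(1, "G00001"), noiseSd = 0.3, seed = 2)
  coh0 <- makeCohort(g, 60, 60, cov, atrophy = atr$wmap, severity = 0,
                     noiseSd = 0.2, seed = 3)
  vals <- as.matrix(coh0$subjects[, regionIds(g)])
  grp <- coh0$subjects$group
  pv <- vapply(seq_len(ncol(vals)), function(j)
    t.test(vals[grp == "control", j], vals[grp == "patient", j])$p.value,
    numeric(1))
  expect_lt(mean(pv < 0.05), 0.2)
  expect_gt(min(pv), 1e-4)

  # sigma = 0: residuals of the generating model vanish exactly
  cohZ <- makeCohort(g, 30, 0, cov, noiseSd = 0, seed = 5)
  res <- vapply(regionIds(g), function(rg)
    max(abs(resid(lm(cohZ$subjects[[rg]] ~ cohZ$subjects$age)))), numeric(1))
  expect_lt(max(res), 1e-10)

  # OLS recovery of the generating betas within +/- 3 SE at n = 400
  coh <- makeCohort(g, 400, 0, cov, noiseSd = 0.2, seed = 6)
  fit <- lm(coh$subjects[[regionIds(g)[1]]] ~ coh$subjects$age)
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - (-0.01)), 3 * est["Std. Error"])
})

test_that("gene-list generator plants the requested overlap odds ratio", {
  genes <- sprintf("g%05d", 1:10000)
  expect_error(makeGeneLists(genes, -0.1, 0.1), "invalid argument")
  expect_error(makeGeneLists(genes, 0.5, 1.0), "invalid argument")

  # independence: Fisher p approximately uniform over replicates
  ps <- vapply(1:20, function(s) {
    cat1 <- makeGeneLists(genes[1:2000], 0.2, 0.2, overlapEnrichment = 1,
                          seed = s)
    fisherOverlap(geneSet(cat1, "HAR"), geneSet(cat1, "CS"),
                  genes[1:2000])$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)

  cat4 <- makeGeneLists(genes, 0.15, 0.08, overlapEnrichment = 4, seed = 11)
  orHat <- attr(cat4, "truth")$oddsRatio
  expect_lt(abs(log(orHat / 4)), 0.25)

  cat0 <- makeGeneLists(genes, 0, 0.1, seed = 1)
  expect_length(geneSet(cat0, "HAR"), 0)
  expect_error(fisherOverlap(geneSet(cat0, "HAR"), geneSet(cat0, "CS"), genes),
               "empty set")
})

test_that("sequence generator plants GU content monotonically and reproducibly", {
  expect_error(makeSequences("g1", lengthRange = c(4, 10)), "invalid argument")

  # AC-only alphabet with no planted runs contains no GT motifs
  s0 <- makeSequences(paste0("g", 1:5), c(50, 80), guWeight = 0,
                      alphabet = c("A", "C"), seed = 1)
  expect_true(all(guProfile(s0)[, c("c4", "c5", "c6")] == 0))

  sA <- makeSequences(paste0("g", 1:10), c(100, 200), guWeight = 0.03, seed = 9)
  sB <- makeSequences(paste0("g", 1:10), c(100, 200), guWeight = 0.03, seed = 9)
  expect_identical(as.character(sA), as.character(sB))

  ids <- paste0("g", 1:200)
  gw <- setNames(rep(c(0.005, 0.08), each = 100), ids)
  seqs <- makeSequences(ids, c(300, 600), gw, seed = 13)
  prof <- guProfile(seqs)
  expect_gt(median(prof$c4[101:200]), median(prof$c4[1:100]))
})

test_that("connectivity library maps decay from their seeds", {
  g <- makeGeometry(10, "sphere", seed = 5)
  expect_error(makeConnectivityLibrary(g, 11, 0.5), "invalid argument")

  lib <- makeConnectivityLibrary(g, 10, kernelScale = 0.5, noiseSd = 0, seed = 2)
  M <- seedMaps(lib)
  for (i in seq_along(librarySeeds(lib))) {
    self <- match(librarySeeds(lib)[i], regionIds(g))
    expect_equal(which.max(M[i, ]), self)
  }
  C <- cor(t(M))
  expect_true(all(C[upper.tri(C)] < 1))

  libInf <- makeConnectivityLibrary(g, 5, kernelScale = Inf, seed = 2)
  expect_true(all(seedMaps(libInf) == 1))
})
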