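# Construct a small donor-level probe dataset positioned exactly on region
# centroids, so sample assignment is unambiguous.
makeToyProbes <- function(geom, genes, probesPerGene, nDonors = 2, seed = 1,
                          noise = 0.1) {
  set.seed(seed)
  coords <- regionCoords(geom)
  n <- nrow(coords)
  samples <- do.call(rbind, lapply(seq_len(nDonors), function(d)
    data.frame(sampleId = sprintf("d%d_s%02d", d, seq_len(n)),
               donor = paste0("donor", d),
               x = coords[, 1], y = coords[, 2], z = coords[, 3])))
  probeId <- unlist(lapply(seq_along(genes), function(i)
    sprintf("%s_p%d", genes[i], seq_len(probesPerGene[i]))))
  geneId <- rep(genes, probesPerGene)
  truth <- matrix(rnorm(length(genes) * n), length(genes), n)
  expr <- t(vapply(seq_along(probeId), function(k)
    rep(truth[match(geneId[k], genes), ], nDonors) +
      noise * rnorm(n * nDonors),
    numeric(n * nDonors)))
  ProbeMatrix(probeId, geneId, expr,
              matrix(TRUE, nrow(expr), ncol(expr)), samples)
}

test_that("background filtering keeps probes strictly above the 50% rule", {
  samples <- data.frame(sampleId = paste0("s", 1:100), donor = "d1",
                        x = 0, y = 0, z = 0)
  bg <- rbind(rep(c(TRUE, FALSE), c(51, 49)),
              rep(c(TRUE, FALSE), c(50, 50)),
              rep(TRUE, 100))
  pm <- ProbeMatrix(paste0("p", 1:3), paste0("g", 1:3),
                    matrix(1, 3, 100), bg, samples)
  kept <- filterBackground(pm)
  expect_setequal(kept@probeId, c("p1", "p3"))

  allIn <- ProbeMatrix(paste0("p", 1:3), paste0("g", 1:3),
                       matrix(1, 3, 100), matrix(TRUE, 3, 100), samples)
  expect_identical(filterBackground(allIn)@probeId, allIn@probeId)
})

test_that("sample assignment matches brute-force nearest-centroid search", {
  g <- makeGeometry(5, "grid", seed = 1)
  set.seed(2)
  pts <- data.frame(sampleId = paste0("s", 1:20),
                    x = runif(20, -1, 3), y = runif(20, -1, 3), z = 0)
  maxDist <- 0.9
  got <- assignSamplesToParcels(pts, g, maxDist)
  for (i in 1:20) {
    d <- sqrt(colSums((t(regionCoords(g)) - as.numeric(pts[i, c("x", "y", "z")]))^2))
    want <- if (min(d) <= maxDist) regionIds(g)[which.min(d)] else NA_character_
    expect_identical(unname(got[i]), want)
  }
  # sample exactly on a centroid maps to that region
  onC <- data.frame(sampleId = "c", x = regionCoords(g)[3, 1],
                    y = regionCoords(g)[3, 2], z = regionCoords(g)[3, 3])
  expect_identical(unname(assignSamplesToParcels(onC, g)[1]), regionIds(g)[3])
})

test_that("probe collapse selects the most stable probe per gene", {
  g <- makeGeometry(12, "grid", seed = 3)
  pm <- makeToyProbes(g, c("gA", "gB"), c(1, 3), nDonors = 3, seed = 4)
  # corrupt gB's probe 2 with heavy independent noise per donor
  idx <- which(pm@probeId == "gB_p2")
  pm@expr[idx, ] <- rnorm(ncol(pm@expr), sd = 5)
  assignment <- assignSamplesToParcels(pm@samples, g)
  collapsed <- collapseProbes(pm, assignment, g)
  expect_setequal(rownames(collapsed), c("gA", "gB"))
  # single-probe gene passes through untouched
  expect_equal(unname(collapsed["gA", ]),
               unname(pm@expr[pm@probeId == "gA_p1", ]))

  # brute force: gB's chosen row must be the probe maximizing the mean
  # pairwise inter-donor Spearman correlation of regional profiles
  profiles <- atrogex:::regionProfiles(
    `rownames<-`(pm@expr, pm@probeId), pm@samples, assignment, g)
  cand <- paste0("gB_p", 1:3)
  ds <- vapply(cand, function(p) {
    cors <- c()
    for (a in 1:2) for (b in (a + 1):3) {
      pa <- profiles[[a]][p, ]; pb <- profiles[[b]][p, ]
      cors <- c(cors, cor(pa, pb, method = "spearman"))
    }
    mean(cors)
  }, numeric(1))
  best <- cand[which.max(ds)]
  expect_equal(unname(collapsed["gB", ]),
               unname(pm@expr[pm@probeId == best, ]))

  # a constant probe can never be selected over a varying one
  pm2 <- makeToyProbes(g, "gC", 2, nDonors = 2, seed = 5)
  pm2@expr[pm2@probeId == "gC_p1", ] <- 7
  col2 <- collapseProbes(pm2, assignSamplesToParcels(pm2@samples, g), g)
  expect_equal(unname(col2["gC", ]),
               unname(pm2@expr[pm2@probeId == "gC_p2", ]))
})

test_that("scaled robust sigmoid normalization behaves as specified", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL))
  out <- normalizeExpression(m, rep("d1", 3))
  expect_equal(as.numeric(out), c(0, 0.5, 1))
  expect_true(all(diff(as.numeric(out)) > 0))

  # invariance under positive affine transforms
  set.seed(6)
  x <- matrix(rnorm(20), 1, dimnames = list("g1", NULL))
  expect_equal(normalizeExpression(5 * x + 3, rep("d1", 20)),
               normalizeExpression(x, rep("d1", 20)))

  # constant gene dropped with warning
  cm <- matrix(c(2, 2, 2, 1, 5, 9), 2, byrow = TRUE,
               dimnames = list(c("gc", "gv"), NULL))
  expect_warning(res <- normalizeExpression(cm, rep("d1", 3)), "constant")
  expect_true(all(is.na(res["gc", ])))
  expect_false(anyNA(res["gv", ]))
})

test_that("inter-donor consistency filter keeps stable genes only", {
  g <- makeGeometry(30, "grid", seed = 7)
  n <- 30
  set.seed(8)
  stable <- matrix(rnorm(5 * n), 5, n,
                   dimnames = list(paste0("s", 1:5), regionIds(g)))
  donors <- list(d1 = stable, d2 = stable, d3 = stable)
  # append independently shuffled genes
  for (d in names(donors)) {
    shuf <- t(vapply(1:10, function(i) sample(rnorm(n)), numeric(n)))
    rownames(shuf) <- paste0("u", 1:10)
    colnames(shuf) <- regionIds(g)
    donors[[d]] <- rbind(donors[[d]], shuf)
  }
  kept <- filterInconsistentGenes(donors, threshold = 0.1)
  expect_true(all(paste0("s", 1:5) %in% kept))
  expect_gt(sum(!paste0("u", 1:10) %in% kept), 5)

  # threshold -1 keeps everything; single donor is the identity with warning
  expect_setequal(filterInconsistentGenes(donors, threshold = -1),
                  rownames(donors$d1))
  expect_warning(one <- filterInconsistentGenes(donors[1]), "single donor")
  expect_identical(one, rownames(donors$d1))
})

test_that("finalization averages donors and drops subcortical regions", {
  g <- makeGeometry(6, "grid", seed = 9, nSubcortical = 2)
  ids <- regionIds(g)
  d1 <- matrix(0.2, 2, 6, dimnames = list(c("g1", "g2"), ids))
  d2 <- matrix(0.4, 2, 6, dimnames = list(c("g1", "g2"), ids))
  d2[, 6] <- NA  # donor 2 missed the last region
  out <- finalizeMatrix(list(d1, d2), g)
  E <- regionGeneMatrix(out)
  cortIds <- ids[isCortical(g)]
  expect_setequal(rownames(E), cortIds)
  for (rg in cortIds) {
    want <- if (rg == ids[6]) 0.2 else 0.3
    expect_equal(unname(E[rg, "g1"]), want)
  }

  # random 3-donor instance equals the brute-force masked mean
  set.seed(10)
  dl <- lapply(1:3, function(d) {
    m <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), ids))
    m[sample(12, 3)] <- NA
    m
  })
  res <- regionGeneMatrix(finalizeMatrix(dl, g))
  for (rg in rownames(res)) for (gn in colnames(res)) {
    v <- vapply(dl, function(m) m[gn, rg], numeric(1))
    expect_equal(unname(res[rg, gn]), mean(v[!is.na(v)]))
  }
})

test_that("the full preparation pipeline produces a clean cortical matrix", {
  g <- makeGeometry(16, "grid", seed = 11, nSubcortical = 3)
  pm <- makeToyProbes(g, paste0("g", 1:8), rep(2, 8), nDonors = 2, seed = 12)
  expr <- prepExpression(pm, g)
  E <- regionGeneMatrix(expr)
  expect_true(all(rownames(E) %in% regionIds(g)[isCortical(g)]))
  expect_false(anyNA(E))
  expect_true(all(E >= 0 & E <= 1))
})
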