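#' Simulate spatially autocorrelated regional gene expression
#'
#' Each gene's regional profile is drawn from a zero-mean Gaussian field
#' over the region geometry with exponential covariance
#' `exp(-dist/autocorrScale)`; per-donor matrices add independent
#' measurement noise on top of the shared latent profile. This emulates the
#' region-by-gene matrices produced from donor microarray data: genes are
#' spatially smooth, donors agree up to noise.
#'
#' @param geom a [RegionGeometry-class].
#' @param nGenes number of genes.
#' @param autocorrScale spatial correlation length (same units as the
#'   geometry's distances); must be > 0.
#' @param nDonors number of donors (default 1).
#' @param donorNoiseSd SD of donor-specific i.i.d. noise (default 0.3).
#' @param seed integer RNG seed.
#' @return a [RegionExpression-class] with one assay per donor
#'   ("donor1", ...) plus assay "expr" (the donor average) and the latent
#'   noise-free profiles in `metadata(x)$latent` (genes x regions).
#' @export
makeExpression <- function(geom, nGenes, autocorrScale, nDonors = 1L,
                           donorNoiseSd = 0.3, seed = 1L) {
  if (!is.numeric(autocorrScale) || autocorrScale <= 0)
    stop("invalid argument: autocorrScale must be > 0")
  n <- length(geom@regionId)
  genes <- sprintf("G%05d", seq_len(nGenes))
  withSeed(seed, {
    latent <- gaussianField(geom@dist, autocorrScale, nGenes) # regions x genes
    donors <- lapply(seq_len(nDonors), function(d) {
      t(latent + donorNoiseSd * matrix(rnorm(n * nGenes), n, nGenes))
    })
    names(donors) <- paste0("donor", seq_len(nDonors))
    avg <- Reduce(`+`, donors) / nDonors
    assays <- c(list(expr = avg), donors)
    assays <- lapply(assays, function(a) {
      dimnames(a) <- list(genes, geom@regionId); a
    })
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = assays,
      colData = S4Vectors::DataFrame(
        regionId = geom@regionId,
        x = geom@coords[, "x"], y = geom@coords[, "y"], z = geom@coords[, "z"],
        cortical = geom@cortical,
        hemisphere = geom@hemisphere,
        nDonors = rep(nDonors, n),
        row.names = geom@regionId))
    S4Vectors::metadata(se)$latent <- t(`dimnames<-`(latent, list(geom@regionId, genes)))
    S4Vectors::metadata(se)$autocorrScale <- autocorrScale
    new("RegionExpression", se)
  })
}

#' Simulate a subtype atrophy map with planted gene correlates
#'
#' Builds a parcel-level atrophy map as a weighted sum of standardized
#' planted-gene expression profiles plus spatially autocorrelated Gaussian
#' noise, and records the ground truth (planted genes, weights, realized
#' correlations). With a single planted gene of weight w and unit-variance
#' noise field scaled by `noiseSd`, the expected map-gene correlation is
#' w / sqrt(w^2 + noiseSd^2).
#'
#' @param geom a [RegionGeometry-class].
#' @param expr a [RegionExpression-class] containing the planted genes.
#' @param planted named numeric vector: gene id -> weight.
#' @param noiseSd SD of the autocorrelated noise field (0 for noiseless).
#' @param autocorrScale correlation length of the noise field.
#' @param seed integer RNG seed.
#' @param label map label (default "synthetic").
#' @return list with elements `wmap` (a [WMap-class]) and `truth` (list:
#'   plantedGenes, weights, realizedR, noiseSd).
#' @export
makeAtrophy <- function(geom, expr, planted, noiseSd = 0.5,
                        autocorrScale = 1, seed = 1L, label = "synthetic") {
  E <- regionGeneMatrix(expr)
  miss <- setdiff(names(planted), colnames(E))
  if (length(miss))
    stop("missing gene: planted gene(s) not in expression matrix: ",
         paste(miss, collapse = ", "))
  E <- E[geom@regionId, , drop = FALSE]
  withSeed(seed, {
    Z <- scale(E[, names(planted), drop = FALSE])
    signal <- as.vector(Z %*% planted)
    noise <- if (noiseSd > 0) {
      f <- gaussianField(geom@dist, autocorrScale, 1L)
      noiseSd * as.vector(scale(f))
    } else rep(0, nrow(E))
    w <- signal + noise
    wmap <- new("WMap", unitId = geom@regionId, w = w, label = label)
    realized <- corVec(w, E[, names(planted), drop = FALSE])
    list(wmap = wmap,
         truth = list(plantedGenes = names(planted),
                      weights = planted,
                      realizedR = setNames(realized, names(planted)),
                      noiseSd = noiseSd))
  })
}

#' Simulate a control/patient cohort of regional grey-matter values
#'
#' Controls get region baselines plus linear covariate effects plus i.i.d.
#' Gaussian noise; patients additionally lose grey matter in proportion to
#' a supplied atrophy map (tissue loss enters as subtraction, scaled by a
#' per-patient severity factor), so that the W-score sign convention maps
#' atrophy onto positive W.
#'
#' @param geom a [RegionGeometry-class].
#' @param nControls,nPatients cohort sizes.
#' @param covariates named list of covariate specifications. A numeric
#'   covariate is `list(mean=, sd=, beta=)`; a categorical one is
#'   `list(levels=, beta=)` with one beta per non-reference level. Betas
#'   may be scalars (shared across regions) or length-nRegions vectors.
#' @param atrophy a [WMap-class] giving the patients' atrophy pattern
#'   (ignored when `nPatients = 0`).
#' @param severity per-patient severity scalar(s); recycled (default 1).
#' @param noiseSd residual SD of the grey-matter values (default 0.1).
#' @param baseline per-region baseline grey matter (default 1).
#' @param seed integer RNG seed.
#' @return list with `subjects` (data.frame: subjectId, group, covariate
#'   columns, then one column per region) and `truth` (generating betas,
#'   severities, noiseSd).
#' @export
makeCohort <- function(geom, nControls, nPatients, covariates,
                       atrophy = NULL, severity = 1, noiseSd = 0.1,
                       baseline = 1, seed = 1L) {
  nCov <- length(covariates)
  if (nControls < nCov + 2)
    stop("underdetermined model: need nControls >= number of covariates + 2")
  if (nPatients > 0 && is.null(atrophy))
    stop("atrophy map required when nPatients > 0")
  nR <- length(geom@regionId)
  nS <- nControls + nPatients
  baseline <- rep_len(baseline, nR)
  withSeed(seed, {
    covdf <- data.frame(row.names = seq_len(nS))
    effects <- matrix(0, nS, nR)
    betas <- list()
    for (nm in names(covariates)) {
      sp <- covariates[[nm]]
      if (!is.null(sp$levels)) {
        x <- factor(sample(sp$levels, nS, replace = TRUE), levels = sp$levels)
        covdf[[nm]] <- x
        b <- sp$beta
        if (is.null(dim(b))) b <- matrix(rep_len(b, length(sp$levels) - 1), ncol = 1)
        bmat <- matrix(0, length(sp$levels) - 1, nR)
        for (j in seq_len(nrow(bmat))) bmat[j, ] <- rep_len(b[j, ], nR)
        ind <- outer(x, sp$levels[-1], `==`) * 1
        effects <- effects + ind %*% bmat
        betas[[nm]] <- bmat
      } else {
        x <- rnorm(nS, sp$mean, sp$sd)
        covdf[[nm]] <- x
        b <- rep_len(sp$beta, nR)
        effects <- effects + outer(x, b)
        betas[[nm]] <- b
      }
    }
    vals <- matrix(baseline, nS, nR, byrow = TRUE) + effects +
      noiseSd * matrix(rnorm(nS * nR), nS, nR)
    sev <- numeric(0)
    if (nPatients > 0) {
      sev <- rep_len(severity, nPatients)
      a <- wValues(atrophy)[geom@regionId]
      idx <- nControls + seq_len(nPatients)
      vals[idx, ] <- vals[idx, ] - outer(sev, a)
    }
    colnames(vals) <- geom@regionId
    subjects <- cbind(
      data.frame(
        subjectId = sprintf("S%04d", seq_len(nS)),
        group = rep(c("control", "patient"), c(nControls, nPatients)),
        stringsAsFactors = FALSE),
      covdf, as.data.frame(vals))
    list(subjects = subjects,
         truth = list(betas = betas, severity = sev, noiseSd = noiseSd,
                      baseline = baseline))
  })
}

#' Simulate HAR / cryptic-splicing gene labels with tunable overlap
#'
#' Assigns HAR membership by Bernoulli(`fracHar`) draws; cryptic-splicing
#' (CS) membership uses base probability `fracCs`, with the odds multiplied
#' by `overlapEnrichment` for HAR genes, so the generating HAR-by-CS odds
#' ratio equals `overlapEnrichment`.
#'
#' @param genes character vector of gene ids (the background universe).
#' @param fracHar,fracCs marginal membership probabilities in \[0, 1).
#' @param overlapEnrichment odds multiplier for CS membership among HAR
#'   genes (1 = independent lists).
#' @param seed integer RNG seed.
#' @return a [GeneSetCatalog-class] with sets "HAR" and "CS"; the realized
#'   2x2 counts and odds ratio are stored in `metadata` attribute `truth`.
#' @export
makeGeneLists <- function(genes, fracHar, fracCs, overlapEnrichment = 1,
                          seed = 1L) {
  for (f in c(fracHar, fracCs))
    if (!is.numeric(f) || f < 0 || f >= 1)
      stop("invalid argument: fractions must lie in [0, 1)")
  if (overlapEnrichment <= 0)
    stop("invalid argument: overlapEnrichment must be > 0")
  withSeed(seed, {
    har <- rbinom(length(genes), 1, fracHar) == 1
    odds0 <- fracCs / (1 - fracCs)
    odds1 <- odds0 * overlapEnrichment
    p1 <- odds1 / (1 + odds1)
    pcs <- ifelse(har, p1, fracCs)
    cs <- rbinom(length(genes), 1, pcs) == 1
    tab <- table(HAR = har, CS = cs)
    orHat <- if (all(dim(tab) == c(2, 2)) && all(tab > 0))
      (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2]) else NA_real_
    cat <- new("GeneSetCatalog",
               sets = list(HAR = genes[har], CS = genes[cs]),
               background = genes)
    attr(cat, "truth") <- list(counts = tab, oddsRatio = orHat,
                               generatingOdds = overlapEnrichment)
    cat
  })
}

#' Simulate gene DNA sequences with planted GU(GT)-repeat content
#'
#' Sequences are built by i.i.d. single-nucleotide draws interleaved with
#' GT-run insertions: at each step, with per-gene probability `guWeight`, a
#' run of 2-4 GT dinucleotides is appended instead of a single random
#' nucleotide. Planting repeats through run insertion (rather than through
#' motif counts) keeps the generator mechanism independent of the
#' motif-counting code it is used to test.
#'
#' @param geneIds character vector of gene ids.
#' @param lengthRange integer(2): min and max sequence length in nt
#'   (min >= 6 so a hexamer can fit).
#' @param guWeight per-gene GT-run insertion probability; scalar or named
#'   vector over `geneIds`.
#' @param alphabet nucleotides for the background draws (default ACGT).
#' @param seed integer RNG seed.
#' @return a [Biostrings::DNAStringSet] named by gene id.
#' @export
makeSequences <- function(geneIds, lengthRange = c(500L, 2000L),
                          guWeight = 0.02, alphabet = c("A", "C", "G", "T"),
                          seed = 1L) {
  if (lengthRange[1] < 6)
    stop("invalid argument: minimum length must be >= 6 (hexamer must fit)")
  gw <- if (is.null(names(guWeight))) setNames(rep_len(guWeight, length(geneIds)), geneIds)
        else guWeight[geneIds]
  withSeed(seed, {
    seqs <- vapply(geneIds, function(g) {
      target <- sample(seq(lengthRange[1], lengthRange[2]), 1)
      parts <- character(0)
      len <- 0
      while (len < target) {
        if (runif(1) < gw[[g]]) {
          run <- strrep("GT", sample(2:4, 1))
        } else {
          run <- sample(alphabet, 1)
        }
        parts <- c(parts, run)
        len <- len + nchar(run)
      }
      substr(paste(parts, collapse = ""), 1, target)
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, geneIds))
  })
}

#' Simulate a normative seed-connectivity library
#'
#' Each seed region's connectivity map decays exponentially with distance
#' from the seed, `exp(-dist(s, .)/kernelScale)`, plus optional small
#' Gaussian noise; self-connectivity is maximal when noise is 0.
#'
#' @param geom a [RegionGeometry-class].
#' @param nSeeds number of seed regions (<= number of cortical regions);
#'   seeds are sampled among cortical regions under the seed.
#' @param kernelScale connectivity decay length; `Inf` gives constant maps
#'   (degenerate, useful for tie-rule tests).
#' @param noiseSd SD of additive map noise (default 0).
#' @param seed integer RNG seed.
#' @return a [ConnectivityLibrary-class].
#' @export
makeConnectivityLibrary <- function(geom, nSeeds, kernelScale, noiseSd = 0,
                                    seed = 1L) {
  cortIdx <- which(geom@cortical)
  if (nSeeds > length(geom@regionId))
    stop("invalid argument: nSeeds exceeds region count")
  if (nSeeds > length(cortIdx))
    stop("invalid argument: nSeeds exceeds cortical region count")
  withSeed(seed, {
    sIdx <- sort(sample(cortIdx, nSeeds))
    maps <- if (is.infinite(kernelScale))
      matrix(1, nSeeds, length(geom@regionId))
    else
      exp(-geom@dist[sIdx, , drop = FALSE] / kernelScale)
    if (noiseSd > 0)
      maps <- maps + noiseSd * matrix(rnorm(length(maps)), nrow(maps))
    new("ConnectivityLibrary",
        seeds = geom@regionId[sIdx],
        maps = maps,
        regionId = geom@regionId)
  })
}
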