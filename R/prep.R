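#' Construct a ProbeMatrix
#'
#' @param probeId,geneId character vectors, one entry per probe.
#' @param expr numeric probes x samples matrix.
#' @param background logical probes x samples matrix (TRUE = measurement
#'   exceeded background signal).
#' @param samples data.frame with sampleId, donor, x, y, z.
#' @return a [ProbeMatrix-class].
#' @export
ProbeMatrix <- function(probeId, geneId, expr, background, samples) {
  new("ProbeMatrix", probeId = probeId, geneId = geneId,
      expr = as.matrix(expr), background = as.matrix(background),
      samples = as.data.frame(samples))
}

#' Drop probes that do not exceed background signal often enough
#'
#' Keeps probes whose background-exceeded fraction across all samples is
#' strictly greater than 0.5 (a probe at exactly 50% is dropped).
#'
#' @param probes a [ProbeMatrix-class].
#' @return the filtered [ProbeMatrix-class].
#' @export
filterBackground <- function(probes) {
  if (!is.logical(probes@background) || anyNA(probes@background))
    stop("invalid input: background flags missing")
  frac <- rowMeans(probes@background)
  keep <- frac > 0.5
  new("ProbeMatrix",
      probeId = probes@probeId[keep],
      geneId = probes@geneId[keep],
      expr = probes@expr[keep, , drop = FALSE],
      background = probes@background[keep, , drop = FALSE],
      samples = probes@samples)
}

#' Assign tissue samples to the nearest region centroid
#'
#' Each sample is assigned to the nearest region centroid within `maxDist`;
#' samples farther than `maxDist` from every centroid stay unassigned (NA).
#' Left-hemisphere samples are never mirrored to the right.
#'
#' @param samples data.frame with sampleId, x, y, z.
#' @param geom a [RegionGeometry-class].
#' @param maxDist maximum assignment distance; default twice the median
#'   nearest-centroid spacing of the geometry.
#' @return named character vector: sampleId -> region id (NA = unassigned).
#' @export
assignSamplesToParcels <- function(samples, geom, maxDist = NULL) {
  if (is.null(maxDist)) {
    nn <- apply(geom@dist + diag(Inf, nrow(geom@dist)), 1, min)
    maxDist <- 2 * median(nn)
  }
  sc <- as.matrix(samples[, c("x", "y", "z")])
  out <- vapply(seq_len(nrow(sc)), function(i) {
    d <- sqrt(colSums((t(geom@coords) - sc[i, ])^2))
    j <- which.min(d)
    if (d[j] <= maxDist) geom@regionId[j] else NA_character_
  }, character(1))
  setNames(out, samples$sampleId)
}

# Per-donor gene (or probe) x region matrix of mean expression; NA where a
# donor contributed no sample to a region.
regionProfiles <- function(values, samples, assignment, geom) {
  donors <- unique(samples$donor)
  reg <- assignment[samples$sampleId]
  lapply(setNames(donors, donors), function(d) {
    out <- matrix(NA_real_, nrow(values), length(geom@regionId),
                  dimnames = list(rownames(values), geom@regionId))
    sel <- samples$donor == d & !is.na(reg)
    if (any(sel)) {
      sub <- values[, sel, drop = FALSE]
      g <- factor(reg[sel], levels = geom@regionId)
      for (lv in levels(g)[tabulate(g) > 0])
        out[, lv] <- rowMeans(sub[, g == lv, drop = FALSE])
    }
    out
  })
}

# Differential stability of each row of a profile list: mean, over donor
# pairs, of the Spearman correlation of the row's regional profiles over
# regions covered by both donors. Undefined correlations (constant
# profiles, < 3 shared regions) contribute -Inf so such rows never win a
# probe-selection contest.
differentialStability <- function(profiles) {
  nd <- length(profiles)
  nr <- nrow(profiles[[1]])
  if (nd < 2) return(rep(NA_real_, nr))
  ds <- numeric(nr)
  for (i in seq_len(nr)) {
    cors <- c()
    for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
      pa <- profiles[[a]][i, ]; pb <- profiles[[b]][i, ]
      ok <- !is.na(pa) & !is.na(pb)
      if (sum(ok) >= 3 && sd(pa[ok]) > 0 && sd(pb[ok]) > 0)
        cors <- c(cors, cor(pa[ok], pb[ok], method = "spearman"))
      else
        cors <- c(cors, -Inf)
    }
    ds[i] <- mean(cors)
  }
  ds
}

#' Collapse probes to one representative measure per gene
#'
#' For genes indexed by multiple probes, selects the probe with the highest
#' differential stability: the mean, across donor pairs, of the Spearman
#' correlation between the probe's regional expression profiles.
#' Single-probe genes pass through. With a single donor no pairs exist and
#' the probe with the largest regional variance is selected instead.
#'
#' @param probes a background-filtered [ProbeMatrix-class].
#' @param assignment sample -> region map from [assignSamplesToParcels()].
#' @param geom a [RegionGeometry-class].
#' @return numeric gene x sample matrix.
#' @export
collapseProbes <- function(probes, assignment, geom) {
  expr <- probes@expr
  rownames(expr) <- probes@probeId
  genes <- unique(probes@geneId)
  profiles <- regionProfiles(expr, probes@samples, assignment, geom)
  multiDonor <- length(profiles) >= 2
  ds <- if (multiDonor) differentialStability(profiles) else {
    # single donor: fall back to regional variance
    apply(profiles[[1]], 1, function(p) {
      p <- p[!is.na(p)]
      if (length(p) < 2) -Inf else var(p)
    })
  }
  pick <- vapply(genes, function(g) {
    idx <- which(probes@geneId == g)
    if (length(idx) == 1) idx else idx[which.max(ds[idx])]
  }, integer(1))
  out <- expr[pick, , drop = FALSE]
  rownames(out) <- genes
  colnames(out) <- probes@samples$sampleId
  out
}

#' Normalize expression within donors (scaled robust sigmoid)
#'
#' For each gene within each donor, applies the scaled robust sigmoid
#' x' = 1 / (1 + exp(-(x - median) / (IQR / 1.35))) followed by a min-max
#' rescale to \[0, 1\] over that donor's samples. The transform is invariant
#' to positive affine rescalings of the input. Genes with zero IQR in a
#' donor are set to NA for that donor; a gene constant in every donor is
#' flagged with a warning. A per-gene z-score alternative is available via
#' `method = "zscore"`.
#'
#' @param mat numeric gene x sample matrix.
#' @param donor character/factor donor label per sample (column).
#' @param method "srs" (default, scaled robust sigmoid) or "zscore".
#' @return normalized matrix of the same shape (NA for dropped gene-donor
#'   combinations).
#' @export
normalizeExpression <- function(mat, donor, method = c("srs", "zscore")) {
  method <- match.arg(method)
  out <- mat
  for (d in unique(donor)) {
    cols <- which(donor == d)
    sub <- mat[, cols, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      x <- sub[i, ]
      if (method == "srs") {
        iqr <- IQR(x)
        if (iqr == 0) { out[i, cols] <- NA_real_; next }
        y <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
        out[i, cols] <- (y - min(y)) / (max(y) - min(y))
      } else {
        s <- sd(x)
        if (s == 0) { out[i, cols] <- NA_real_; next }
        out[i, cols] <- (x - mean(x)) / s
      }
    }
  }
  allNA <- rowSums(!is.na(out)) == 0
  if (any(allNA))
    warning("gene(s) constant in all donors: ",
            paste(rownames(mat)[allNA], collapse = ", "))
  out
}

#' Filter genes inconsistently expressed across donors
#'
#' Keeps genes whose differential stability — the mean pairwise inter-donor
#' Spearman correlation of regional profiles over shared regions — is
#' strictly greater than `threshold`. With a single donor the filter is the
#' identity (no pairs) and a warning is issued.
#'
#' @param donorProfiles list (one per donor) of gene x region matrices, as
#'   produced internally by [prepExpression()]; NA marks regions without
#'   samples for that donor.
#' @param threshold stability cutoff (default 0.1).
#' @return character vector of retained gene ids.
#' @export
filterInconsistentGenes <- function(donorProfiles, threshold = 0.1) {
  genes <- rownames(donorProfiles[[1]])
  if (length(donorProfiles) < 2) {
    warning("single donor: stability filter is the identity")
    return(genes)
  }
  ds <- differentialStability(donorProfiles)
  genes[ds > threshold]
}

#' Average donor profiles into the final region x gene matrix
#'
#' Region value = mean over donors contributing at least one sample to that
#' region. Subcortical regions and regions with no samples from any donor
#' are removed.
#'
#' @param donorProfiles list of gene x region matrices (NA = no samples).
#' @param geom a [RegionGeometry-class].
#' @return a [RegionExpression-class] (assay "expr", genes x regions).
#' @export
finalizeMatrix <- function(donorProfiles, geom) {
  arr <- simplify2array(donorProfiles)  # genes x regions x donors
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  avg <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  dimnames(avg) <- dimnames(donorProfiles[[1]])
  covered <- colSums(!is.na(avg)) > 0
  keep <- covered & geom@cortical[match(colnames(avg), geom@regionId)]
  avg <- avg[, keep, drop = FALSE]
  if (ncol(avg) == 0 || nrow(avg) == 0) stop("no data after finalization")
  nDon <- apply(simplify2array(lapply(donorProfiles, function(p)
    colSums(!is.na(p)) > 0)), 1, sum)[keep]
  g2 <- subsetGeometry(geom, colnames(avg))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = avg),
    colData = S4Vectors::DataFrame(
      regionId = g2@regionId,
      x = g2@coords[, "x"], y = g2@coords[, "y"], z = g2@coords[, "z"],
      cortical = g2@cortical, hemisphere = g2@hemisphere,
      nDonors = as.integer(nDon), row.names = g2@regionId))
  new("RegionExpression", se)
}

#' Run the full expression-preparation pipeline
#'
#' Chains background filtering, probe collapse (differential stability),
#' sample-to-parcel assignment, within-donor normalization, inter-donor
#' consistency filtering and donor averaging into the final cortical
#' region x gene matrix.
#'
#' @param probes a [ProbeMatrix-class].
#' @param geom a [RegionGeometry-class].
#' @param maxDist see [assignSamplesToParcels()].
#' @param stabilityThreshold see [filterInconsistentGenes()].
#' @param method normalization method, see [normalizeExpression()].
#' @return a [RegionExpression-class].
#' @export
prepExpression <- function(probes, geom, maxDist = NULL,
                           stabilityThreshold = 0.1, method = "srs") {
  probes <- filterBackground(probes)
  assignment <- assignSamplesToParcels(probes@samples, geom, maxDist)
  gs <- collapseProbes(probes, assignment, geom)
  norm <- normalizeExpression(gs, probes@samples$donor, method = method)
  norm <- norm[rowSums(!is.na(norm)) > 0, , drop = FALSE]
  donorProfiles <- regionProfiles(norm, probes@samples, assignment, geom)
  keep <- suppressWarnings(filterInconsistentGenes(donorProfiles,
                                                   stabilityThreshold))
  donorProfiles <- lapply(donorProfiles, function(p) p[keep, , drop = FALSE])
  finalizeMatrix(donorProfiles, geom)
}
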