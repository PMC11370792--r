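#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor coef dist lm.fit mad median model.matrix p.adjust
#'   phyper quantile rbinom rnorm runif sd setNames var wilcox.test
#'   chisq.test IQR ks.test
#' @importFrom utils head read.delim write.table
NULL

#' RegionGeometry: parcellated brain geometry
#'
#' Holds the abstract geometry of a brain parcellation: one point (centroid)
#' per region, the pairwise Euclidean distance matrix, and per-region
#' metadata (cortical flag, hemisphere). All spatial operations in the
#' package (Gaussian-field simulation, variogram estimation, surrogate
#' generation, connectivity kernels) are defined on this object.
#'
#' @slot regionId character vector of unique region identifiers.
#' @slot coords numeric matrix (regions x 3) of centroid coordinates,
#'   arbitrary units.
#' @slot dist symmetric numeric matrix of pairwise Euclidean distances with
#'   zero diagonal and strictly positive off-diagonal entries.
#' @slot cortical logical vector; FALSE marks subcortical regions, which the
#'   expression-preparation step removes.
#' @slot hemisphere character vector, "L" or "R" per region.
#'
#' @seealso [makeGeometry()]
#' @export
setClass("RegionGeometry",
  representation(
    regionId = "character",
    coords = "matrix",
    dist = "matrix",
    cortical = "logical",
    hemisphere = "character"
  )
)

setValidity("RegionGeometry", function(object) {
  n <- length(object@regionId)
  msg <- character()
  if (anyDuplicated(object@regionId)) msg <- c(msg, "duplicated region ids")
  if (nrow(object@coords) != n) msg <- c(msg, "coords row count != region count")
  if (!all(dim(object@dist) == c(n, n))) msg <- c(msg, "dist dims != region count")
  if (length(object@cortical) != n) msg <- c(msg, "cortical length != region count")
  if (length(object@hemisphere) != n) msg <- c(msg, "hemisphere length != region count")
  if (!all(object@hemisphere %in% c("L", "R")))
    msg <- c(msg, "hemisphere entries must be 'L' or 'R'")
  if (n > 0) {
    if (max(abs(object@dist - t(object@dist))) > 1e-8)
      msg <- c(msg, "dist must be symmetric")
    if (any(abs(diag(object@dist)) > 1e-12))
      msg <- c(msg, "dist diagonal must be zero")
    off <- object@dist[upper.tri(object@dist)]
    if (length(off) && any(off <= 0))
      msg <- c(msg, "off-diagonal distances must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' RegionExpression: region-by-gene expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with genes in rows and
#' regions (parcels) in columns. Region metadata (coordinates, cortical
#' flag, hemisphere, donor coverage) lives in `colData`. Multiple assays
#' hold donor-level matrices where relevant; assay "expr" is the
#' donor-averaged matrix used in all downstream analyses.
#'
#' @seealso [makeExpression()], [regionGeneMatrix()], [finalizeMatrix()]
#' @export
setClass("RegionExpression", contains = "SummarizedExperiment")

#' ProbeMatrix: donor-level microarray probe data
#'
#' Probe-by-sample expression with per-probe gene annotation, a
#' probe-by-sample background-exceeded indicator, and per-sample metadata
#' (donor, spatial coordinates). Input to the expression-preparation
#' pipeline.
#'
#' @slot probeId character, unique probe identifiers.
#' @slot geneId character, gene annotation per probe (one gene per probe).
#' @slot expr numeric matrix, probes x samples.
#' @slot background logical matrix, probes x samples; TRUE where the
#'   measurement exceeded background signal.
#' @slot samples data.frame with columns sampleId, donor, x, y, z.
#'
#' @export
setClass("ProbeMatrix",
  representation(
    probeId = "character",
    geneId = "character",
    expr = "matrix",
    background = "matrix",
    samples = "data.frame"
  )
)

setValidity("ProbeMatrix", function(object) {
  msg <- character()
  np <- length(object@probeId)
  if (anyDuplicated(object@probeId)) msg <- c(msg, "duplicated probe ids")
  if (length(object@geneId) != np) msg <- c(msg, "geneId length != probe count")
  if (nrow(object@expr) != np) msg <- c(msg, "expr rows != probe count")
  if (!identical(dim(object@expr), dim(object@background)))
    msg <- c(msg, "expr and background dims differ")
  need <- c("sampleId", "donor", "x", "y", "z")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, "samples must have sampleId, donor, x, y, z")
  else if (nrow(object@samples) != ncol(object@expr))
    msg <- c(msg, "sample rows != expr columns")
  if (length(msg)) msg else TRUE
})

#' WMap: per-unit atrophy W-scores
#'
#' A W-score map for one subject or a group average: a covariate-adjusted,
#' z-like atrophy score per unit (voxel or parcel). Under the package's
#' default sign convention higher W means more severe atrophy (less grey
#' matter than expected).
#'
#' @slot unitId character, voxel or parcel identifiers.
#' @slot w numeric, finite W-score per unit.
#' @slot label character(1), subject or group label.
#'
#' @seealso [computeWMap()], [aggregateToParcels()], [groupAverage()]
#' @export
setClass("WMap",
  representation(unitId = "character", w = "numeric", label = "character")
)

setValidity("WMap", function(object) {
  msg <- character()
  if (length(object@unitId) != length(object@w))
    msg <- c(msg, "unitId and w lengths differ")
  if (anyDuplicated(object@unitId)) msg <- c(msg, "duplicated unit ids")
  if (length(object@w) && !all(is.finite(object@w)))
    msg <- c(msg, "W values must be finite")
  if (length(object@label) != 1) msg <- c(msg, "label must be length 1")
  if (length(msg)) msg else TRUE
})

#' ControlModel: normative covariate model for W-scores
#'
#' Per-unit ordinary-least-squares fit of grey-matter values on a covariate
#' design, estimated on healthy controls. Stores the coefficient matrix,
#' the residual standard deviation per unit, and the covariate schema
#' needed to rebuild the design matrix for new subjects.
#'
#' @slot units character, unit ids retained by the model.
#' @slot coefficients numeric matrix, (intercept + covariate terms) x units.
#' @slot sde numeric, residual standard deviation per retained unit
#'   (denominator n - p - 1 for p covariate terms).
#' @slot covariates character, covariate column names in the subject table.
#' @slot xlevels list, factor levels per categorical covariate (first level
#'   is the reference of the one-hot encoding).
#' @slot degenerate character, unit ids excluded because their residual SD
#'   was zero.
#'
#' @seealso [fitControlModel()], [computeWMap()]
#' @export
setClass("ControlModel",
  representation(
    units = "character",
    coefficients = "matrix",
    sde = "numeric",
    covariates = "character",
    xlevels = "list",
    degenerate = "character"
  )
)

setValidity("ControlModel", function(object) {
  msg <- character()
  if (ncol(object@coefficients) != length(object@units))
    msg <- c(msg, "coefficient columns != unit count")
  if (length(object@sde) != length(object@units))
    msg <- c(msg, "sde length != unit count")
  if (length(object@sde) && any(object@sde <= 0))
    msg <- c(msg, "sde must be > 0 for every retained unit")
  if (length(msg)) msg else TRUE
})

#' SurrogateEnsemble: autocorrelation-matched null maps
#'
#' B surrogate maps generated from one source map so that each surrogate
#' approximately preserves the source's spatial variogram, used as the null
#' for map-gene correlation tests.
#'
#' @slot maps numeric matrix, B x regions; one surrogate per row.
#' @slot source numeric, the source map.
#' @slot regionId character, region ids (columns of `maps`).
#' @slot seed integer(1), RNG seed that produced the ensemble.
#' @slot fit data.frame of per-surrogate diagnostics (chosen kernel scale,
#'   smoothing/noise weights, variogram fit error).
#'
#' @seealso [generateSurrogates()], [surrogatePValues()]
#' @export
setClass("SurrogateEnsemble",
  representation(
    maps = "matrix",
    source = "numeric",
    regionId = "character",
    seed = "integer",
    fit = "data.frame"
  )
)

setValidity("SurrogateEnsemble", function(object) {
  msg <- character()
  if (nrow(object@maps) < 1) msg <- c(msg, "ensemble must contain >= 1 surrogate")
  if (ncol(object@maps) != length(object@source))
    msg <- c(msg, "surrogate length != source length")
  if (length(object@regionId) != length(object@source))
    msg <- c(msg, "regionId length != source length")
  if (length(msg)) msg else TRUE
})

#' GeneSetCatalog: named gene sets over a background universe
#'
#' Named gene sets (HAR genes, cryptic-splicing genes, high-GU genes,
#' atrophy-correlated genes per subtype, ...) together with the background
#' universe they are drawn from (by default the brain-expressed gene list).
#' Every set must be a subset of the background.
#'
#' @slot sets named list of character vectors.
#' @slot background character, the universe; no duplicates.
#'
#' @seealso [makeGeneLists()], [fisherOverlap()], [oraCollections()]
#' @export
setClass("GeneSetCatalog",
  representation(sets = "list", background = "character")
)

setValidity("GeneSetCatalog", function(object) {
  msg <- character()
  if (anyDuplicated(object@background)) msg <- c(msg, "background has duplicates")
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || any(names(object@sets) == ""))
      msg <- c(msg, "all sets must be named")
    bad <- vapply(object@sets, function(s) !all(s %in% object@background), logical(1))
    if (any(bad))
      msg <- c(msg, paste("sets not contained in background:",
                          paste(names(object@sets)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityLibrary: normative seed-connectivity maps
#'
#' A library of region-wise connectivity maps, one per seed region,
#' emulating normative task-free functional connectivity. Used to assign
#' each patient a best-fit disease epicentre.
#'
#' @slot seeds character, seed region ids (subset of regionId).
#' @slot maps numeric matrix, seeds x regions; row s is seed s's map.
#' @slot regionId character, region ids (columns of `maps`).
#'
#' @seealso [makeConnectivityLibrary()], [findEpicentre()]
#' @export
setClass("ConnectivityLibrary",
  representation(seeds = "character", maps = "matrix", regionId = "character")
)

setValidity("ConnectivityLibrary", function(object) {
  msg <- character()
  if (nrow(object@maps) != length(object@seeds))
    msg <- c(msg, "map rows != seed count")
  if (ncol(object@maps) != length(object@regionId))
    msg <- c(msg, "map columns != region count")
  if (!all(object@seeds %in% object@regionId))
    msg <- c(msg, "seeds must be a subset of region ids")
  if (length(msg)) msg else TRUE
})

#' CoexpressionGraph: thresholded gene co-expression network
#'
#' Gene-gene Pearson correlations over regions, binarized at a threshold
#' (edge iff r strictly above the threshold, no self-loops), with nodal
#' degree per gene.
#'
#' @slot genes character, node (gene) ids.
#' @slot r numeric matrix, gene x gene Pearson correlations (diagonal 1).
#' @slot theta numeric(1), binarization threshold (default 0.3).
#' @slot adjacency matrix of 0/1, symmetric, zero diagonal.
#' @slot degree numeric, edges per node.
#' @slot absolute logical(1), TRUE if |r| was thresholded.
#'
#' @seealso [coexpressionMatrix()], [binarizeAndDegree()]
#' @export
setClass("CoexpressionGraph",
  representation(
    genes = "character",
    r = "matrix",
    theta = "numeric",
    adjacency = "matrix",
    degree = "numeric",
    absolute = "logical"
  )
)

setValidity("CoexpressionGraph", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (!all(dim(object@adjacency) == c(n, n))) msg <- c(msg, "adjacency dims")
  else {
    if (max(abs(object@adjacency - t(object@adjacency))) > 0)
      msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(object@adjacency) != 0)) msg <- c(msg, "self-loops present")
    if (!isTRUE(all.equal(unname(object@degree), unname(rowSums(object@adjacency)))))
      msg <- c(msg, "degree must equal adjacency row sums")
  }
  if (length(msg)) msg else TRUE
})
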