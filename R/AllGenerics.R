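#' @rdname RegionGeometry-class
#' @param x,object an object.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname RegionGeometry-class
#' @export
setGeneric("regionDist", function(x) standardGeneric("regionDist"))

#' @rdname RegionGeometry-class
#' @export
setGeneric("regionCoords", function(x) standardGeneric("regionCoords"))

#' @rdname RegionGeometry-class
#' @export
setGeneric("isCortical", function(x) standardGeneric("isCortical"))

#' @rdname RegionGeometry-class
#' @export
setMethod("regionIds", "RegionGeometry", function(x) x@regionId)

#' @rdname RegionGeometry-class
#' @export
setMethod("regionDist", "RegionGeometry", function(x) x@dist)

#' @rdname RegionGeometry-class
#' @export
setMethod("regionCoords", "RegionGeometry", function(x) x@coords)

#' @rdname RegionGeometry-class
#' @export
setMethod("isCortical", "RegionGeometry", function(x) x@cortical)

#' @export
setMethod("show", "RegionGeometry", function(object) {
  cat("RegionGeometry with", length(object@regionId), "regions",
      sprintf("(%d cortical, %d L / %d R)\n",
              sum(object@cortical),
              sum(object@hemisphere == "L"),
              sum(object@hemisphere == "R")))
})

#' Extract the regions x genes expression matrix
#'
#' Returns the expression values of a [RegionExpression-class] object as a
#' numeric matrix with regions in rows and genes in columns — the
#' orientation used by the spatial-correlation machinery.
#'
#' @param x a `RegionExpression`.
#' @param assay assay name or index (default "expr", the donor average).
#' @return numeric matrix, regions x genes, with region ids as row names.
#' @export
regionGeneMatrix <- function(x, assay = "expr") {
  t(SummarizedExperiment::assay(x, assay))
}

#' @rdname WMap-class
#' @param x a `WMap`.
#' @export
wValues <- function(x) setNames(x@w, x@unitId)

#' @rdname WMap-class
#' @export
wLabel <- function(x) x@label

#' @export
setMethod("show", "WMap", function(object) {
  cat("WMap '", object@label, "': ", length(object@w), " units, mean W = ",
      sprintf("%.3f", mean(object@w)), "\n", sep = "")
})

#' @export
setMethod("show", "ControlModel", function(object) {
  cat("ControlModel:", length(object@units), "units,",
      nrow(object@coefficients), "design terms;",
      length(object@degenerate), "degenerate unit(s) excluded\n")
})

#' @rdname SurrogateEnsemble-class
#' @param x a `SurrogateEnsemble`.
#' @export
surrogateMaps <- function(x) x@maps

#' @export
setMethod("show", "SurrogateEnsemble", function(object) {
  cat("SurrogateEnsemble:", nrow(object@maps), "surrogates over",
      ncol(object@maps), "regions (seed", object@seed, ")\n")
})

#' @rdname GeneSetCatalog-class
#' @param x a `GeneSetCatalog`.
#' @param name set name.
#' @export
geneSet <- function(x, name) {
  if (!name %in% names(x@sets)) stop("unknown gene set: ", name)
  x@sets[[name]]
}

#' @rdname GeneSetCatalog-class
#' @export
geneSets <- function(x) x@sets

#' @rdname GeneSetCatalog-class
#' @export
setBackground <- function(x) x@background

#' @export
setMethod("show", "GeneSetCatalog", function(object) {
  cat("GeneSetCatalog:", length(object@sets), "sets over a background of",
      length(object@background), "genes\n")
  for (nm in names(object@sets))
    cat("  ", nm, ": ", length(object@sets[[nm]]), " genes\n", sep = "")
})

#' @rdname ConnectivityLibrary-class
#' @param x a `ConnectivityLibrary`.
#' @export
librarySeeds <- function(x) x@seeds

#' @rdname ConnectivityLibrary-class
#' @export
seedMaps <- function(x) x@maps

#' @export
setMethod("show", "ConnectivityLibrary", function(object) {
  cat("ConnectivityLibrary:", length(object@seeds), "seed maps over",
      length(object@regionId), "regions\n")
})

#' @rdname CoexpressionGraph-class
#' @param x a `CoexpressionGraph`.
#' @export
nodalDegree <- function(x) setNames(x@degree, x@genes)

#' @rdname CoexpressionGraph-class
#' @export
graphAdjacency <- function(x) x@adjacency

#' @export
setMethod("show", "CoexpressionGraph", function(object) {
  cat("CoexpressionGraph:", length(object@genes), "genes,",
      sum(object@adjacency) / 2, "edges at",
      if (object@absolute) "|r| >" else "r >", object@theta, "\n")
})
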