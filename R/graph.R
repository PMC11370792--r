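#' Gene-to-gene regional co-expression matrix
#'
#' Pairwise Pearson correlation of the selected genes' regional expression
#' profiles. Genes with constant regional expression have undefined
#' correlations and are dropped with a warning.
#'
#' @param expr a [RegionExpression-class] or regions x genes matrix.
#' @param genes character gene subset; all must be present.
#' @return gene x gene correlation matrix with unit diagonal.
#' @export
coexpressionMatrix <- function(expr, genes) {
  E <- if (is(expr, "RegionExpression")) regionGeneMatrix(expr) else expr
  miss <- setdiff(genes, colnames(E))
  if (length(miss)) stop("genes absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  if (nrow(E) < 3) stop("need >= 3 regions")
  E <- E[, genes, drop = FALSE]
  v <- apply(E, 2, sd)
  if (any(v == 0)) {
    warning("constant gene(s) dropped: ",
            paste(colnames(E)[v == 0], collapse = ", "))
    E <- E[, v > 0, drop = FALSE]
  }
  R <- cor(E)
  diag(R) <- 1
  R
}

#' Binarize a co-expression matrix and compute nodal degree
#'
#' An undirected edge connects two genes iff their correlation is strictly
#' above the threshold (default r > 0.3 on the signed correlation; set
#' `absolute = TRUE` to threshold |r|). Self-loops are excluded. Nodal
#' degree counts the surviving edges per gene.
#'
#' @param r square symmetric correlation matrix.
#' @param theta binarization threshold (default 0.3).
#' @param absolute threshold |r| instead of signed r (default FALSE).
#' @return a [CoexpressionGraph-class].
#' @export
binarizeAndDegree <- function(r, theta = 0.3, absolute = FALSE) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop("invalid input: need a square matrix")
  if (max(abs(r - t(r))) > 1e-8)
    stop("invalid input: matrix not symmetric")
  genes <- if (!is.null(rownames(r))) rownames(r) else paste0("g", seq_len(nrow(r)))
  val <- if (absolute) abs(r) else r
  A <- (val > theta) * 1
  diag(A) <- 0
  new("CoexpressionGraph",
      genes = genes, r = r, theta = theta,
      adjacency = A, degree = rowSums(A), absolute = absolute)
}

#' Edge list of a co-expression graph
#'
#' @param graph a [CoexpressionGraph-class].
#' @return data.frame: geneA, geneB, r (one row per undirected edge).
#' @export
graphEdges <- function(graph) {
  idx <- which(upper.tri(graph@adjacency) & graph@adjacency == 1,
               arr.ind = TRUE)
  data.frame(geneA = graph@genes[idx[, 1]],
             geneB = graph@genes[idx[, 2]],
             r = graph@r[idx],
             stringsAsFactors = FALSE)
}

#' Convert a co-expression graph to igraph
#'
#' @param graph a [CoexpressionGraph-class].
#' @return an igraph object (requires the igraph package).
#' @export
asIgraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for asIgraph()")
  ig <- igraph::graph_from_adjacency_matrix(graph@adjacency, mode = "undirected")
  igraph::set_vertex_attr(ig, "name", value = graph@genes)
}
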