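#' Assign a patient's best-fit disease epicentre
#'
#' The epicentre is the seed region whose normative connectivity map shows
#' the highest Pearson correlation with the patient's parcel-level atrophy
#' W-map. Ties are broken by the lowest seed index (library order). A
#' constant W-map has no defined correlation and returns an NA epicentre
#' sentinel. The assignment is invariant to positive affine rescalings of
#' the W-map.
#'
#' @param wmap a [WMap-class] at parcel level.
#' @param library a [ConnectivityLibrary-class] over the same regions.
#' @param subtype optional subtype label to record.
#' @return one-row data.frame: patient, subtype, epicentre, fitR.
#' @export
findEpicentre <- function(wmap, library, subtype = NA_character_) {
  w <- wValues(wmap)
  shared <- intersect(names(w), library@regionId)
  if (length(shared) < 3) stop("insufficient overlap with library regions")
  w <- w[shared]
  M <- library@maps[, match(shared, library@regionId), drop = FALSE]
  if (sd(w) == 0) {
    warning("constant W-map: no epicentre")
    return(data.frame(patient = wmap@label, subtype = subtype,
                      epicentre = NA_character_, fitR = NA_real_,
                      stringsAsFactors = FALSE))
  }
  # constant seed maps yield NA correlations (cor warns); they cannot win
  r <- as.vector(suppressWarnings(cor(w, t(M))))
  r[is.na(r)] <- -Inf
  best <- which.max(r)  # which.max returns the first (lowest-index) maximum
  data.frame(patient = wmap@label, subtype = subtype,
             epicentre = library@seeds[best], fitR = r[best],
             stringsAsFactors = FALSE)
}

#' Epicentre assignments for a list of patient W-maps
#'
#' @param wmaps list of [WMap-class].
#' @param library a [ConnectivityLibrary-class].
#' @param subtypes subtype label(s), recycled over patients.
#' @return data.frame with one row per patient.
#' @export
findEpicentres <- function(wmaps, library, subtypes = NA_character_) {
  subtypes <- rep_len(subtypes, length(wmaps))
  do.call(rbind, lapply(seq_along(wmaps), function(i)
    findEpicentre(wmaps[[i]], library, subtypes[i])))
}

#' Per-subtype epicentre frequency maps and unique/shared partition
#'
#' Tallies how often each seed is selected as epicentre within each
#' subtype (frequency = count / subtype size), classifies each used seed
#' as unique to one subtype or shared across subtypes, and reports
#' patient-level unique/shared tallies.
#'
#' @param assignments data.frame from [findEpicentres()] with columns
#'   subtype and epicentre.
#' @return list: `frequency` (data.frame subtype, epicentre, count, freq),
#'   `seedClass` (named character "unique"/"shared" per used seed),
#'   `patientTally` (data.frame subtype, nUnique, nShared).
#' @export
epicentreFrequency <- function(assignments) {
  a <- assignments[!is.na(assignments$epicentre), , drop = FALSE]
  if (!nrow(a)) stop("invalid argument: no assignments")
  tab <- as.data.frame(table(subtype = a$subtype, epicentre = a$epicentre),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  nSub <- table(a$subtype)
  tab$freq <- tab$count / as.numeric(nSub[tab$subtype])
  usedBy <- tapply(tab$subtype, tab$epicentre,
                   function(s) length(unique(s)))
  seedClass <- ifelse(usedBy > 1, "shared", "unique")
  a$class <- seedClass[a$epicentre]
  tally <- do.call(rbind, lapply(split(a, a$subtype), function(d)
    data.frame(subtype = d$subtype[1],
               nUnique = sum(d$class == "unique"),
               nShared = sum(d$class == "shared"),
               stringsAsFactors = FALSE)))
  rownames(tally) <- NULL
  rownames(tab) <- NULL
  list(frequency = tab,
       seedClass = setNames(as.character(seedClass), names(usedBy)),
       patientTally = tally)
}

#' Compare gene expression at disease epicentres across two subtypes
#'
#' For each gene, collects its regional expression value at every
#' patient's assigned epicentre, per subtype, and compares the two samples
#' with a rank-based test. The default is the unpaired rank-sum
#' (Mann-Whitney) test with exact small-sample p-values; a signed-rank
#' mode (requiring equal group sizes, pairing patients by rank order of
#' their values) is available for strict replication of paired-style
#' analyses. The cross-fold change is mean(group A) / mean(group B)
#' (NA sentinel when the denominator is 0); p-values are
#' Benjamini-Hochberg adjusted across genes.
#'
#' @param genes character gene set.
#' @param assignments data.frame from [findEpicentres()] with columns
#'   subtype and epicentre.
#' @param expr a [RegionExpression-class] or regions x genes matrix.
#' @param groups character(2): the two subtype labels to compare (A, B).
#' @param test "ranksum" (default) or "signedrank".
#' @return data.frame: gene, foldChange, p, pFdr; one row per gene.
#' @export
compareEpicentreExpression <- function(genes, assignments, expr,
                                       groups,
                                       test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  E <- if (is(expr, "RegionExpression")) regionGeneMatrix(expr) else expr
  miss <- setdiff(genes, colnames(E))
  if (length(miss)) stop("genes absent from expression matrix")
  epiA <- assignments$epicentre[assignments$subtype == groups[1]]
  epiB <- assignments$epicentre[assignments$subtype == groups[2]]
  epiA <- epiA[!is.na(epiA)]; epiB <- epiB[!is.na(epiB)]
  if (length(epiA) < 2 || length(epiB) < 2)
    stop("insufficient sample: each subtype needs >= 2 assignments")
  if (test == "signedrank" && length(epiA) != length(epiB))
    stop("signed-rank mode requires equal group sizes")
  res <- lapply(genes, function(g) {
    xa <- E[epiA, g]; xb <- E[epiB, g]
    p <- if (test == "ranksum") {
      suppressWarnings(wilcox.test(xa, xb, exact = TRUE)$p.value)
    } else {
      suppressWarnings(wilcox.test(sort(xa), sort(xb), paired = TRUE,
                                   exact = TRUE)$p.value)
    }
    fc <- if (mean(xb) == 0) NA_real_ else mean(xa) / mean(xb)
    data.frame(gene = g, foldChange = fc, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$pFdr <- p.adjust(tab$p, method = "BH")
  tab
}
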