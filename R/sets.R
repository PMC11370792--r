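#' Venn partition of gene sets into unique and shared counts
#'
#' Exact inclusion-exclusion partition over membership patterns: every gene
#' in the union is counted once, under the combination of set names it
#' belongs to (names joined by "&"). Counts sum to the union size and are
#' invariant to input order.
#'
#' @param sets named list of >= 2 character vectors.
#' @return named integer vector over non-empty membership patterns.
#' @examples
#' partitionUniqueShared(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
partitionUniqueShared <- function(sets) {
  if (length(sets) < 2) stop("invalid argument: need >= 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("S", seq_along(sets))
  universe <- unique(unlist(sets))
  if (!length(universe)) return(setNames(integer(0), character(0)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(NULL, names(sets)))
  # canonical pattern names: set names sorted, so the result is order-invariant
  pat <- apply(memb, 1, function(m) paste(sort(names(sets)[m]), collapse = "&"))
  counts <- table(pat)
  setNames(as.integer(counts), names(counts))
}

#' Uniqueness index of a three-way gene-set partition
#'
#' U = (sum of single-set unique counts) / (sum of all shared counts,
#' pairwise and triple). When no gene is shared the index is undefined and
#' `NA` is returned as a sentinel (never +Inf).
#'
#' @param partition named counts from [partitionUniqueShared()] over three
#'   sets, or a named list of three sets.
#' @return numeric U, or NA when the denominator is zero.
#' @export
uniquenessIndex <- function(partition) {
  if (is.list(partition)) {
    if (length(partition) != 3) stop("need a three-set partition")
    partition <- partitionUniqueShared(partition)
  }
  single <- !grepl("&", names(partition))
  num <- sum(partition[single])
  den <- sum(partition[!single])
  if (den == 0) return(NA_real_)
  num / den
}

#' Sweep the |r| threshold and compute the uniqueness index
#'
#' Re-applies the gene selection rule at every threshold in `tauGrid`
#' (selected iff pFdr < alpha and |r| >= tau), partitions the selected sets
#' into unique and shared counts, and computes the uniqueness index U(tau).
#' The chosen threshold tau* is the smallest tau whose U reaches
#' `plateauFrac` (default 90%) of the maximum defined U — favouring longer
#' gene lists among near-optimal thresholds. The full sweep table is always
#' returned; if U is undefined at every tau, tau* is NA.
#'
#' @param tables named list of per-subtype gene correlation data.frames
#'   (from [selectCorrelatedGenes()] or [spatialAssociation()]).
#' @param tauGrid thresholds to sweep (default seq(0, 0.5, 0.05)).
#' @param alpha FDR significance level (default 0.05).
#' @param plateauFrac fraction of the maximum U defining the plateau
#'   (default 0.9).
#' @return data.frame with one row per tau: tau, the per-pattern counts,
#'   U, and nSelected per subtype; attribute "tauStar" holds tau*.
#' @export
thresholdSweep <- function(tables, tauGrid = seq(0, 0.5, 0.05), alpha = 0.05,
                           plateauFrac = 0.9) {
  stopifnot(length(tables) >= 2)
  rows <- lapply(tauGrid, function(tau) {
    sel <- lapply(tables, function(tb)
      tb$gene[tb$pFdr < alpha & abs(tb$r) >= tau])
    part <- partitionUniqueShared(sel)
    U <- if (length(tables) == 3) uniquenessIndex(part) else NA_real_
    c(list(tau = tau, U = U),
      as.list(setNames(vapply(sel, length, integer(1)),
                       paste0("n_", names(tables)))),
      as.list(part))
  })
  allCols <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- 0L
    as.data.frame(r[allCols])
  }))
  tauStar <- NA_real_
  if (any(!is.na(tab$U))) {
    target <- plateauFrac * max(tab$U, na.rm = TRUE)
    ok <- which(!is.na(tab$U) & tab$U >= target)
    if (length(ok)) tauStar <- tab$tau[min(ok)]
  }
  attr(tab, "tauStar") <- tauStar
  tab
}

#' One-tailed Fisher (hypergeometric) overlap test
#'
#' Exact upper-tail probability P(X >= observed overlap) of the
#' hypergeometric distribution with margins |A|, |B| and background size N
#' ("greater" alternative; enrichment only).
#'
#' @param setA,setB character gene sets, both non-empty subsets of
#'   `background`.
#' @param background character universe.
#' @return list: overlap, p, and the 2x2 table.
#' @examples
#' # overlap of 808 genes between 1373 HAR genes and 8276 atrophy-correlated
#' # genes in a background of 15655 brain-expressed genes
#' bg <- as.character(seq_len(15655))
#' fisherOverlap(bg[1:1373], bg[c(1:808, 1374:(1374 + 8276 - 809))], bg)$p
#' @export
fisherOverlap <- function(setA, setB, background) {
  if (!length(setA) || !length(setB)) stop("empty set")
  if (!all(setA %in% background) || !all(setB %in% background))
    stop("universe violation: sets must be subsets of the background")
  setA <- unique(setA); setB <- unique(setB)
  N <- length(unique(background))
  ov <- length(intersect(setA, setB))
  p <- phyper(ov - 1, length(setA), N - length(setA), length(setB),
              lower.tail = FALSE)
  tab <- matrix(c(ov, length(setA) - ov,
                  length(setB) - ov, N - length(setA) - length(setB) + ov),
                2, 2, dimnames = list(A = c("in", "out"), B = c("in", "out")))
  list(overlap = ov, p = p, table = tab)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 table \[k1, n1-k1; k2, n2-k2\] without
#' continuity correction, 1 degree of freedom. The uncorrected statistic is
#' the default because it is the convention this analysis reports; a
#' corrected variant is available via `correct = TRUE`.
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list: statistic, p, df.
#' @examples
#' chisqProportions(146, 257, 88, 257)$statistic # 26.39
#' @export
chisqProportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Resampling null for a gene-list overlap
#'
#' Draws B uniform without-replacement subsamples of `size` genes from
#' `pool`, records the overlap of each subsample with `query`, and returns
#' the null distribution together with an empirical P for the supplied
#' observed overlap in the declared direction.
#'
#' @param pool character gene set to subsample from.
#' @param size subsample size (<= |pool|).
#' @param query character gene set to intersect with.
#' @param B number of resamples.
#' @param observed observed overlap count the null is compared against.
#' @param direction "greater" (P = fraction of null >= observed) or "less".
#' @param seed integer RNG seed.
#' @return list: null (integer vector length B), p.
#' @export
resampleOverlapNull <- function(pool, size, query, B = 5000, observed,
                                direction = c("greater", "less"), seed = 1L) {
  direction <- match.arg(direction)
  if (size > length(pool)) stop("invalid argument: size exceeds pool")
  qset <- unique(query)
  withSeed(seed, {
    null <- vapply(seq_len(B), function(b)
      length(intersect(sample(pool, size), qset)), integer(1))
    p <- if (direction == "greater") mean(null >= observed)
         else mean(null <= observed)
    list(null = null, p = p)
  })
}

#' Nearest-neighbour matching of control genes by length
#'
#' Greedy 1:1 matching of each query gene to the candidate with the closest
#' log-length, processing queries in descending length, without
#' replacement; ties go to the earlier candidate in input order. Returns a
#' matched control set of the same size as the query set.
#'
#' @param queryLengths named numeric: query gene -> length (positive).
#' @param candidateLengths named numeric: candidate gene -> length; at
#'   least as many candidates as queries.
#' @return named character: query gene -> matched candidate gene.
#' @export
matchByLength <- function(queryLengths, candidateLengths) {
  if (length(candidateLengths) < length(queryLengths))
    stop("insufficient candidates")
  if (any(queryLengths <= 0) || any(candidateLengths <= 0))
    stop("invalid argument: lengths must be positive")
  qOrd <- names(queryLengths)[order(-queryLengths)]
  avail <- rep(TRUE, length(candidateLengths))
  lcand <- log(candidateLengths)
  out <- character(0)
  for (q in qOrd) {
    d <- abs(log(queryLengths[[q]]) - lcand)
    d[!avail] <- Inf
    j <- which.min(d)  # which.min takes the first minimum: earlier id wins ties
    out[q] <- names(candidateLengths)[j]
    avail[j] <- FALSE
  }
  out[names(queryLengths)]
}

#' Over-representation analysis against gene-set collections
#'
#' One-tailed hypergeometric enrichment of a query gene list against each
#' term of a named collection, with Holm step-down adjustment across terms.
#'
#' @param query non-empty character gene set.
#' @param collections named list of character gene sets (the terms).
#' @param background character universe containing the query and all terms.
#' @return data.frame: term, termSize, overlap, p, pHolm; sorted by p.
#' @export
oraCollections <- function(query, collections, background) {
  if (!length(query)) stop("empty set: query is empty")
  res <- lapply(names(collections), function(term) {
    f <- fisherOverlap(query, collections[[term]], background)
    data.frame(term = term, termSize = length(unique(collections[[term]])),
               overlap = f$overlap, p = f$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$pHolm <- p.adjust(tab$p, method = "holm")
  tab[order(tab$p), , drop = FALSE]
}
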