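#' Count GU(GT)-repeat k-mers in a DNA sequence
#'
#' Counts positions where the alternating GT-repeat motif of length k
#' (GTGT, GTGTG or GTGTGT) occurs in the sense-strand DNA sequence,
#' counting overlapping occurrences by default (so "GTGTGTGT" contains
#' three GTGT tetramers). These motifs are the DNA form of the GU repeats
#' that constitute putative TDP-43 binding sites in pre-mRNA. An N never
#' matches. A non-overlapping mode is available.
#'
#' @param sequence a DNA string over A, C, G, T, N (character,
#'   [Biostrings::DNAString] or single-element DNAStringSet).
#' @param k motif length, one of 4, 5, 6.
#' @param overlapping count overlapping occurrences (default TRUE).
#' @return integer count.
#' @examples
#' countGuKmers("GTGTGTGT", 4) # 3
#' @export
countGuKmers <- function(sequence, k, overlapping = TRUE) {
  if (!k %in% c(4, 5, 6)) stop("invalid argument: k must be 4, 5 or 6")
  if (is(sequence, "XStringSet")) sequence <- sequence[[1]]
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s)) stop("invalid sequence: characters outside ACGTN")
  motif <- substr("GTGTGT", 1, k)
  if (overlapping) {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
    length(m)
  } else {
    length(gregexpr(motif, s, fixed = TRUE)[[1]][gregexpr(motif, s, fixed = TRUE)[[1]] > 0])
  }
}

#' GU-repeat profile of a set of gene sequences
#'
#' Computes overlapping occurrence counts of the GT tetramer, pentamer and
#' hexamer motifs per gene, together with the sequence length.
#'
#' @param seqs a named [Biostrings::DNAStringSet] (names = gene ids), or a
#'   named character vector.
#' @param overlapping count overlapping occurrences (default TRUE).
#' @return data.frame: gene, c4, c5, c6, length. The counts are nested:
#'   c4 >= c5 >= c6.
#' @export
guProfile <- function(seqs, overlapping = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("gene", seq_along(seqs))
  counts <- vapply(c(4, 5, 6), function(k)
    vapply(seq_along(seqs), function(i)
      countGuKmers(seqs[[i]], k, overlapping), integer(1)),
    integer(length(seqs)))
  counts <- matrix(counts, ncol = 3)
  data.frame(gene = names(seqs),
             c4 = counts[, 1], c5 = counts[, 2], c6 = counts[, 3],
             length = Biostrings::width(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes with above-median GU-repeat content
#'
#' A gene is classified high-GU — putatively TDP-43 regulated — if its
#' tetramer OR pentamer OR hexamer count is strictly above the respective
#' median over all input genes (disjunction; strict inequality, so when
#' all genes are identical the set is empty).
#'
#' @param profiles data.frame from [guProfile()] (columns gene, c4, c5,
#'   c6); at least 2 genes.
#' @return character vector of high-GU gene ids.
#' @export
classifyHighGu <- function(profiles) {
  if (nrow(profiles) < 2) stop("invalid argument: need >= 2 genes")
  m4 <- median(profiles$c4); m5 <- median(profiles$c5); m6 <- median(profiles$c6)
  hi <- profiles$c4 > m4 | profiles$c5 > m5 | profiles$c6 > m6
  profiles$gene[hi]
}
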