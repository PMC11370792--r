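# Plain-text readers and writers for every container the pipeline
# exchanges. All tables are TSV; gene lists are one id per line;
# sequences are FASTA; ground truth and manifests are JSON.

#' Write / read a region x gene expression matrix as TSV
#'
#' Rows are regions, columns genes; the first column is region_id. Region
#' metadata (coordinates, cortical flag, hemisphere) is carried in
#' commented header lines so a round trip restores the full object.
#'
#' @param expr a [RegionExpression-class].
#' @param path output file.
#' @export
writeExpressionTSV <- function(expr, path) {
  E <- regionGeneMatrix(expr)
  cd <- SummarizedExperiment::colData(expr)
  hdr <- sprintf("# region_meta\t%s\t%f\t%f\t%f\t%s\t%s",
                 rownames(cd), cd$x, cd$y, cd$z,
                 ifelse(cd$cortical, "1", "0"), cd$hemisphere)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(region_id = rownames(E), E, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeExpressionTSV
#' @param path TSV file written by [writeExpressionTSV()].
#' @return a [RegionExpression-class].
#' @export
readExpressionTSV <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# region_meta")]
  md <- do.call(rbind, strsplit(meta, "\t"))
  df <- read.delim(text = lines[!startsWith(lines, "#")],
                   check.names = FALSE)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df$region_id
  ord <- match(df$region_id, md[, 2])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = t(E)),
    colData = S4Vectors::DataFrame(
      regionId = df$region_id,
      x = as.numeric(md[ord, 3]), y = as.numeric(md[ord, 4]),
      z = as.numeric(md[ord, 5]),
      cortical = md[ord, 6] == "1",
      hemisphere = md[ord, 7],
      nDonors = NA_integer_,
      row.names = df$region_id))
  new("RegionExpression", se)
}

#' Write / read a W-map as TSV
#'
#' @param wmap a [WMap-class].
#' @param path output file.
#' @export
writeWMapTSV <- function(wmap, path) {
  write.table(data.frame(unit_id = wmap@unitId, w = wmap@w),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeWMapTSV
#' @param label map label for the object read back.
#' @return a [WMap-class].
#' @export
readWMapTSV <- function(path, label = basename(path)) {
  df <- read.delim(path)
  new("WMap", unitId = as.character(df$unit_id), w = df$w, label = label)
}

#' Write / read a gene list as one-id-per-line text
#'
#' @param genes character vector.
#' @param path output file.
#' @export
writeGeneList <- function(genes, path) writeLines(genes, path)

#' @rdname writeGeneList
#' @return character vector.
#' @export
readGeneList <- function(path) readLines(path)

#' Write / read a connectivity library as region x region TSV
#'
#' Rows are seeds (first column seed_id), columns regions.
#'
#' @param library a [ConnectivityLibrary-class].
#' @param path output file.
#' @export
writeConnectivityTSV <- function(library, path) {
  df <- data.frame(seed_id = library@seeds, library@maps, check.names = FALSE)
  colnames(df) <- c("seed_id", library@regionId)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeConnectivityTSV
#' @return a [ConnectivityLibrary-class].
#' @export
readConnectivityTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  new("ConnectivityLibrary",
      seeds = as.character(df$seed_id),
      maps = as.matrix(df[, -1, drop = FALSE]),
      regionId = colnames(df)[-1])
}

#' Write sequences as FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
}

#' @rdname writeFasta
#' @return a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)
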