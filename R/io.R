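#' Write a labelled matrix as TSV (header row + first column of labels)
#' @param m matrix with dimnames.
#' @param file output path.
#' @param label name of the first (row-label) column.
#' @export
writeMatrixTSV <- function(m, file, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a labelled matrix from TSV
#' @param file path produced by \code{\link{writeMatrixTSV}}.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a data frame as TSV
#' @param df data.frame.
#' @param file output path.
#' @export
writeTSV <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV written by \code{\link{writeTSV}}
#' @param file path.
#' @return data.frame.
#' @export
readTSV <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write ChIP-seq peaks as BED6+signal
#' @param peaks GRanges with mcols tf, signal.
#' @param file output path.
#' @export
writePeaksBED <- function(peaks, file) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,  # BED 0-based
                   end = GenomicRanges::end(peaks),
                   name = as.character(peaks$tf),
                   score = 0L,
                   strand = ".",
                   signal = as.numeric(peaks$signal))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a GeneAnnotation as an Ensembl-dialect GTF
#' @param ann a \code{GeneAnnotation}.
#' @param file output path.
#' @export
writeGeneAnnotationGTF <- function(ann, file) {
  fmt <- function(gr, type, attr) {
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(seqnames(gr)), type,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(strand(gr)), attr)
  }
  g <- ann@genes; tx <- ann@transcripts; ex <- ann@exons
  lines <- c(
    fmt(g, "gene", sprintf('gene_id "%s"; gene_biotype "%s";',
                           g$gene_id, ifelse(is.na(g$biotype),
                                             "protein_coding", g$biotype))),
    fmt(tx, "transcript", sprintf('gene_id "%s"; transcript_id "%s";',
                                  tx$gene_id, tx$tx_id)),
    fmt(ex, "exon", sprintf('gene_id "%s"; transcript_id "%s";',
                            ex$gene_id, ex$tx_id)))
  writeLines(lines, file)
  invisible(file)
}
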