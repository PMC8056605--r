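#' Read an Ensembl-dialect GTF into a GeneAnnotation
#'
#' Imports gene/transcript/exon records (via rtracklayer, which converts GTF
#' 1-based coordinates into GRanges). When \code{gene_biotype} is present only
#' protein-coding genes are retained, since the regulatory-window analysis is
#' defined for protein-coding target genes.
#'
#' @param file path to a GTF file.
#' @param protein_coding_only drop genes whose \code{gene_biotype} is present
#'   and not \code{"protein_coding"}.
#' @return a \code{\linkS4class{GeneAnnotation}}.
#' @export
readGeneAnnotation <- function(file, protein_coding_only = TRUE) {
  gr <- rtracklayer::import(file, format = "gtf")
  typ <- as.character(gr$type)
  if (!"gene_biotype" %in% colnames(mcols(gr))) gr$gene_biotype <- NA_character_
  genes <- gr[typ == "gene"]
  tx <- gr[typ == "transcript"]
  ex <- gr[typ == "exon"]
  if (protein_coding_only && !all(is.na(genes$gene_biotype))) {
    keep <- is.na(genes$gene_biotype) | genes$gene_biotype == "protein_coding"
    genes <- genes[keep]
    tx <- tx[tx$gene_id %in% genes$gene_id]
    ex <- ex[ex$gene_id %in% genes$gene_id]
  }
  g <- granges(genes)
  mcols(g) <- S4Vectors::DataFrame(gene_id = genes$gene_id,
                                   biotype = genes$gene_biotype)
  t2 <- granges(tx)
  mcols(t2) <- S4Vectors::DataFrame(tx_id = tx$transcript_id,
                                    gene_id = tx$gene_id)
  e2 <- granges(ex)
  mcols(e2) <- S4Vectors::DataFrame(tx_id = ex$transcript_id,
                                    gene_id = ex$gene_id)
  methods::new("GeneAnnotation", genes = g, transcripts = t2, exons = e2)
}

#' Read ChIP-seq peaks from BED
#'
#' BED6+ with column 4 the TF name and column 7 (when present) the signal
#' value. rtracklayer handles the 0-based half-open to 1-based conversion.
#'
#' @param file path to a BED file.
#' @return \code{GRanges} with mcols \code{tf} and \code{signal}.
#' @export
readPeaksBED <- function(file) {
  ec <- c(signal = "numeric")
  gr <- tryCatch(rtracklayer::import(file, format = "bed", extraCols = ec),
                 error = function(e) rtracklayer::import(file, format = "bed"))
  tf <- if ("name" %in% colnames(mcols(gr))) gr$name else NA_character_
  sig <- if ("signal" %in% colnames(mcols(gr))) gr$signal else
         if ("score" %in% colnames(mcols(gr))) as.numeric(gr$score) else 0
  out <- granges(gr)
  mcols(out) <- S4Vectors::DataFrame(tf = tf, signal = sig)
  if (any(out$signal < 0, na.rm = TRUE)) stop("negative peak signal")
  out
}

.geneRow <- function(ann, gene_id) {
  i <- match(gene_id, ann@genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  ann@genes[i]
}

#' Longest transcript of a gene
#'
#' Maximal span (end - start); ties broken by lexicographically smallest
#' transcript id so the choice is reproducible.
#'
#' @param ann a \code{GeneAnnotation}.
#' @param gene_id gene identifier.
#' @return length-1 \code{GRanges} (the transcript span, mcols \code{tx_id}).
#' @export
longestTranscript <- function(ann, gene_id) {
  tx <- ann@transcripts[ann@transcripts$gene_id == gene_id]
  if (length(tx) == 0L) stop("no transcripts for gene ", gene_id)
  o <- order(-GenomicRanges::width(tx), tx$tx_id)
  tx[o[1L]]
}

#' TSS of a gene (longest transcript)
#'
#' Strand-aware: start of the longest transcript on +, end on -.
#'
#' @inheritParams longestTranscript
#' @return integer position (1-based).
#' @export
geneTSS <- function(ann, gene_id) {
  tx <- longestTranscript(ann, gene_id)
  if (as.character(strand(tx)) == "-") GenomicRanges::end(tx)
  else GenomicRanges::start(tx)
}

#' Candidate (pre-CTCF) cis-regulatory window
#'
#' The window from 50 kb (default) upstream of the longest-transcript TSS to
#' 50 kb downstream of the gene body 3' end, mirrored on the minus strand and
#' clipped at position 1.
#'
#' @inheritParams longestTranscript
#' @param flank flank size in bp (default 50000).
#' @return length-1 \code{GRanges} (mcols \code{gene_id}).
#' @export
candidateWindow <- function(ann, gene_id, flank = 50000L) {
  if (flank < 0) stop("flank must be non-negative")
  gene <- .geneRow(ann, gene_id)
  tss <- geneTSS(ann, gene_id)
  minus <- as.character(strand(gene)) == "-"
  if (minus) {
    lo <- GenomicRanges::start(gene) - flank   # 3' end side
    hi <- tss + flank
  } else {
    lo <- tss - flank
    hi <- GenomicRanges::end(gene) + flank
  }
  out <- GRanges(seqnames(gene), IRanges(max(1L, lo), hi), strand = strand(gene))
  out$gene_id <- gene_id
  out
}

.midpoint <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

#' CTCF-bounded cis-regulatory window
#'
#' Truncates the candidate window at the most distant CTCF peak midpoint on
#' each side of the gene body (the peak closest to the candidate edge); flanks
#' with no CTCF peak keep the candidate boundary. Peaks whose midpoint lies
#' inside the gene body are ignored, so the window never shrinks into the body.
#'
#' @param candidate length-1 \code{GRanges} from \code{\link{candidateWindow}}.
#' @param gene_body length-1 \code{GRanges}, the gene span.
#' @param ctcf_peaks \code{GRanges} of CTCF peaks (may be empty).
#' @return length-1 \code{GRanges}.
#' @export
ctcfBoundedWindow <- function(candidate, gene_body, ctcf_peaks) {
  lo <- GenomicRanges::start(candidate); hi <- GenomicRanges::end(candidate)
  if (length(ctcf_peaks)) {
    same <- as.character(seqnames(ctcf_peaks)) ==
      as.character(seqnames(candidate))
    mids <- .midpoint(ctcf_peaks[same])
    up <- mids[mids >= lo & mids < GenomicRanges::start(gene_body)]
    dn <- mids[mids <= hi & mids > GenomicRanges::end(gene_body)]
    if (length(up)) lo <- min(up)   # most distant from the body
    if (length(dn)) hi <- max(dn)
  }
  out <- GRanges(seqnames(candidate), IRanges(lo, hi),
                 strand = strand(candidate))
  mcols(out) <- mcols(candidate)
  out
}

#' Promoter region of a gene
#'
#' The \code{length} bp (default 5000) immediately upstream of the
#' longest-transcript TSS, strand-aware and clipped at position 1.
#'
#' @inheritParams longestTranscript
#' @param length promoter length in bp.
#' @return length-1 \code{GRanges} (mcols \code{gene_id}).
#' @export
promoterRegion <- function(ann, gene_id, length = 5000L) {
  gene <- .geneRow(ann, gene_id)
  tss <- geneTSS(ann, gene_id)
  minus <- as.character(strand(gene)) == "-"
  if (minus) {
    lo <- tss + 1L; hi <- tss + length
  } else {
    lo <- tss - length; hi <- tss - 1L
  }
  lo <- max(1L, lo)
  if (hi < lo) hi <- lo  # fully clipped edge case at chromosome start
  out <- GRanges(seqnames(gene), IRanges(lo, hi), strand = strand(gene))
  out$gene_id <- gene_id
  out
}

#' Intronic regions of a gene
#'
#' Per transcript, the span minus the union of its exons; the per-transcript
#' introns are then unioned across transcripts and merged.
#'
#' @inheritParams longestTranscript
#' @return \code{GRanges} (possibly empty) of merged intronic intervals.
#' @export
intronicRegions <- function(ann, gene_id) {
  tx <- ann@transcripts[ann@transcripts$gene_id == gene_id]
  if (length(tx) == 0L) stop("no transcripts for gene ", gene_id)
  pieces <- lapply(seq_along(tx), function(i) {
    ex <- ann@exons[ann@exons$tx_id == tx$tx_id[i]]
    GenomicRanges::setdiff(granges(tx[i]), reduce(granges(ex)),
                           ignore.strand = FALSE)
  })
  out <- reduce(do.call(c, pieces))
  out
}

#' Build regulatory windows for all genes
#'
#' Computes, per gene: the candidate flank window, the CTCF-bounded window,
#' the promoter and the intronic regions.
#'
#' @param ann a \code{GeneAnnotation}.
#' @param ctcf_peaks \code{GRanges} of CTCF peaks (optional).
#' @param flank upstream/downstream flank in bp (default 50000).
#' @param promoter_length promoter size in bp (default 5000).
#' @return a \code{\linkS4class{RegulatoryWindows}}.
#' @export
regulatoryWindows <- function(ann, ctcf_peaks = GRanges(), flank = 50000L,
                              promoter_length = 5000L) {
  ids <- ann@genes$gene_id
  cand <- do.call(c, lapply(ids, function(g) candidateWindow(ann, g, flank)))
  bounded <- do.call(c, lapply(seq_along(ids), function(i) {
    ctcfBoundedWindow(cand[i], .geneRow(ann, ids[i]), ctcf_peaks)
  }))
  bounded$tss <- vapply(ids, function(g) as.integer(geneTSS(ann, g)),
                        integer(1))
  prom <- do.call(c, lapply(ids, function(g)
    promoterRegion(ann, g, promoter_length)))
  introns <- GRangesList(lapply(ids, function(g) intronicRegions(ann, g)))
  names(introns) <- ids
  methods::new("RegulatoryWindows", bounded = bounded, candidate = cand,
               promoters = prom, introns = introns)
}

#' Partition peaks into promoter / intronic / distal classes
#'
#' Every peak overlapping (>= 1 bp) a gene's CTCF-bounded window is assigned
#' exactly one category for that gene, with precedence
#' promoter > intronic > distal when a peak overlaps several region types.
#' Peaks outside the bounded window are excluded.
#'
#' @param peaks \code{GRanges} with mcols \code{tf} and \code{signal}.
#' @param rw a \code{RegulatoryWindows}.
#' @return data.frame with columns \code{tf}, \code{gene_id},
#'   \code{category} (factor: promoter/intronic/distal), \code{peak_chrom},
#'   \code{peak_start}, \code{peak_end}, \code{signal}.
#' @export
partitionPeaks <- function(peaks, rw) {
  hits <- findOverlaps(peaks, rw@bounded, ignore.strand = TRUE)
  pk <- queryHits(hits); gi <- subjectHits(hits)
  gene <- rw@bounded$gene_id[gi]
  key <- paste0(pk, "\r", gene)
  ph <- findOverlaps(peaks, rw@promoters, ignore.strand = TRUE)
  pkey <- paste0(queryHits(ph), "\r", rw@promoters$gene_id[subjectHits(ph)])
  intr <- unname(unlist(rw@introns))
  igene <- rep(names(rw@introns), S4Vectors::elementNROWS(rw@introns))
  ih <- findOverlaps(peaks, intr, ignore.strand = TRUE)
  ikey <- paste0(queryHits(ih), "\r", igene[subjectHits(ih)])
  cat_lab <- rep("distal", length(pk))
  cat_lab[key %in% ikey] <- "intronic"
  cat_lab[key %in% pkey] <- "promoter"
  data.frame(
    tf = as.character(peaks$tf[pk]),
    gene_id = gene,
    category = factor(cat_lab, levels = c("promoter", "intronic", "distal")),
    peak_chrom = as.character(seqnames(peaks))[pk],
    peak_start = GenomicRanges::start(peaks)[pk],
    peak_end = GenomicRanges::end(peaks)[pk],
    signal = as.numeric(peaks$signal)[pk],
    stringsAsFactors = FALSE)
}
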