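#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList granges strand seqnames
#'   findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Gene annotation container
#'
#' Holds the strand-aware gene/transcript/exon geometry the regulatory-window
#' machinery operates on. All ranges are 1-based closed (GRanges convention);
#' GTF input is converted on read by \code{\link{readGeneAnnotation}}.
#'
#' @slot genes \code{GRanges}, one per gene, with metadata columns
#'   \code{gene_id} and \code{biotype}; the range is the gene body (union of
#'   its transcripts).
#' @slot transcripts \code{GRanges} with \code{tx_id} and \code{gene_id}.
#' @slot exons \code{GRanges} with \code{tx_id} and \code{gene_id}.
#' @export
setClass("GeneAnnotation",
  slots = c(genes = "GRanges", transcripts = "GRanges", exons = "GRanges"))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes; tx <- object@transcripts; ex <- object@exons
  msg <- character()
  need <- function(gr, cols) all(cols %in% colnames(mcols(gr)))
  if (!need(g, c("gene_id", "biotype"))) msg <- c(msg, "genes need gene_id, biotype")
  if (!need(tx, c("tx_id", "gene_id"))) msg <- c(msg, "transcripts need tx_id, gene_id")
  if (!need(ex, c("tx_id", "gene_id"))) msg <- c(msg, "exons need tx_id, gene_id")
  if (length(msg)) return(msg)
  if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene_id")
  if (anyDuplicated(tx$tx_id)) msg <- c(msg, "duplicate tx_id")
  if (!all(tx$gene_id %in% g$gene_id)) msg <- c(msg, "orphan transcripts")
  if (!all(ex$tx_id %in% tx$tx_id)) msg <- c(msg, "orphan exons")
  if (!all(tx$tx_id %in% ex$tx_id)) msg <- c(msg, "transcript without exons")
  if (length(msg)) msg else TRUE
})

#' Per-gene regulatory windows
#'
#' The CTCF-bounded cis-regulatory window, the pre-CTCF candidate window, the
#' promoter and the intronic regions for each gene, as produced by
#' \code{\link{regulatoryWindows}}.
#'
#' @slot bounded \code{GRanges} (one per gene; mcols \code{gene_id},
#'   \code{tss}) — the CTCF-bounded window.
#' @slot candidate \code{GRanges} — the pre-CTCF flank window.
#' @slot promoters \code{GRanges} — 5 kb (default) upstream of the TSS.
#' @slot introns \code{GRangesList} named by gene_id.
#' @export
setClass("RegulatoryWindows",
  slots = c(bounded = "GRanges", candidate = "GRanges",
            promoters = "GRanges", introns = "GRangesList"))

setValidity("RegulatoryWindows", function(object) {
  b <- object@bounded; cand <- object@candidate; p <- object@promoters
  if (!all(c("gene_id", "tss") %in% colnames(mcols(b))))
    return("bounded needs gene_id and tss")
  if (length(b) != length(cand) || length(b) != length(p))
    return("bounded/candidate/promoters lengths differ")
  if (any(GenomicRanges::start(b) < GenomicRanges::start(cand)) ||
      any(GenomicRanges::end(b) > GenomicRanges::end(cand)))
    return("bounded window not contained in candidate window")
  if (!all(names(object@introns) %in% b$gene_id))
    return("introns named by unknown gene_id")
  TRUE
})

#' TF-by-gene network matrix
#'
#' A labelled TF x gene matrix used for motif priors (binary or
#' affinity-weighted), Hi-C-adjusted priors, and PANDA output edge weights.
#'
#' @slot matrix numeric matrix; rownames are TF names, colnames gene ids.
#' @slot mode one of \code{"binary"}, \code{"weighted"}, \code{"panda"},
#'   \code{"hic"}.
#' @export
setClass("TFGeneNetwork",
  slots = c(matrix = "matrix", mode = "character"))

setValidity("TFGeneNetwork", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix must carry TF rownames and gene colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("duplicate row or column labels")
  if (!all(is.finite(m))) return("non-finite entries")
  if (!object@mode %in% c("binary", "weighted", "panda", "hic"))
    return("unknown mode")
  if (object@mode == "binary" && !all(m %in% c(0, 1)))
    return("binary network entries must be 0/1")
  TRUE
})

#' PANDA fit result
#'
#' @slot regulatory TF x gene regulatory network (W) at convergence.
#' @slot cooperativity TF x TF cooperativity network (P) at convergence.
#' @slot coregulation gene x gene co-regulation network (C) at convergence.
#' @slot hamming per-iteration mean absolute change of W.
#' @slot converged whether the Hamming tolerance was met before max_iter.
#' @slot update the message-passing update (learning) rate used.
#' @export
setClass("PandaResult",
  slots = c(regulatory = "matrix", cooperativity = "matrix",
            coregulation = "matrix",
            hamming = "numeric", converged = "logical", update = "numeric"))

setValidity("PandaResult", function(object) {
  if (nrow(object@regulatory) != nrow(object@cooperativity) ||
      ncol(object@regulatory) != ncol(object@coregulation))
    return("W/P/C shapes inconsistent")
  if (any(object@hamming < 0)) return("negative hamming distance")
  if (object@update < 0 || object@update > 1) return("update must be in [0,1]")
  TRUE
})

#' Averaged TF effect estimates
#'
#' Per-TF elastic-net coefficients averaged over resampling iterations, with
#' optional quintile bin labels (1 = most repressive, 5 = most activating).
#'
#' @slot beta named numeric, mean standardized coefficient per TF.
#' @slot bins named integer in 1..5, or NA before binning.
#' @export
setClass("EffectEstimates",
  slots = c(beta = "numeric", bins = "integer"))

setValidity("EffectEstimates", function(object) {
  if (is.null(names(object@beta))) return("beta must be named by TF")
  if (length(object@bins) && length(object@bins) != length(object@beta))
    return("bins length must match beta")
  if (length(object@bins) && !all(is.na(object@bins) | object@bins %in% 1:5))
    return("bins must be in 1..5")
  TRUE
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(object@genes), "genes,",
      length(object@transcripts), "transcripts,",
      length(object@exons), "exons\n")
})

setMethod("show", "RegulatoryWindows", function(object) {
  cat("RegulatoryWindows for", length(object@bounded), "genes",
      "(CTCF-bounded; promoters + introns attached)\n")
})

setMethod("show", "TFGeneNetwork", function(object) {
  cat("TFGeneNetwork [", object@mode, "]: ",
      nrow(object@matrix), " TFs x ", ncol(object@matrix), " genes\n", sep = "")
})

setMethod("show", "PandaResult", function(object) {
  cat("PandaResult:", nrow(object@regulatory), "TFs x",
      ncol(object@regulatory), "genes;",
      length(object@hamming), "iterations;",
      if (object@converged) "converged" else "NOT converged", "\n")
})

setMethod("show", "EffectEstimates", function(object) {
  cat("EffectEstimates for", length(object@beta), "TFs")
  if (length(object@bins)) cat(" (binned into quintiles)")
  cat("\n")
})

#' @describeIn TFGeneNetwork-class extract the numeric matrix.
#' @param x a \code{TFGeneNetwork}.
#' @export
networkMatrix <- function(x) {
  stopifnot(is(x, "TFGeneNetwork"))
  x@matrix
}

#' @describeIn TFGeneNetwork-class TF (row) names.
#' @export
tfNames <- function(x) rownames(networkMatrix(x))

#' @describeIn TFGeneNetwork-class gene (column) names.
#' @export
targetNames <- function(x) colnames(networkMatrix(x))

#' @describeIn EffectEstimates-class mean coefficient per TF.
#' @param object an \code{EffectEstimates}.
#' @export
effectBeta <- function(object) {
  stopifnot(is(object, "EffectEstimates"))
  object@beta
}

#' @describeIn EffectEstimates-class quintile bin per TF (integer 1..5).
#' @export
effectBins <- function(object) {
  stopifnot(is(object, "EffectEstimates"))
  object@bins
}

#' @describeIn PandaResult-class the fitted TF x gene edge-weight matrix.
#' @param x a \code{PandaResult}.
#' @export
pandaW <- function(x) {
  stopifnot(is(x, "PandaResult"))
  x@regulatory
}

#' @describeIn RegulatoryWindows-class the CTCF-bounded windows as GRanges.
#' @param x a \code{RegulatoryWindows}.
#' @export
boundedWindows <- function(x) {
  stopifnot(is(x, "RegulatoryWindows"))
  x@bounded
}

#' @describeIn RegulatoryWindows-class promoter regions as GRanges.
#' @export
promoterRegions <- function(x) {
  stopifnot(is(x, "RegulatoryWindows"))
  x@promoters
}

#' @describeIn RegulatoryWindows-class intronic regions as a GRangesList.
#' @export
intronRegions <- function(x) {
  stopifnot(is(x, "RegulatoryWindows"))
  x@introns
}
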