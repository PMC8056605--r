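#' Read normalized Hi-C promoter-contact records
#'
#' Sparse triplet TSV with columns \code{chrom}, \code{peak_start},
#' \code{peak_end}, \code{tf}, \code{gene_id}, \code{kr_contacts}: the number
#' of matrix-balanced (KR-normalized) contacts between a TF ChIP-seq peak and
#' a gene's promoter. Only peaks with at least one contact need appear;
#' absent records mean zero contacts.
#'
#' @param file path to the contact TSV.
#' @return data.frame of contact records.
#' @export
readContacts <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "peak_start", "peak_end", "tf", "gene_id", "kr_contacts")
  if (!all(need %in% names(df)))
    stop("contact file must have columns: ", paste(need, collapse = ", "))
  if (any(df$kr_contacts < 0)) stop("negative contact counts")
  df
}

.peakKey <- function(chrom, start, end, tf, gene) {
  paste(chrom, start, end, tf, gene, sep = "\r")
}

#' Mean promoter contacts per TF-gene pair
#'
#' For each (tf, gene) pair present in the positional binding records, the
#' arithmetic mean of KR-normalized contacts over all of that TF's peaks in
#' the gene's regulatory region; peaks without a recorded contact contribute
#' zero. Pairs absent from \code{tfbs} (no peaks) are not represented.
#'
#' @param tfbs data.frame from \code{\link{positionalTFBS}} (all peaks of
#'   each TF in each gene's region).
#' @param contacts data.frame from \code{\link{readContacts}}.
#' @return data.frame: \code{tf}, \code{gene_id}, \code{mean_contacts}.
#' @export
meanContacts <- function(tfbs, contacts) {
  if (nrow(tfbs) == 0L) stop("no TF-gene peak records")
  ck <- .peakKey(contacts$chrom, contacts$peak_start, contacts$peak_end,
                 contacts$tf, contacts$gene_id)
  cmap <- stats::setNames(contacts$kr_contacts, ck)
  pk <- .peakKey(tfbs$peak_chrom, tfbs$peak_start, tfbs$peak_end,
                 tfbs$tf, tfbs$gene_id)
  cp <- unname(cmap[pk])
  cp[is.na(cp)] <- 0  # zero-fill: peak with no recorded contact
  agg <- stats::aggregate(cp, by = list(tf = tfbs$tf, gene_id = tfbs$gene_id),
                          FUN = mean)
  names(agg)[3] <- "mean_contacts"
  agg
}

#' Scale mean contacts into [0, 0.99]
#'
#' x -> 0.99 * x / max(x), so zero mean contacts map exactly to 0 (hence an
#' Eq.-2 weight of exactly 1) and the maximal pair maps exactly to 0.99. An
#' all-zero input is returned unchanged with a warning.
#'
#' @param x non-negative numeric vector of mean contacts.
#' @return scaled vector in [0, 0.99].
#' @export
scaleContacts <- function(x) {
  if (any(x < 0)) stop("mean contacts must be non-negative")
  mx <- max(x)
  if (mx == 0) {
    warning("all mean contacts are zero; returning zeros")
    return(x)
  }
  0.99 * (x / mx)  # x/mx first: the maximum maps to exactly 0.99
}

#' Hi-C adjusted edge weight
#'
#' \code{C = 1 + scaled}: 1 for pairs with no promoter contacts, at most 1.99.
#'
#' @param scaled scaled mean contacts in [0, 0.99].
#' @return weight(s) in [1, 1.99].
#' @export
hicWeight <- function(scaled) {
  if (any(scaled < 0 | scaled > 0.99))
    stop("scaled contacts must lie in [0, 0.99]")
  1 + scaled
}

#' Full Hi-C weight matrix over a motif prior
#'
#' Combines \code{\link{meanContacts}}, \code{\link{scaleContacts}} (one
#' global scaler per matrix) and \code{\link{hicWeight}}: every TF-gene pair
#' of the motif prior gets a weight in [1, 1.99]; pairs without peaks or
#' without contacts get exactly 1.
#'
#' @param motif binary \code{TFGeneNetwork}.
#' @param tfbs positional binding records.
#' @param contacts contact records.
#' @return numeric TF x gene matrix of Eq.-2 weights.
#' @export
hicWeightMatrix <- function(motif, tfbs, contacts) {
  m <- networkMatrix(motif)
  mc <- meanContacts(tfbs, contacts)
  keep <- mc$tf %in% rownames(m) & mc$gene_id %in% colnames(m)
  mc <- mc[keep, , drop = FALSE]
  sc <- scaleContacts(mc$mean_contacts)
  W <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  W[cbind(match(mc$tf, rownames(m)), match(mc$gene_id, colnames(m)))] <-
    hicWeight(sc)
  W
}

#' Apply the Hi-C DP or UP weighting scheme to a motif prior
#'
#' DP multiplies every motif entry by its Hi-C weight; UP additionally boosts
#' promoter-based pairs whose weight is exactly 1.0 (no promoter contacts) to
#' the maximum weight 2.0, so promoter TFs missed by low-resolution Hi-C are
#' not down-weighted. Absent motif edges stay 0 under both schemes.
#'
#' @param motif binary \code{TFGeneNetwork}.
#' @param weights TF x gene weight matrix from \code{\link{hicWeightMatrix}}.
#' @param promoter_pairs data.frame with columns \code{tf}, \code{gene_id}:
#'   pairs having at least one promoter-category peak (see
#'   \code{\link{partitionPeaks}}). Only used by UP.
#' @param scheme \code{"DP"} or \code{"UP"}.
#' @return a \code{TFGeneNetwork} (mode \code{"hic"}).
#' @export
applyScheme <- function(motif, weights, promoter_pairs = NULL,
                        scheme = c("DP", "UP")) {
  scheme <- match.arg(scheme)
  m <- networkMatrix(motif)
  if (!identical(dim(m), dim(weights)))
    stop("motif and weight matrices must be aligned")
  out <- m * weights
  if (scheme == "UP" && NROW(promoter_pairs)) {
    i <- cbind(match(promoter_pairs$tf, rownames(m)),
               match(promoter_pairs$gene_id, colnames(m)))
    i <- i[stats::complete.cases(i), , drop = FALSE]
    boost <- weights[i] == 1.0
    out[i[boost, , drop = FALSE]] <- 2.0 * m[i[boost, , drop = FALSE]]
  }
  methods::new("TFGeneNetwork", matrix = out, mode = "hic")
}
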