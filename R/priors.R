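#' Build a motif adjacency matrix from TF-gene binding evidence
#'
#' Binary mode marks each unique (tf, gene) pair with 1 (any-evidence rule);
#' weighted mode places the supplied affinity values. Pairs without evidence
#' are 0.
#'
#' @param pairs data.frame with columns \code{tf}, \code{gene_id} and, for
#'   weighted mode, \code{value}.
#' @param tfs character vector of all modelled TFs (matrix rows).
#' @param genes character vector of all modelled genes (matrix columns).
#' @param mode \code{"binary"} or \code{"weighted"}.
#' @return a \code{\linkS4class{TFGeneNetwork}}.
#' @export
motifAdjacency <- function(pairs, tfs, genes, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  bad_tf <- setdiff(unique(pairs$tf), tfs)
  if (length(bad_tf)) stop("unknown TF label(s): ", paste(bad_tf, collapse = ", "))
  bad_g <- setdiff(unique(pairs$gene_id), genes)
  if (length(bad_g)) stop("unknown gene label(s): ", paste(bad_g, collapse = ", "))
  m <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  i <- cbind(match(pairs$tf, tfs), match(pairs$gene_id, genes))
  if (mode == "binary") {
    m[unique(i, MARGIN = 1)] <- 1
  } else {
    if (!"value" %in% names(pairs)) stop("weighted mode needs a value column")
    # last value wins for duplicated pairs; callers pass aggregated scores
    m[i] <- pairs$value
  }
  methods::new("TFGeneNetwork", matrix = m, mode = mode)
}

#' Symmetric 0/1 protein-protein interaction network over the modelled TFs
#'
#' Edges touching TFs outside \code{tfs} are dropped with a message; the
#' diagonal (self-cooperativity) is fixed at 1, the PANDA convention.
#'
#' @param edges data.frame with two columns of TF names (may be empty).
#' @param tfs character vector of modelled TFs.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
ppiNetwork <- function(edges, tfs) {
  m <- diag(1, length(tfs))
  dimnames(m) <- list(tfs, tfs)
  if (NROW(edges)) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    known <- a %in% tfs & b %in% tfs
    if (any(!known))
      message(sum(!known), " PPI edge(s) dropped (TF not modelled)")
    ia <- match(a[known], tfs); ib <- match(b[known], tfs)
    m[cbind(ia, ib)] <- 1
    m[cbind(ib, ia)] <- 1
  }
  diag(m) <- 1
  m
}

#' Pearson co-expression network
#'
#' Correlation across samples of a samples x genes expression matrix.
#' Zero-variance genes get 0 on all off-diagonal entries and 1 on the
#' diagonal (and are reported via a message).
#'
#' @param expr numeric matrix, samples in rows, genes in columns (named).
#' @return symmetric gene x gene correlation matrix.
#' @export
coexpressionNetwork <- function(expr) {
  if (nrow(expr) < 3) stop("need at least 3 samples for co-expression")
  v <- apply(expr, 2, stats::var)
  flat <- v == 0 | is.na(v)
  cc <- suppressWarnings(stats::cor(expr))
  if (any(flat)) {
    message(sum(flat), " zero-variance gene(s) in co-expression input")
    cc[flat, ] <- 0; cc[, flat] <- 0
  }
  diag(cc) <- 1
  cc[is.na(cc)] <- 0
  # enforce exact symmetry against floating-point asymmetries
  (cc + t(cc)) / 2
}

#' Restrict motif, PPI and co-expression networks to common labels
#'
#' Genes must appear in both the motif prior and the expression-derived
#' co-expression network; dropped labels are reported.
#'
#' @param motif a \code{TFGeneNetwork}.
#' @param ppi TF x TF matrix.
#' @param coexpr gene x gene matrix.
#' @return list(motif, ppi, coexpr) aligned on common TFs/genes.
#' @export
alignNetworks <- function(motif, ppi, coexpr) {
  m <- networkMatrix(motif)
  tfs <- intersect(rownames(m), rownames(ppi))
  genes <- intersect(colnames(m), colnames(coexpr))
  drop_g <- setdiff(colnames(m), genes)
  if (length(drop_g))
    message(length(drop_g), " gene(s) dropped from networks: ",
            paste(utils::head(drop_g, 5), collapse = ", "),
            if (length(drop_g) > 5) ", ..." else "")
  list(motif = methods::new("TFGeneNetwork",
                            matrix = m[tfs, genes, drop = FALSE],
                            mode = motif@mode),
       ppi = ppi[tfs, tfs, drop = FALSE],
       coexpr = coexpr[genes, genes, drop = FALSE])
}
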