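#' Row/column z-score normalization of a network matrix
#'
#' Each entry becomes (z_row + z_col) / sqrt(2), where z_row and z_col are
#' the entry's z-scores within its row and column (sample sd). Entries in
#' constant rows or columns fall back to the overall z-score of the matrix;
#' a fully constant matrix maps to all zeros.
#'
#' @param M numeric matrix (finite entries).
#' @return normalized matrix of the same shape and dimnames.
#' @export
normalizeNetwork <- function(M) {
  stopifnot(all(is.finite(M)))
  rmu <- rowMeans(M); rsd <- apply(M, 1, stats::sd)
  cmu <- colMeans(M); csd <- apply(M, 2, stats::sd)
  omu <- mean(M); osd <- stats::sd(as.vector(M))
  oz <- if (is.na(osd) || osd == 0) M * 0 else (M - omu) / osd
  zr <- (M - rmu) / rsd
  zc <- sweep(sweep(M, 2, cmu), 2, csd, "/")
  badr <- !is.finite(rsd) | rsd == 0
  badc <- !is.finite(csd) | csd == 0
  if (any(badr)) zr[badr, ] <- oz[badr, ]
  if (any(badc)) zc[, badc] <- oz[, badc]
  out <- (zr + zc) / sqrt(2)
  dimnames(out) <- dimnames(M)
  out
}

#' Continuous Tanimoto similarity between row vectors of X and columns of Y
#'
#' T[i,j] = (x_i . y_j) / sqrt(||x_i||^2 + ||y_j||^2 - |x_i . y_j|), the
#' similarity kernel of the PANDA message-passing updates. The denominator is
#' floored at 1e-10.
#'
#' @param X matrix (n x k).
#' @param Y matrix (k x m).
#' @return n x m similarity matrix.
#' @export
tanimoto <- function(X, Y) {
  XY <- X %*% Y
  den <- sqrt(outer(rowSums(X^2), colSums(Y^2), "+") - abs(XY))
  XY / pmax(den, 1e-10)
}

# PANDA diagonal damping: the diagonal of an implied cooperativity /
# co-regulation matrix is replaced by the off-diagonal row sd inflated by an
# iteration-dependent factor, preventing self-similarity from dominating.
.updateDiagonal <- function(M, update, step) {
  num <- nrow(M)
  diag(M) <- NA
  dsd <- apply(M, 1, stats::sd, na.rm = TRUE)
  dsd[!is.finite(dsd)] <- 0
  diag(M) <- dsd * num * exp(2 * update * step)
  M
}

#' Fit a PANDA gene regulatory network
#'
#' Message passing between a motif prior W (TF x gene), a TF cooperativity
#' network P (PPI) and a gene co-regulation network C (co-expression). All
#' three are z-score normalized, then iterated:
#' responsibility R = tanimoto(P, W), availability A = tanimoto(W, C),
#' W <- (1-u) W + u (R+A)/2; P and C are moved toward the cooperativity /
#' co-regulation implied by W at the same rate u with diagonal damping.
#' Iteration stops when the Hamming distance mean(|W_t - W_{t-1}|) drops
#' below \code{tol}; with u = 0 the network is returned unchanged after one
#' iteration (fixed point). The algorithm is deterministic.
#'
#' @param motif \code{TFGeneNetwork} or TF x gene matrix (the prior).
#' @param ppi TF x TF symmetric matrix with unit diagonal.
#' @param coexpr gene x gene symmetric correlation matrix.
#' @param update message-passing update rate u in (0, 1]; 0 allowed as the
#'   degenerate no-update case. Default 0.1.
#' @param tol Hamming-distance convergence threshold (default 0.001).
#' @param max_iter iteration cap (default 200); non-convergence warns.
#' @return a \code{\linkS4class{PandaResult}}; \code{\link{pandaW}} extracts
#'   the fitted edge weights.
#' @export
pandaFit <- function(motif, ppi, coexpr, update = 0.1, tol = 0.001,
                     max_iter = 200L) {
  W0 <- if (is(motif, "TFGeneNetwork")) networkMatrix(motif) else motif
  if (!identical(rownames(W0), rownames(ppi)) ||
      !identical(rownames(ppi), colnames(ppi)))
    stop("TF labels of motif and ppi must match")
  if (!identical(colnames(W0), rownames(coexpr)) ||
      !identical(rownames(coexpr), colnames(coexpr)))
    stop("gene labels of motif and coexpr must match")
  if (update < 0 || update > 1) stop("update must be in [0,1]")
  W <- normalizeNetwork(W0)
  P <- normalizeNetwork(ppi)
  C <- normalizeNetwork(coexpr)
  hseq <- numeric(0)
  step <- 0L
  converged <- FALSE
  repeat {
    R <- tanimoto(P, W)
    A <- tanimoto(W, C)
    Wnew <- (1 - update) * W + update * (R + A) / 2
    h <- mean(abs(Wnew - W))
    hseq <- c(hseq, h)
    W <- Wnew
    if (h < tol) { converged <- TRUE; break }
    if (step + 1L >= max_iter) break
    co_tf <- .updateDiagonal(tanimoto(W, t(W)), update, step)
    P <- (1 - update) * P + update * co_tf
    co_gene <- .updateDiagonal(tanimoto(t(W), W), update, step)
    C <- (1 - update) * C + update * co_gene
    step <- step + 1L
  }
  if (!converged)
    warning("PANDA did not reach tol ", tol, " within ", max_iter,
            " iterations (last Hamming distance ",
            signif(utils::tail(hseq, 1), 4), ")")
  dimnames(W) <- dimnames(W0)
  methods::new("PandaResult", regulatory = W, cooperativity = P,
               coregulation = C, hamming = hseq,
               converged = converged, update = update)
}

#' Long-format edge list of a TF x gene weight matrix
#'
#' @param W \code{TFGeneNetwork}, \code{PandaResult} or labelled matrix.
#' @return data.frame: \code{tf}, \code{gene_id}, \code{weight}.
#' @export
edgeList <- function(W) {
  m <- if (is(W, "TFGeneNetwork")) networkMatrix(W)
       else if (is(W, "PandaResult")) pandaW(W) else W
  data.frame(tf = rep(rownames(m), times = ncol(m)),
             gene_id = rep(colnames(m), each = nrow(m)),
             weight = as.vector(m), stringsAsFactors = FALSE)
}
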