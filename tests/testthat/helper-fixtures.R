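suppressPackageStartupMessages({
  library(GenomicRanges)
})

# Build a GeneAnnotation from a compact transcript table.
# tx: data.frame(gene, tx, start, end, strand); exons: data.frame(tx, start, end)
makeAnnotation <- function(tx, exons, chrom = "chr1", biotype = "protein_coding") {
  genes <- do.call(rbind, lapply(split(tx, tx$gene), function(d)
    data.frame(gene = d$gene[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1])))
  g <- GRanges(chrom, IRanges(genes$start, genes$end), strand = genes$strand)
  g$gene_id <- genes$gene; g$biotype <- biotype
  t2 <- GRanges(chrom, IRanges(tx$start, tx$end), strand = tx$strand)
  t2$tx_id <- tx$tx; t2$gene_id <- tx$gene
  exs <- merge(exons, tx[, c("tx", "gene", "strand")], by = "tx")
  e2 <- GRanges(chrom, IRanges(exs$start, exs$end), strand = exs$strand)
  e2$tx_id <- exs$tx; e2$gene_id <- exs$gene
  new("GeneAnnotation", genes = g, transcripts = t2, exons = e2)
}

# one plus-strand gene with body [100001, 110000] (TSS 100001), single
# spanning transcript/exon -- the canonical window-arithmetic fixture
plusGene <- function() {
  makeAnnotation(
    tx = data.frame(gene = "G1", tx = "G1.t1", start = 100001, end = 110000,
                    strand = "+"),
    exons = data.frame(tx = "G1.t1", start = 100001, end = 110000))
}

minusGene <- function() {
  makeAnnotation(
    tx = data.frame(gene = "G1", tx = "G1.t1", start = 100001, end = 110000,
                    strand = "-"),
    exons = data.frame(tx = "G1.t1", start = 100001, end = 110000))
}

peakGR <- function(starts, ends, tf = "TFA", signal = 1, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(starts, ends))
  gr$tf <- tf; gr$signal <- signal
  gr
}

# ---- independent naive-loop PANDA reference --------------------------------
# Literal element-wise implementation of the same contract, for the oracle
# equivalence test; shares no code with pandaFit.
refNormalize <- function(M) {
  out <- matrix(0, nrow(M), ncol(M))
  omu <- mean(M); osd <- sd(as.vector(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    r <- M[i, ]; cc <- M[, j]
    zr <- if (sd(r) > 0) (M[i, j] - mean(r)) / sd(r)
          else if (osd > 0) (M[i, j] - omu) / osd else 0
    zc <- if (sd(cc) > 0) (M[i, j] - mean(cc)) / sd(cc)
          else if (osd > 0) (M[i, j] - omu) / osd else 0
    out[i, j] <- (zr + zc) / sqrt(2)
  }
  out
}

refTanimoto <- function(X, Y) {
  out <- matrix(0, nrow(X), ncol(Y))
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(Y))) {
    num <- sum(X[i, ] * Y[, j])
    den <- sqrt(sum(X[i, ]^2) + sum(Y[, j]^2) - abs(num))
    out[i, j] <- num / max(den, 1e-10)
  }
  out
}

refUpdateDiagonal <- function(M, update, step) {
  num <- nrow(M)
  for (i in seq_len(num)) {
    off <- M[i, -i]
    M[i, i] <- sd(off) * num * exp(2 * update * step)
  }
  M
}

refPanda <- function(W0, P0, C0, update = 0.1, tol = 0.001, max_iter = 200) {
  W <- refNormalize(W0); P <- refNormalize(P0); C <- refNormalize(C0)
  step <- 0
  repeat {
    R <- refTanimoto(P, W)
    A <- refTanimoto(W, C)
    Wnew <- (1 - update) * W + update * (R + A) / 2
    h <- mean(abs(Wnew - W))
    W <- Wnew
    if (h < tol) break
    if (step + 1 >= max_iter) break
    P <- (1 - update) * P + update * refUpdateDiagonal(refTanimoto(W, t(W)),
                                                       update, step)
    C <- (1 - update) * C + update * refUpdateDiagonal(refTanimoto(t(W), W),
                                                       update, step)
    step <- step + 1
  }
  dimnames(W) <- dimnames(W0)
  W
}

# ---- exact PWM-scan oracle: enumerate all 4^L k-mers -----------------------
# Returns function(kmer) -> exact tail p-value under the background, using
# the same pseudocount and score discretization contract as the scanner.
enumPwmOracle <- function(pwm, pseudocount = 1e-3, res = 1e-3) {
  L <- nrow(pwm$probs)
  p <- pwm$probs + pseudocount
  p <- p / rowSums(p)
  ktab <- round(log2(sweep(p, 2, pwm$background, "/")) / res)
  combos <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(combos)); probs <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    idx <- combos[r, ]
    scores[r] <- sum(ktab[cbind(seq_len(L), idx)])
    probs[r] <- prod(pwm$background[idx])
  }
  function(kmer) {
    idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
    s <- sum(ktab[cbind(seq_len(L), idx)])
    sum(probs[scores >= s])
  }
}

# brute-force O(n*m) interval overlap counter (1-based closed)
bruteOverlapPairs <- function(peaks_df, windows_df) {
  out <- list()
  for (i in seq_len(nrow(peaks_df))) for (j in seq_len(nrow(windows_df))) {
    if (peaks_df$start[i] <= windows_df$end[j] &&
        peaks_df$end[i] >= windows_df$start[j])
      out[[length(out) + 1L]] <- data.frame(tf = peaks_df$tf[i],
                                            gene_id = windows_df$gene_id[j])
  }
  if (!length(out)) return(data.frame(tf = character(), gene_id = character()))
  unique(do.call(rbind, out))
}
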