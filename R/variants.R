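#' Filter variants to rare ones (MAF strictly below threshold)
#'
#' @param variants data.frame with a \code{maf} column.
#' @param maf_threshold rarity threshold (default 0.01); the boundary value
#'   itself is dropped (strict inequality).
#' @return the rare subset of \code{variants}.
#' @export
filterRare <- function(variants, maf_threshold = 0.01) {
  if (!"maf" %in% names(variants)) stop("variants need a maf column")
  variants[variants$maf < maf_threshold, , drop = FALSE]
}

#' Keep binding z-scores that significantly perturb a TFBS
#'
#' @param zscores data.frame with a \code{pvalue} column (QBiC-Pred-style
#'   per-variant, per-peak binding-change tests).
#' @param p_threshold significance threshold (default 1e-4); records with
#'   \code{pvalue <= p_threshold} are retained.
#' @return the significant subset.
#' @export
significantBinding <- function(zscores, p_threshold = 1e-4) {
  if (!"pvalue" %in% names(zscores)) stop("zscores need a pvalue column")
  zscores[zscores$pvalue <= p_threshold, , drop = FALSE]
}

#' Effect-scaled binding z-score for one (variant, TF, gene)
#'
#' beta_bar * mean(z) over the TF's significantly perturbed peaks in the
#' gene's regulatory region. An empty peak set is an error (the pair is
#' skipped upstream, not zero-filled).
#'
#' @param z numeric vector of per-peak binding z-scores (length >= 1).
#' @param beta_bar the TF's averaged elastic-net effect estimate.
#' @return scaled z-score.
#' @export
scaledZ <- function(z, beta_bar) {
  if (length(z) == 0L) stop("empty peak set: pair should be skipped")
  beta_bar * mean(z)
}

#' Merge score of a variant for a gene
#'
#' The mean over TFs (with defined effect-scaled z-scores for this
#' variant-gene) of those scores.
#'
#' @param per_tf numeric vector, one effect-scaled z per TF (length >= 1).
#' @return merge score.
#' @export
mergeScore <- function(per_tf) {
  if (length(per_tf) == 0L) stop("no TFs with defined scores for this pair")
  mean(per_tf)
}

#' Per-variant, per-gene merge scores over a z-score table
#'
#' Applies the effect-scaled z-score and merge-score averaging across a table
#' of significant binding z-scores: for each (variant, gene), per-TF peak
#' means are multiplied by that TF's averaged effect estimate, then averaged
#' over TFs. Setting all effect estimates to 1 yields the aggregate z-score
#' variant (\code{\link{aggregateZTable}}).
#'
#' @param zscores data.frame: \code{variant_id}, \code{tf}, \code{gene_id},
#'   \code{zscore} (already filtered to significant records).
#' @param beta_bar named numeric, effect estimate per TF; TFs absent from it
#'   are skipped.
#' @return data.frame: \code{variant_id}, \code{gene_id}, \code{score}.
#' @export
mergeScoreTable <- function(zscores, beta_bar) {
  keep <- zscores$tf %in% names(beta_bar)
  z <- zscores[keep, , drop = FALSE]
  if (nrow(z) == 0L)
    return(data.frame(variant_id = character(), gene_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  ptf <- stats::aggregate(z$zscore,
    by = list(variant_id = z$variant_id, gene_id = z$gene_id, tf = z$tf),
    FUN = mean)
  ptf$Z <- unname(beta_bar[ptf$tf]) * ptf$x
  out <- stats::aggregate(ptf$Z,
    by = list(variant_id = ptf$variant_id, gene_id = ptf$gene_id),
    FUN = mean)
  names(out)[3] <- "score"
  out
}

#' Aggregate (effect-free) z-score table
#'
#' Identical to \code{\link{mergeScoreTable}} with every TF effect estimate
#' set to 1: the unweighted impact of a variant on TF binding alone.
#'
#' @inheritParams mergeScoreTable
#' @param tfs TFs to include (default: all in the table).
#' @return data.frame: \code{variant_id}, \code{gene_id}, \code{score}.
#' @export
aggregateZTable <- function(zscores, tfs = unique(zscores$tf)) {
  mergeScoreTable(zscores, stats::setNames(rep(1, length(tfs)), tfs))
}

#' Scale scores into [-1, 1]
#'
#' x -> x / max(|x|): the extreme maps to +/-1 and 0 stays 0. All-zero input
#' is returned unchanged.
#'
#' @param x numeric vector (length >= 1).
#' @return scaled vector in [-1, 1].
#' @export
scaleScores <- function(x) {
  if (!length(x)) stop("empty score vector")
  m <- max(abs(x))
  if (m == 0) return(x)
  x / m
}

# Liu three-moment (modified) p-value for Q ~ sum lambda_i chi^2_1
.liuPvalue <- function(Q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  tstar <- (Q - muQ) / sigmaQ
  muX <- l + d; sigmaX <- sqrt(2) * a
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = d, lower.tail = FALSE)
}

#' Weighted sequence kernel association test (SKAT)
#'
#' Variance-component score test of a variant set against a quantitative
#' phenotype. The null model regresses the phenotype on an intercept plus
#' covariates by least squares; with residuals r and residual variance
#' sigma^2, Q = r' G diag(w)^2 G' r / sigma^2 (weights enter squared, so
#' their sign is irrelevant). The p-value comes from the mixture-of-chi-square
#' null via the Liu three-moment approximation, with the mixture eigenvalues
#' computed exactly from the covariate-projected kernel. Missing dosages are
#' imputed to twice the allele frequency (the column mean).
#'
#' @param genotypes n x m dosage matrix (0/1/2, NA allowed).
#' @param phenotype length-n numeric.
#' @param covariates n x k numeric matrix or NULL.
#' @param weights length-m per-variant weights (e.g. scaled merge scores).
#' @return list(Q, pvalue, n_variants).
#' @export
skatTest <- function(genotypes, phenotype, covariates = NULL, weights) {
  G <- as.matrix(genotypes)
  n <- nrow(G); m <- ncol(G)
  if (length(phenotype) != n) stop("phenotype length mismatch")
  if (length(weights) != m) stop("weights length mismatch")
  if (m < 2) stop("need at least 2 variants")
  if (all(weights == 0)) return(list(Q = 0, pvalue = 1, n_variants = m))
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  Xc <- if (is.null(covariates)) matrix(1, n, 1)
        else cbind(1, as.matrix(covariates))
  if (n <= ncol(Xc) + 2) stop("too few individuals for the covariate model")
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) stop("singular covariate matrix")
  r <- stats::residuals(stats::lm.fit(Xc, phenotype))
  df <- n - ncol(Xc)
  sigma2 <- sum(r^2) / df
  Gw <- sweep(G, 2, weights, "*")
  Q <- sum(as.numeric(crossprod(Gw, r))^2) / sigma2
  B <- Gw - Xc %*% qr.coef(qx, Gw)      # (I - H) G W
  K <- crossprod(B)
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda, 0)]
  if (!length(lambda) || Q == 0)
    return(list(Q = Q, pvalue = 1, n_variants = m))
  list(Q = Q, pvalue = min(1, .liuPvalue(Q, lambda)), n_variants = m)
}

#' Run weighted SKAT gene-by-gene
#'
#' @param genotypes n x M dosage matrix with variant-id column names.
#' @param phenotypes n x G matrix of per-gene phenotypes (normalized
#'   expression), gene ids as column names.
#' @param covariates n x k matrix or NULL.
#' @param scores data.frame: \code{variant_id}, \code{gene_id}, \code{score}
#'   (already scaled to [-1,1]); each gene is tested with its own variant
#'   set and weights.
#' @param p_adjust_threshold significance threshold; defaults to Bonferroni
#'   0.05 / number of genes tested.
#' @return data.frame: \code{gene_id}, \code{n_variants}, \code{Q},
#'   \code{pvalue}, \code{significant}.
#' @export
skatByGene <- function(genotypes, phenotypes, covariates = NULL, scores,
                       p_adjust_threshold = NULL) {
  genes <- intersect(unique(scores$gene_id), colnames(phenotypes))
  rows <- lapply(genes, function(g) {
    sg <- scores[scores$gene_id == g & scores$score != 0, , drop = FALSE]
    vs <- intersect(sg$variant_id, colnames(genotypes))
    if (length(vs) < 2) return(NULL)
    w <- sg$score[match(vs, sg$variant_id)]
    res <- skatTest(genotypes[, vs, drop = FALSE], phenotypes[, g],
                    covariates, w)
    data.frame(gene_id = g, n_variants = length(vs), Q = res$Q,
               pvalue = res$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(gene_id = character(),
                                      n_variants = integer(), Q = numeric(),
                                      pvalue = numeric(),
                                      significant = logical()))
  if (is.null(p_adjust_threshold)) p_adjust_threshold <- 0.05 / nrow(out)
  out$significant <- out$pvalue < p_adjust_threshold
  out
}

#' Toy PWM-delta binding-disruption score (synthetic-fixture stub)
#'
#' A stand-in for an external variant-effect predictor, used only to generate
#' synthetic binding z-scores: the log-odds difference between the alt and
#' ref k-mers under a PWM, at the best-scoring ref position.
#'
#' @param pwm a PWM from \code{\link{newPWM}}.
#' @param ref_kmer,alt_kmer equal-length DNA strings covering the motif.
#' @return numeric log-odds delta (alt minus ref, bits).
#' @export
pwmDeltaScore <- function(pwm, ref_kmer, alt_kmer) {
  stopifnot(nchar(ref_kmer) == nchar(alt_kmer))
  sc <- function(km) {
    h <- scanPWM(km, pwm, p_threshold = 1)
    if (nrow(h) == 0) return(NA_real_)
    max(h$score)
  }
  a <- sc(alt_kmer); r <- sc(ref_kmer)
  if (is.na(a) || is.na(r)) return(0)
  a - r
}
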