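#' Pivot a GRN edge list into a gene x TF feature matrix
#'
#' Rows are genes (regression observations), columns TFs (features); missing
#' edges are 0. Duplicate (tf, gene) edges are an error.
#'
#' @param edges data.frame: \code{tf}, \code{gene_id}, \code{weight}.
#' @param genes,tfs label vectors fixing row/column order.
#' @return numeric gene x TF matrix.
#' @export
assembleFeatures <- function(edges, genes, tfs) {
  key <- paste0(edges$tf, "\r", edges$gene_id)
  if (anyDuplicated(key)) stop("duplicate (tf, gene) edges in edge list")
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  i <- cbind(match(edges$gene_id, genes), match(edges$tf, tfs))
  ok <- stats::complete.cases(i)
  X[i[ok, , drop = FALSE]] <- edges$weight[ok]
  X
}

.lambdaGrid <- function() exp(seq(log(1e1), log(1e-4), length.out = 50))

#' Elastic-net fit of log-expression on GRN features
#'
#' One random 80/20 train/test split (controlled by \code{seed}); features
#' are standardized column-wise on the training set inside the fit, the
#' penalty strength is chosen by inner k-fold cross-validation (default 20
#' folds) minimizing MSE over a 50-point log-spaced grid on [1e-4, 10], and
#' coefficients are reported on the standardized scale so they are comparable
#' across TFs. Test-set MSE and Pearson correlation are returned; a constant
#' prediction yields PCC 0 with a warning.
#'
#' @param X gene x TF feature matrix (>= 25 rows, >= 2 columns).
#' @param y named numeric response (log10 FPKM), aligned with rows of X.
#' @param alpha_ratio elastic-net mixing parameter (1 = lasso, 0 = ridge);
#'   default 0.5.
#' @param train_frac training fraction (default 0.8).
#' @param inner_folds inner CV folds (default 20).
#' @param seed RNG seed for the split and fold assignment.
#' @return list with \code{fit} (coefficients, intercept, lambda, seed) and
#'   \code{perf} (iteration_id = seed, mse, pcc).
#' @export
fitENet <- function(X, y, alpha_ratio = 0.5, train_frac = 0.8,
                    inner_folds = 20L, seed = 1L) {
  n <- nrow(X)
  if (n < 25) stop("need at least 25 genes to fit")
  if (ncol(X) < 2) stop("need at least 2 feature columns")
  if (stats::sd(y) == 0) stop("constant response")
  ntrain <- floor(train_frac * n)
  if (inner_folds > ntrain) stop("inner_folds exceeds training-set size")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  tr <- perm[seq_len(ntrain)]; te <- perm[-seq_len(ntrain)]
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  live <- is.finite(sdv) & sdv > 0
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (sum(live) < 2) {
    warning("fewer than 2 informative features; intercept-only model")
    pred <- rep(mean(y[tr]), length(te))
    mse <- mean((y[te] - pred)^2)
    warning("constant prediction; PCC reported as 0")
    return(list(fit = list(coefficients = coefs, intercept = mean(y[tr]),
                           lambda = NA_real_, seed = seed),
                perf = list(iteration_id = seed, mse = mse, pcc = 0)))
  }
  Xs <- sweep(sweep(X[, live, drop = FALSE], 2, mu[live]), 2, sdv[live], "/")
  foldid <- sample(rep(seq_len(inner_folds), length.out = ntrain))
  cv <- glmnet::cv.glmnet(Xs[tr, , drop = FALSE], y[tr],
                          alpha = alpha_ratio, lambda = .lambdaGrid(),
                          foldid = foldid, standardize = FALSE,
                          family = "gaussian", type.measure = "mse")
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  coefs[live] <- cf[-1]
  intercept <- cf[1]
  pred <- as.numeric(intercept + Xs[te, , drop = FALSE] %*% cf[-1])
  mse <- mean((y[te] - pred)^2)
  if (stats::sd(pred) == 0) {
    warning("constant prediction; PCC reported as 0")
    pcc <- 0
  } else pcc <- stats::cor(y[te], pred)
  list(fit = list(coefficients = coefs, intercept = intercept,
                  lambda = cv$lambda.min, seed = seed),
       perf = list(iteration_id = seed, mse = mse, pcc = pcc))
}

#' Repeat the elastic-net fit over resampling iterations
#'
#' Iteration n (n = 0 .. iterations-1) uses seed \code{base_seed + n}, so a
#' single iteration reproduces \code{fitENet(seed = base_seed)} exactly and
#' reruns are bitwise identical.
#'
#' @inheritParams fitENet
#' @param iterations number of resampling iterations (default 20).
#' @param base_seed base RNG seed.
#' @return list(fits, perf): lists of per-iteration fit and performance
#'   records.
#' @export
repeatFit <- function(X, y, alpha_ratio = 0.5, train_frac = 0.8,
                      inner_folds = 20L, iterations = 20L, base_seed = 1L) {
  res <- lapply(seq_len(iterations) - 1L, function(n)
    fitENet(X, y, alpha_ratio = alpha_ratio, train_frac = train_frac,
            inner_folds = inner_folds, seed = base_seed + n))
  list(fits = lapply(res, `[[`, "fit"),
       perf = lapply(res, `[[`, "perf"))
}

#' Compare two models' resampled performance (Wilcoxon rank sum)
#'
#' Two-sided Wilcoxon rank-sum tests on the PCC lists and the MSE lists of
#' two models; exact null when the combined sample size is at most 20 and
#' there are no ties, normal approximation with continuity correction
#' otherwise.
#'
#' @param perfA,perfB lists of performance records from \code{\link{repeatFit}}.
#' @return data.frame: \code{metric}, \code{statistic}, \code{pvalue},
#'   \code{median_A}, \code{median_B}.
#' @export
compareModels <- function(perfA, perfB) {
  if (length(perfA) < 3 || length(perfB) < 3)
    stop("need at least 3 performance records per model")
  one <- function(metric) {
    a <- vapply(perfA, `[[`, numeric(1), metric)
    b <- vapply(perfB, `[[`, numeric(1), metric)
    exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
    wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                             exact = exact, correct = TRUE)
    data.frame(metric = metric, statistic = unname(wt$statistic),
               pvalue = wt$p.value, median_A = stats::median(a),
               median_B = stats::median(b), stringsAsFactors = FALSE)
  }
  rbind(one("pcc"), one("mse"))
}

#' Average per-TF effect estimates over resampling iterations
#'
#' The per-TF arithmetic mean of the standardized elastic-net coefficients
#' across all fits; positive means activating, negative repressive.
#'
#' @param fits list of fit records sharing one feature set.
#' @return an \code{\linkS4class{EffectEstimates}} (bins unset).
#' @export
averageEffects <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  nm <- names(fits[[1]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), nm))
      stop("fits have mismatched feature sets")
  B <- vapply(fits, `[[`, numeric(length(nm)), "coefficients")
  beta <- if (is.matrix(B)) rowMeans(B) else mean(B)
  methods::new("EffectEstimates", beta = stats::setNames(beta, nm),
               bins = integer(0))
}

#' Quintile-bin TF effect estimates
#'
#' TFs sorted ascending by mean effect are split into 5 contiguous bins whose
#' sizes differ by at most one (any remainder goes to the lower bins first);
#' bin 1 holds the most repressive, bin 5 the most activating TFs. Tied
#' values spanning a bin boundary are kept together in the lower bin.
#'
#' @param effects an \code{EffectEstimates} (>= 5 TFs).
#' @return the \code{EffectEstimates} with bins filled.
#' @export
quintileBins <- function(effects) {
  beta <- effectBeta(effects)
  n <- length(beta)
  if (n < 5) stop("need at least 5 TFs to form quintiles")
  o <- order(beta, names(beta))
  sizes <- rep(n %/% 5, 5) + (seq_len(5) <= n %% 5)
  bin_sorted <- rep(seq_len(5), times = sizes)
  # keep ties together: every element equal in value to the one before it
  # inherits that element's bin
  bs <- beta[o]
  for (i in 2:n) if (bs[i] == bs[i - 1]) bin_sorted[i] <- bin_sorted[i - 1]
  bins <- integer(n)
  bins[o] <- bin_sorted
  methods::new("EffectEstimates", beta = beta,
               bins = stats::setNames(bins, names(beta)))
}
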