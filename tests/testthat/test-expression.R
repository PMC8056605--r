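simXY <- function(n = 500, p = 10, beta1 = 2, noise = 0.01, seed = 123) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("G%03d", 1:n), paste0("x", 1:p)))
  y <- beta1 * X[, 1] + rnorm(n, 0, noise)
  names(y) <- rownames(X)
  list(X = X, y = y)
}

test_that("assembleFeatures pivots edge lists order-invariantly", {
  e <- data.frame(tf = c("t1", "t2", "t1", "t2"),
                  gene_id = c("g1", "g1", "g2", "g2"),
                  weight = c(1, 2, 3, 4))
  X <- assembleFeatures(e, c("g1", "g2"), c("t1", "t2"))
  expect_equal(X, matrix(c(1, 3, 2, 4), 2, 2,
                         dimnames = list(c("g1", "g2"), c("t1", "t2"))))
  Xs <- assembleFeatures(e[sample(4), ], c("g1", "g2"), c("t1", "t2"))
  expect_equal(Xs, X)
  expect_error(assembleFeatures(rbind(e, e[1, ]), c("g1", "g2"),
                                c("t1", "t2")), "duplicate")
  one <- assembleFeatures(data.frame(tf = "t1", gene_id = "g1", weight = 7),
                          "g1", "t1")
  expect_equal(unname(one), matrix(7))
})

test_that("fitENet recovers a planted coefficient within 10%", {
  d <- simXY()
  res <- fitENet(d$X, d$y, seed = 1)
  # coefficients are on the standardized scale; translate back via the
  # training-column sd (~1 for N(0,1) features)
  sdx <- apply(d$X, 2, sd)
  b_raw <- res$fit$coefficients / sdx
  expect_lt(abs(b_raw["x1"] - 2) / 2, 0.10)
  expect_true(all(abs(b_raw[-1]) < 0.05))
  expect_lt(res$perf$mse, 0.05)
  expect_gt(res$perf$pcc, 0.99)
})

test_that("fitENet handles degenerate inputs as specified", {
  d <- simXY(n = 100)
  Z <- matrix(0, 100, 5, dimnames = list(rownames(d$X), paste0("x", 1:5)))
  expect_warning(expect_warning(res <- fitENet(Z, d$y, seed = 1),
                                "intercept-only"), "PCC reported as 0")
  expect_equal(res$perf$pcc, 0)
  expect_true(all(res$fit$coefficients == 0))
  expect_error(fitENet(d$X[1:10, ], d$y[1:10], seed = 1), "25 genes")
  expect_error(fitENet(d$X, rep(1, 100), seed = 1), "constant")
  expect_error(fitENet(d$X, d$y, inner_folds = 1000, seed = 1),
               "inner_folds")
})

test_that("the lasso/ridge ends of the penalty behave as expected", {
  d <- simXY()
  ridge <- fitENet(d$X, d$y, alpha_ratio = 0, seed = 1)
  expect_true(all(ridge$fit$coefficients != 0))  # ridge never zeroes exactly
  lasso <- fitENet(d$X, d$y, alpha_ratio = 1, seed = 1)
  expect_gte(sum(lasso$fit$coefficients == 0), 8)  # sparse on 9 null features
})

test_that("repeatFit is seeded, deterministic, and accurate on recovery data", {
  d <- simXY(n = 200, noise = 0.3)
  one <- repeatFit(d$X, d$y, iterations = 1, base_seed = 42)
  direct <- fitENet(d$X, d$y, seed = 42)
  expect_identical(one$fits[[1]], direct$fit)
  expect_identical(one$perf[[1]], direct$perf)
  again <- repeatFit(d$X, d$y, iterations = 3, base_seed = 42)
  twice <- repeatFit(d$X, d$y, iterations = 3, base_seed = 42)
  expect_identical(again, twice)
  full <- repeatFit(d$X, d$y, iterations = 20, base_seed = 42)
  expect_gt(median(vapply(full$perf, `[[`, numeric(1), "pcc")), 0.9)
  expect_true(all(vapply(full$perf, `[[`, numeric(1), "mse") >= 0))
})

test_that("compareModels runs exact Wilcoxon rank-sum tests where possible", {
  pr <- function(v) lapply(v, function(x) list(pcc = x, mse = x + 10))
  same <- compareModels(pr(c(1, 2, 3, 4)), pr(c(1, 2, 3, 4)))
  expect_true(all(same$pvalue > 0.65))  # identical up to ties handling
  sep <- compareModels(pr(c(1, 2, 3)), pr(c(10, 20, 30)))
  # the most extreme ranking at n=3,3: exact two-sided p = 2/20
  expect_equal(sep$pvalue, c(0.1, 0.1))
  expect_equal(sep$statistic, c(0, 0))  # complete separation
  expect_error(compareModels(pr(1:2), pr(1:5)), "at least 3")
})

test_that("averageEffects is the per-TF mean across fits", {
  mk <- function(b) list(coefficients = c(tfA = b[1], tfB = b[2]))
  one <- averageEffects(list(mk(c(0.1, -0.5))))
  expect_equal(effectBeta(one), c(tfA = 0.1, tfB = -0.5))
  two <- averageEffects(list(mk(c(0.1, 0)), mk(c(0.3, 0))))
  expect_equal(effectBeta(two)[["tfA"]], 0.2)
  four <- averageEffects(lapply(c(0.6, 0.6, 0.7, 0.6334 * 4 - 1.9),
                                function(b) mk(c(b, 0))))
  expect_equal(effectBeta(four)[["tfA"]],
               mean(c(0.6, 0.6, 0.7, 0.6334 * 4 - 1.9)))
  bad <- list(mk(c(1, 2)), list(coefficients = c(tfA = 1, tfC = 2)))
  expect_error(averageEffects(bad), "mismatched")
})

test_that("quintileBins partitions ascending effects into 5 near-equal bins", {
  mkEff <- function(b) {
    names(b) <- sprintf("tf%02d", seq_along(b))
    averageEffects(list(list(coefficients = b)))
  }
  ten <- quintileBins(mkEff(seq(-1, 1, length.out = 10)))
  expect_equal(as.vector(table(effectBins(ten))), rep(2L, 5))
  # most negative in bin 1, most positive in bin 5
  b <- effectBeta(ten); bins <- effectBins(ten)
  expect_equal(unname(bins[which.min(b)]), 1L)
  expect_equal(unname(bins[which.max(b)]), 5L)
  # 7 TFs: remainder assigned from bin 1 upward -> sizes 2,2,1,1,1
  seven <- quintileBins(mkEff(seq_len(7)))
  expect_equal(as.vector(table(effectBins(seven))), c(2L, 2L, 1L, 1L, 1L))
  # ties spanning a boundary collapse into the lower bin
  tied <- quintileBins(mkEff(c(1, 2, 2, 3, 4, 5, 6)))
  bt <- effectBins(tied)
  expect_equal(unname(bt[2]), unname(bt[3]))
  expect_error(quintileBins(mkEff(1:4)), "at least 5")
})
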