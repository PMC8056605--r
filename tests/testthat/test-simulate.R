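# small desk-scale config shared across simulator tests
smallCfg <- function(seed = 5)
  simConfig(n_genes = 24, n_tfs = 6, n_samples = 30, n_individuals = 120,
            module_size = 8, seed = seed)

test_that("simConfig validates and derives planted effects from the seed", {
  expect_error(simConfig(), "seed")
  cfg <- smallCfg()
  expect_length(cfg$effect_sizes, 6)
  expect_true(any(cfg$effect_sizes > 0) && any(cfg$effect_sizes < 0))
  # same seed -> same planted effects
  expect_identical(cfg$effect_sizes, smallCfg()$effect_sizes)
  expect_error(
    simulateAnnotation(simConfig(n_genes = 100, genome_length = 1e5,
                                 seed = 1), with_sequence = FALSE),
    "overcrowded")
})

test_that("simulateAnnotation is deterministic and structurally valid", {
  cfg <- smallCfg()
  a1 <- simulateAnnotation(cfg, with_sequence = FALSE)
  a2 <- simulateAnnotation(cfg, with_sequence = FALSE)
  expect_identical(a1$sites, a2$sites)
  expect_identical(as.data.frame(a1$annotation@genes),
                   as.data.frame(a2$annotation@genes))
  ann <- a1$annotation
  expect_length(ann@genes, cfg$n_genes)       # gene count as configured
  expect_true(validObject(ann))
  # genes do not overlap
  expect_equal(length(GenomicRanges::reduce(granges(ann@genes),
                                            ignore.strand = TRUE)),
               cfg$n_genes)
  # every gene has at least one regulator site; sites sit within 50 kb
  expect_true(all(ann@genes$gene_id %in% a1$sites$gene_id))
  tssv <- vapply(ann@genes$gene_id, function(g) geneTSS(ann, g), numeric(1))
  d <- abs(a1$sites$pos - tssv[a1$sites$gene_id])
  expect_true(all(d <= 50000))
})

test_that("simulated sequence carries the planted motif consensus", {
  cfg <- simConfig(n_genes = 4, n_tfs = 3, n_samples = 10,
                   n_individuals = 20, module_size = 2, seed = 9)
  a <- simulateAnnotation(cfg, with_sequence = TRUE)
  seqc <- as.character(a$sequence[[1]])
  hit <- 0
  for (i in seq_len(nrow(a$sites))) {
    cons <- multiGRN:::.consensus(a$pwms[[a$sites$tf[i]]])
    if (substr(seqc, a$sites$pos[i],
               a$sites$pos[i] + nchar(cons) - 1) == cons) hit <- hit + 1
  }
  # planting is in site order, so all but overwritten overlaps must match
  expect_gte(hit, nrow(a$sites) - 2)
})

test_that("simulateRegulation plants recoverable cis/trans structure", {
  cfg <- smallCfg()
  sim <- simulateAnnotation(cfg, with_sequence = FALSE)
  reg <- simulateRegulation(cfg, sim)
  expect_equal(dim(reg$expression), c(cfg$n_samples, cfg$n_genes))
  expect_true(all(reg$peaks$signal >= 0))
  # planted activators correlate positively with their targets' expression
  beta <- reg$truth$beta; B <- reg$truth$B_true
  act <- names(beta)[beta > 0.4]
  for (tf in act) {
    targets <- colnames(B)[B[tf, ] == 1]
    others <- setdiff(colnames(B), targets)
    expect_gt(mean(colMeans(reg$expression[, targets, drop = FALSE])),
              mean(colMeans(reg$expression[, others, drop = FALSE])))
  }
  # Hi-C contacts decay with distance in expectation (binned means)
  ann <- sim$annotation
  tssv <- vapply(ann@genes$gene_id, function(g) geneTSS(ann, g), numeric(1))
  d <- abs((reg$contacts$peak_start + reg$contacts$peak_end) / 2 -
             tssv[reg$contacts$gene_id])
  bins <- cut(d, c(0, 10000, 25000, 50000))
  mu <- tapply(reg$contacts$kr_contacts, bins, mean)
  expect_true(all(diff(mu) < 0))
  # determinism
  reg2 <- simulateRegulation(cfg, sim)
  expect_identical(reg$expression, reg2$expression)
  expect_identical(reg$contacts, reg2$contacts)
})

test_that("simulateGenotypes plants rare causal variants inside TFBS", {
  cfg <- smallCfg()
  sim <- simulateAnnotation(cfg, with_sequence = FALSE)
  reg <- simulateRegulation(cfg, sim)
  gen <- simulateGenotypes(cfg, sim, reg)
  expect_true(all(gen$variants$maf < 0.05))
  expect_equal(nrow(gen$variants), cfg$n_genes * cfg$n_variants_per_gene)
  expect_equal(dim(gen$genotypes),
               c(cfg$n_individuals, nrow(gen$variants)))
  expect_true(all(gen$genotypes %in% 0:2))
  # causal variants live inside binding sites of large-effect TFs
  cz <- gen$variants[gen$variants$causal, ]
  expect_gt(nrow(cz), 0)
  expect_true(all(abs(reg$truth$beta[cz$tf]) >= 0.3))
  expect_true(all(cz$gene_id %in% gen$causal_genes))
  # z-score records only for in-TFBS variants, with valid p-values
  expect_true(all(gen$zscores$pvalue > 0 & gen$zscores$pvalue <= 1))
  expect_true(all(gen$zscores$variant_id %in% gen$variants$variant_id))
  # regeneration is bitwise identical
  gen2 <- simulateGenotypes(cfg, sim, reg)
  expect_identical(gen$genotypes, gen2$genotypes)
  expect_identical(gen$zscores, gen2$zscores)
})

test_that("causal genes show inflated SKAT signal against matched null genes", {
  cfg <- smallCfg(seed = 6)
  sim <- simulateAnnotation(cfg, with_sequence = FALSE)
  reg <- simulateRegulation(cfg, sim)
  gen <- simulateGenotypes(cfg, sim, reg)
  z <- significantBinding(gen$zscores)
  ms <- mergeScoreTable(z, reg$truth$beta)
  ms$score <- scaleScores(ms$score)
  res <- skatByGene(gen$genotypes, gen$phenotypes, gen$covariates, ms,
                    p_adjust_threshold = 0.05)
  caus <- res$pvalue[res$gene_id %in% gen$causal_genes]
  null <- res$pvalue[!res$gene_id %in% gen$causal_genes]
  expect_gt(length(caus), 0)
  expect_lt(median(caus), 0.5)  # enrichment of small p-values at causal genes
  if (length(null) >= 3) expect_lt(median(caus), median(null))
})
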