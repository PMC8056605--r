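#' Default pipeline run configuration
#'
#' Stage parameters default to the framework's standard settings: 50 kb
#' flank, 5 kb promoter, motif-scan p 0.01, PANDA update 0.1 with Hamming
#' tolerance 0.001, elastic-net mixing 0.5 with 20 resampling iterations,
#' MAF threshold 0.01, binding-z p threshold 1e-4.
#'
#' @param outdir output directory for stage artifacts.
#' @param seed master seed for the synthetic inputs.
#' @return named list of parameters.
#' @export
defaultRunConfig <- function(outdir = "grn_run", seed = 1L) {
  list(outdir = outdir, seed = as.integer(seed),
       n_genes = 200L, n_tfs = 20L, n_samples = 50L, n_individuals = 300L,
       flank = 50000L, promoter = 5000L, fimo_p = 0.01,
       update = 0.1, tol = 0.001, max_iter = 200L,
       alpha_ratio = 0.5, iterations = 20L, train_frac = 0.8,
       inner_folds = 20L, maf = 0.01, qbic_p = 1e-4,
       scheme = "none", with_sequence = FALSE)
}

#' Read a YAML run configuration, filling defaults
#' @param file YAML file with any subset of the \code{\link{defaultRunConfig}}
#'   keys.
#' @return full configuration list.
#' @export
readRunConfig <- function(file) {
  user <- yaml::read_yaml(file)
  cfg <- defaultRunConfig()
  cfg[names(user)] <- user
  cfg
}

.stages <- c("simulate", "regions", "tfbs", "grn", "hic", "fit", "effects",
             "varscore", "skat")

.stageInputs <- function(name, d) {
  p <- function(...) file.path(d, c(...))
  switch(name,
    simulate = character(0),
    regions = p("annotation.gtf", "ctcf.bed"),
    tfbs = p("annotation.gtf", "ctcf.bed", "peaks.bed"),
    grn = p("tfbs.tsv", "ppi.tsv", "expression.tsv"),
    hic = p("tfbs.tsv", "contacts.tsv", "partition.tsv"),
    fit = p("panda_edges.tsv", "response.tsv"),
    effects = p("coefficients.tsv"),
    varscore = p("variants.tsv", "zscores.tsv", "effects.tsv"),
    skat = p("genotypes.tsv", "phenotypes.tsv", "covariates.tsv",
             "scores_merge.tsv", "scores_aggz.tsv"),
    stop("unknown stage: ", name))
}

.stageOutputs <- function(name, d) {
  p <- function(...) file.path(d, c(...))
  switch(name,
    simulate = p("annotation.gtf", "peaks.bed", "ctcf.bed", "ppi.tsv",
                 "expression.tsv", "contacts.tsv", "response.tsv",
                 "genotypes.tsv", "phenotypes.tsv", "covariates.tsv",
                 "zscores.tsv", "variants.tsv", "truth_beta.tsv"),
    regions = p("windows.bed", "promoters.bed", "introns.bed", "tss.tsv"),
    tfbs = p("tfbs.tsv", "partition.tsv", "affinity.tsv"),
    grn = p("motif.tsv", "coexpression.tsv", "ppi_matrix.tsv",
            "panda_edges.tsv"),
    hic = p("hic_weights.tsv", "motif_dp.tsv", "motif_up.tsv"),
    fit = p("performance.tsv", "coefficients.tsv"),
    effects = p("effects.tsv"),
    varscore = p("scores_merge.tsv", "scores_aggz.tsv"),
    skat = p("skat_merge.tsv", "skat_aggz.tsv"))
}

.manifestPath <- function(d) file.path(d, "manifest.tsv")

.inputsHash <- function(files, params) {
  md5 <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  paste(c(md5, params), collapse = "|")
}

.paramString <- function(config) {
  keep <- setdiff(names(config), "outdir")
  paste(sprintf("%s=%s", keep, vapply(config[keep], function(x)
    paste(format(x), collapse = ","), character(1))), collapse = ";")
}

.windowsFromFiles <- function(config) {
  ann <- readGeneAnnotation(file.path(config$outdir, "annotation.gtf"))
  ctcf <- readPeaksBED(file.path(config$outdir, "ctcf.bed"))
  regulatoryWindows(ann, ctcf, flank = config$flank,
                    promoter_length = config$promoter)
}

#' Run one pipeline stage
#'
#' Stages: simulate, regions, tfbs, grn, hic, fit, effects, varscore, skat.
#' Each stage reads the TSV/BED/GTF artifacts of its upstream stages from
#' \code{config$outdir}, writes its own, and appends a manifest line (stage,
#' input hashes, parameters, outputs). A rerun with unchanged inputs and
#' parameters is a no-op unless \code{force}.
#'
#' @param name stage name.
#' @param config list from \code{\link{defaultRunConfig}} /
#'   \code{\link{readRunConfig}}.
#' @param force rerun even if the manifest shows up-to-date outputs.
#' @return character vector of output paths, invisibly.
#' @export
runStage <- function(name, config = defaultRunConfig(), force = FALSE) {
  if (!name %in% .stages) stop("unknown stage: ", name,
                               " (stages: ", paste(.stages, collapse = ", "), ")")
  d <- config$outdir
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  ins <- .stageInputs(name, d)
  missing_in <- ins[!file.exists(ins)]
  if (length(missing_in)) {
    idx <- match(name, .stages)
    stop("missing upstream artifact(s) ", paste(basename(missing_in),
                                                collapse = ", "),
         "; run stage '", .stages[max(1, idx - 1)], "' first")
  }
  outs <- .stageOutputs(name, d)
  hash <- .inputsHash(ins, .paramString(config))
  mf <- .manifestPath(d)
  if (!force && file.exists(mf)) {
    man <- utils::read.delim(mf, stringsAsFactors = FALSE)
    done <- man$stage == name & man$hash == hash
    if (any(done) && all(file.exists(outs))) {
      message("stage '", name, "' up to date; skipping (use force = TRUE)")
      return(invisible(outs))
    }
  }
  t0 <- Sys.time()
  message("[", name, "] running ...")
  .stageBody(name, config)
  line <- data.frame(stage = name, hash = hash,
                     params = .paramString(config),
                     outputs = paste(basename(outs), collapse = ","),
                     seconds = round(as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs")), 2))
  utils::write.table(line, mf, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(mf), append = file.exists(mf))
  invisible(outs)
}

.stageBody <- function(name, config) {
  d <- config$outdir
  p <- function(...) file.path(d, ...)
  switch(name,
  simulate = {
    cfg <- simConfig(n_genes = config$n_genes, n_tfs = config$n_tfs,
                     n_samples = config$n_samples,
                     n_individuals = config$n_individuals,
                     seed = config$seed)
    sim <- simulateAnnotation(cfg, with_sequence = isTRUE(config$with_sequence))
    reg <- simulateRegulation(cfg, sim)
    gen <- simulateGenotypes(cfg, sim, reg)
    writeGeneAnnotationGTF(sim$annotation, p("annotation.gtf"))
    writePeaksBED(reg$peaks, p("peaks.bed"))
    writePeaksBED(reg$ctcf, p("ctcf.bed"))
    writeTSV(reg$ppi, p("ppi.tsv"))
    writeMatrixTSV(reg$expression, p("expression.tsv"), "sample")
    writeTSV(reg$contacts, p("contacts.tsv"))
    writeTSV(data.frame(gene_id = names(reg$truth$response),
                        response = reg$truth$response), p("response.tsv"))
    writeMatrixTSV(gen$genotypes, p("genotypes.tsv"), "individual")
    writeMatrixTSV(gen$phenotypes, p("phenotypes.tsv"), "individual")
    writeMatrixTSV(gen$covariates, p("covariates.tsv"), "individual")
    writeTSV(gen$zscores, p("zscores.tsv"))
    writeTSV(gen$variants, p("variants.tsv"))
    writeTSV(data.frame(tf = names(cfg$effect_sizes),
                        beta = cfg$effect_sizes), p("truth_beta.tsv"))
    if (!is.null(sim$sequence))
      Biostrings::writeXStringSet(sim$sequence, p("genome.fa"))
  },
  regions = {
    rw <- .windowsFromFiles(config)
    b <- boundedWindows(rw)
    rtracklayer::export(.asBed(b, b$gene_id), p("windows.bed"))
    pr <- promoterRegions(rw)
    rtracklayer::export(.asBed(pr, pr$gene_id), p("promoters.bed"))
    intr <- unlist(intronRegions(rw))
    ig <- rep(names(intronRegions(rw)),
              S4Vectors::elementNROWS(intronRegions(rw)))
    rtracklayer::export(.asBed(unname(intr), ig), p("introns.bed"))
    writeTSV(data.frame(gene_id = b$gene_id, tss = b$tss), p("tss.tsv"))
  },
  tfbs = {
    rw <- .windowsFromFiles(config)
    peaks <- readPeaksBED(p("peaks.bed"))
    tf_tab <- positionalTFBS(peaks, rw)
    writeTSV(tf_tab, p("tfbs.tsv"))
    writeTSV(partitionPeaks(peaks, rw), p("partition.tsv"))
    writeTSV(affinityTable(tf_tab, rw), p("affinity.tsv"))
  },
  grn = {
    tf_tab <- readTSV(p("tfbs.tsv"))
    ppi_edges <- readTSV(p("ppi.tsv"))
    expr <- readMatrixTSV(p("expression.tsv"))
    tfs <- sort(unique(tf_tab$tf))
    genes <- colnames(expr)
    pairs <- unique(tf_tab[tf_tab$gene_id %in% genes, c("tf", "gene_id")])
    motif <- motifAdjacency(pairs, tfs, genes, mode = "binary")
    coex <- coexpressionNetwork(expr)
    ppi <- ppiNetwork(ppi_edges, tfs)
    nets <- alignNetworks(motif, ppi, coex)
    writeMatrixTSV(networkMatrix(nets$motif), p("motif.tsv"), "tf")
    writeMatrixTSV(nets$coexpr, p("coexpression.tsv"), "gene")
    writeMatrixTSV(nets$ppi, p("ppi_matrix.tsv"), "tf")
    fit <- pandaFit(nets$motif, nets$ppi, nets$coexpr,
                    update = config$update, tol = config$tol,
                    max_iter = config$max_iter)
    writeTSV(edgeList(fit), p("panda_edges.tsv"))
  },
  hic = {
    motif <- methods::new("TFGeneNetwork",
                          matrix = readMatrixTSV(p("motif.tsv")),
                          mode = "binary")
    tf_tab <- readTSV(p("tfbs.tsv"))
    contacts <- readTSV(p("contacts.tsv"))
    part <- readTSV(p("partition.tsv"))
    W <- hicWeightMatrix(motif, tf_tab, contacts)
    writeMatrixTSV(W, p("hic_weights.tsv"), "tf")
    prom <- unique(part[part$category == "promoter", c("tf", "gene_id")])
    dp <- applyScheme(motif, W, prom, "DP")
    up <- applyScheme(motif, W, prom, "UP")
    writeMatrixTSV(networkMatrix(dp), p("motif_dp.tsv"), "tf")
    writeMatrixTSV(networkMatrix(up), p("motif_up.tsv"), "tf")
  },
  fit = {
    edges <- readTSV(p("panda_edges.tsv"))
    resp <- readTSV(p("response.tsv"))
    genes <- intersect(unique(edges$gene_id), resp$gene_id)
    tfs <- unique(edges$tf)
    X <- assembleFeatures(edges, genes, tfs)
    y <- stats::setNames(resp$response, resp$gene_id)[genes]
    rf <- repeatFit(X, y, alpha_ratio = config$alpha_ratio,
                    train_frac = config$train_frac,
                    inner_folds = config$inner_folds,
                    iterations = config$iterations,
                    base_seed = config$seed)
    perf <- do.call(rbind, lapply(rf$perf, as.data.frame))
    writeTSV(perf, p("performance.tsv"))
    co <- t(vapply(rf$fits, `[[`, numeric(length(tfs)), "coefficients"))
    rownames(co) <- sprintf("iter%02d", seq_len(nrow(co)))
    writeMatrixTSV(co, p("coefficients.tsv"), "iteration")
  },
  effects = {
    co <- readMatrixTSV(p("coefficients.tsv"))
    fits <- lapply(seq_len(nrow(co)), function(i)
      list(coefficients = co[i, ]))
    eff <- quintileBins(averageEffects(fits))
    writeTSV(data.frame(tf = names(effectBeta(eff)),
                        beta_mean = effectBeta(eff),
                        bin = effectBins(eff)), p("effects.tsv"))
  },
  varscore = {
    variants <- filterRare(readTSV(p("variants.tsv")), config$maf)
    z <- significantBinding(readTSV(p("zscores.tsv")), config$qbic_p)
    z <- z[z$variant_id %in% variants$variant_id, , drop = FALSE]
    eff <- readTSV(p("effects.tsv"))
    beta_bar <- stats::setNames(eff$beta_mean, eff$tf)
    ms <- mergeScoreTable(z, beta_bar)
    ms$score <- scaleScores(ms$score)
    az <- aggregateZTable(z)
    az$score <- scaleScores(az$score)
    writeTSV(ms, p("scores_merge.tsv"))
    writeTSV(az, p("scores_aggz.tsv"))
  },
  skat = {
    G <- readMatrixTSV(p("genotypes.tsv"))
    Ph <- readMatrixTSV(p("phenotypes.tsv"))
    Cv <- readMatrixTSV(p("covariates.tsv"))
    ms <- readTSV(p("scores_merge.tsv"))
    az <- readTSV(p("scores_aggz.tsv"))
    writeTSV(skatByGene(G, Ph, Cv, ms), p("skat_merge.tsv"))
    writeTSV(skatByGene(G, Ph, Cv, az), p("skat_aggz.tsv"))
  })
  invisible(NULL)
}

.asBed <- function(gr, names) {
  out <- granges(gr)
  mcols(out) <- NULL
  out$name <- names
  out
}

#' Run the full pipeline end to end
#'
#' Executes every stage in order (simulate through skat). Deterministic:
#' identical config and seed reproduce identical result files.
#'
#' @inheritParams runStage
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), force = FALSE) {
  for (s in .stages) runStage(s, config, force = force)
  invisible(config$outdir)
}
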