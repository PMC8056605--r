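#' Configuration for the synthetic multi-omics fixture generator
#'
#' Defaults define desk-scale study conditions: 200 genes in co-regulated
#' modules of 20, 20 TFs, 50 expression samples, 300 genotyped individuals,
#' 8 rare variants per gene, genes spaced 60 kb apart so every 50 kb
#' regulatory window is well formed. Planted TF effects span activators
#' (positive), repressors (negative) and near-zero cofactors; binding-site
#' dropout (30%) creates the cis-evidence gaps that trans information
#' (co-expression) can fill. A master seed drives one RNG stream per data
#' type so regenerating any component is reproducible in isolation.
#'
#' @param n_genes,n_tfs,n_samples,n_individuals counts (all >= 1).
#' @param genome_length simulated chromosome length; default gives 60 kb
#'   gene spacing.
#' @param seed master RNG seed (mandatory).
#' @param effect_sizes named numeric of planted per-TF effects; default:
#'   40\% activators in [0.4, 1.2], 30\% repressors in [-1.0, -0.3], the
#'   rest near zero.
#' @param noise_sd expression noise sd (log10 FPKM scale), default 0.5.
#' @param hic_decay_bp Hi-C contact decay length, default 20000.
#' @param n_variants_per_gene rare variants simulated per gene, default 8.
#' @param causal_fraction fraction of genes given causal regulatory
#'   variants, default 0.5.
#' @param module_size genes per co-expression module, default 20.
#' @param dropout probability a true binding site lacks an observed peak,
#'   default 0.3.
#' @param variant_effect phenotype shift per causal allele per unit planted
#'   TF effect, default 1.5.
#' @param motif_length planted PWM length, default 8.
#' @return list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_genes = 200L, n_tfs = 20L, n_samples = 50L,
                      genome_length = NULL, seed,
                      effect_sizes = NULL, noise_sd = 0.5,
                      hic_decay_bp = 20000L, n_individuals = 300L,
                      n_variants_per_gene = 8L, causal_fraction = 0.5,
                      module_size = 20L, dropout = 0.3,
                      variant_effect = 1.5, motif_length = 8L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 1, n_tfs >= 1, n_samples >= 1, n_individuals >= 1,
            n_variants_per_gene >= 1, module_size >= 1)
  if (is.null(genome_length)) genome_length <- n_genes * 60000L + 120000L
  if (is.null(effect_sizes)) {
    set.seed(as.integer(seed) + 7L)
    n_act <- max(1L, round(0.4 * n_tfs))
    n_rep <- max(1L, round(0.3 * n_tfs))
    n_nil <- n_tfs - n_act - n_rep
    effect_sizes <- c(stats::runif(n_act, 0.4, 1.2),
                      -stats::runif(n_rep, 0.3, 1.0),
                      stats::runif(max(0L, n_nil), -0.05, 0.05))
    names(effect_sizes) <- sprintf("TF%02d", seq_len(n_tfs))
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples),
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed), effect_sizes = effect_sizes,
                 noise_sd = noise_sd, hic_decay_bp = as.integer(hic_decay_bp),
                 n_individuals = as.integer(n_individuals),
                 n_variants_per_gene = as.integer(n_variants_per_gene),
                 causal_fraction = causal_fraction,
                 module_size = as.integer(module_size), dropout = dropout,
                 variant_effect = variant_effect,
                 motif_length = as.integer(motif_length)),
            class = "SimConfig")
}

.simChrom <- "chrS"

.randomPWM <- function(tf, L) {
  cons <- sample(1:4, L, replace = TRUE)
  probs <- matrix(0.05, L, 4)
  probs[cbind(seq_len(L), cons)] <- 0.85
  newPWM(tf, probs)
}

.consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Simulate gene annotation, sequence and planted binding sites
#'
#' Places non-overlapping multi-transcript genes (alternating strand) along a
#' synthetic chromosome, groups them into co-regulation modules, assigns each
#' module 2-4 regulator TFs, and plants each regulator's motif consensus at a
#' promoter, intronic or distal site of every target gene inside a random
#' background sequence.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param with_sequence generate the chromosome sequence (default TRUE).
#' @return list: \code{annotation} (\code{GeneAnnotation}), \code{sequence}
#'   (\code{DNAStringSet} or NULL), \code{pwms}, \code{sites} (data.frame
#'   tf/gene_id/pos — the true binding map), \code{modules} (int per gene),
#'   \code{tf_names}.
#' @export
simulateAnnotation <- function(cfg, with_sequence = TRUE) {
  spacing <- (cfg$genome_length - 120000L) %/% cfg$n_genes
  if (spacing < 60000L)
    stop("overcrowded genome: need >= 60 kb per gene, have ", spacing)
  set.seed(cfg$seed + 11L)
  tfs <- names(cfg$effect_sizes)
  pwms <- lapply(tfs, .randomPWM, L = cfg$motif_length)
  names(pwms) <- tfs

  gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  gstart <- 60000L + (seq_len(cfg$n_genes) - 1L) * spacing +
    sample(0:4000, cfg$n_genes, replace = TRUE)
  glen <- sample(3000:9000, cfg$n_genes, replace = TRUE)
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  txg <- list(); exg <- list()
  for (i in seq_len(cfg$n_genes)) {
    ntx <- sample(1:3, 1)
    s0 <- gstart[i]; e0 <- gstart[i] + glen[i] - 1L
    for (j in seq_len(ntx)) {
      if (j == 1L) { ts <- s0; te <- e0 } else {
        ts <- s0 + sample(0:floor(glen[i] / 3), 1)
        te <- e0 - sample(0:floor(glen[i] / 3), 1)
        if (te - ts < 500L) { ts <- s0; te <- e0 }
      }
      txid <- sprintf("%s.t%d", gene_ids[i], j)
      txg[[length(txg) + 1L]] <- data.frame(tx = txid, gene = gene_ids[i],
                                            start = ts, end = te,
                                            strand = gstrand[i])
      k <- sample(1:4, 1)
      if (k == 1L) { exs <- ts; exe <- te } else {
        cuts <- sort(sample((ts + 1L):(te - 1L), 2L * (k - 1L)))
        bounds <- c(ts, cuts, te)
        exs <- bounds[seq(1, 2 * k - 1, by = 2)]
        exe <- bounds[seq(2, 2 * k, by = 2)]
        exe[k] <- te
      }
      exg[[length(exg) + 1L]] <- data.frame(tx = txid, gene = gene_ids[i],
                                            start = exs, end = exe,
                                            strand = gstrand[i])
    }
  }
  txd <- do.call(rbind, txg); exd <- do.call(rbind, exg)
  genes <- GRanges(.simChrom, IRanges(gstart, gstart + glen - 1L),
                   strand = gstrand)
  genes$gene_id <- gene_ids; genes$biotype <- "protein_coding"
  tx <- GRanges(.simChrom, IRanges(txd$start, txd$end), strand = txd$strand)
  tx$tx_id <- txd$tx; tx$gene_id <- txd$gene
  ex <- GRanges(.simChrom, IRanges(exd$start, exd$end), strand = exd$strand)
  ex$tx_id <- exd$tx; ex$gene_id <- exd$gene
  ann <- methods::new("GeneAnnotation", genes = genes, transcripts = tx,
                      exons = ex)

  modules <- (seq_len(cfg$n_genes) - 1L) %/% cfg$module_size + 1L
  n_mod <- max(modules)
  mod_tfs <- lapply(seq_len(n_mod), function(m)
    sample(tfs, sample(2:min(4, cfg$n_tfs), 1)))

  sites <- list()
  for (i in seq_len(cfg$n_genes)) {
    regs <- unique(c(mod_tfs[[modules[i]]],
                     if (stats::runif(1) < 0.3) sample(tfs, 1)))
    tss <- if (gstrand[i] == "+") gstart[i] else gstart[i] + glen[i] - 1L
    updir <- if (gstrand[i] == "+") -1L else 1L
    for (tf in regs) {
      r <- stats::runif(1)
      pos <- if (r < 0.5) tss + updir * sample(500:4500, 1)           # promoter
             else if (r < 0.8) gstart[i] + sample(200:(glen[i] - 200), 1) # genic
             else tss + updir * sample(6000:40000, 1)                 # distal
      sites[[length(sites) + 1L]] <- data.frame(tf = tf,
                                                gene_id = gene_ids[i],
                                                pos = max(10L, pos))
    }
  }
  sites <- do.call(rbind, sites)

  sequence <- NULL
  if (with_sequence) {
    bases <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
    for (s in seq_len(nrow(sites))) {
      cons <- strsplit(.consensus(pwms[[sites$tf[s]]]), "")[[1]]
      p <- sites$pos[s]
      if (p + length(cons) - 1L <= cfg$genome_length)
        bases[p:(p + length(cons) - 1L)] <- cons
    }
    sequence <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(sequence) <- .simChrom
  }

  list(annotation = ann, sequence = sequence, pwms = pwms, sites = sites,
       modules = stats::setNames(modules, gene_ids), tf_names = tfs)
}

#' Simulate binding peaks, PPI, expression, Hi-C contacts and ground truth
#'
#' Observed ChIP-seq peaks cover each planted binding site with probability
#' 1 - dropout (plus background peaks); CTCF peaks flank every gene near the
#' 45 kb mark. Expression couples cis binding (sample-varying TF activity
#' times planted effects) with module-level trans factors, producing
#' block-structured co-expression. Hi-C contacts between peaks and promoters
#' are Poisson draws with exponential distance decay. The truth record holds
#' the planted effects, the full binding map and a held-out response vector
#' (expression of an independent instance) for recovery tests.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param sim output of \code{\link{simulateAnnotation}}.
#' @return list: \code{peaks}, \code{ctcf} (GRanges), \code{ppi}
#'   (data.frame), \code{expression} (samples x genes), \code{contacts}
#'   (data.frame), \code{truth}.
#' @export
simulateRegulation <- function(cfg, sim) {
  set.seed(cfg$seed + 22L)
  ann <- sim$annotation
  tfs <- sim$tf_names
  gene_ids <- ann@genes$gene_id
  beta <- cfg$effect_sizes[tfs]

  B_true <- matrix(0, cfg$n_tfs, cfg$n_genes, dimnames = list(tfs, gene_ids))
  B_true[cbind(match(sim$sites$tf, tfs), match(sim$sites$gene_id, gene_ids))] <- 1

  kept <- stats::runif(nrow(sim$sites)) >= cfg$dropout
  obs <- sim$sites[kept, , drop = FALSE]
  pk_start <- pmax(1L, obs$pos - 150L)
  peaks <- GRanges(.simChrom, IRanges(pk_start, obs$pos + 149L))
  peaks$tf <- obs$tf
  peaks$signal <- 5 + stats::rexp(nrow(obs), 1 / 5)
  nbg <- cfg$n_tfs * 10L
  bgpos <- sample.int(cfg$genome_length - 400L, nbg)
  bg <- GRanges(.simChrom, IRanges(bgpos, bgpos + 299L))
  bg$tf <- sample(tfs, nbg, replace = TRUE)
  bg$signal <- 2 + stats::rexp(nbg, 1 / 2)
  peaks <- c(peaks, bg)

  g <- ann@genes
  tssv <- vapply(gene_ids, function(x) as.integer(geneTSS(ann, x)), integer(1))
  cst <- c(pmax(1L, GenomicRanges::start(g) - 45000L +
                  sample(-2000:2000, length(g), replace = TRUE)),
           GenomicRanges::end(g) + 45000L +
             sample(-2000:2000, length(g), replace = TRUE))
  ctcf <- GRanges(.simChrom, IRanges(cst, cst + 299L))
  ctcf$tf <- "CTCF"; ctcf$signal <- 10

  ppi <- list()
  for (m in seq_len(max(sim$modules))) {
    mt <- unique(sim$sites$tf[sim$sites$gene_id %in%
                                names(sim$modules)[sim$modules == m]])
    if (length(mt) >= 2) {
      prs <- utils::combn(sort(mt), 2)
      pick <- stats::runif(ncol(prs)) < 0.8
      if (any(pick))
        ppi[[length(ppi) + 1L]] <- data.frame(tfA = prs[1, pick],
                                              tfB = prs[2, pick])
    }
  }
  ppi <- unique(do.call(rbind, c(ppi, list(data.frame(tfA = character(),
                                                      tfB = character())))))

  activity <- matrix(stats::rnorm(cfg$n_samples * cfg$n_tfs, 1, 0.3),
                     cfg$n_samples, cfg$n_tfs, dimnames = list(NULL, tfs))
  modfac <- matrix(stats::rnorm(cfg$n_samples * max(sim$modules), 0, 0.7),
                   cfg$n_samples, max(sim$modules))
  cis <- activity %*% (B_true * beta)     # samples x genes
  expr <- cis + modfac[, sim$modules[gene_ids]] +
    matrix(stats::rnorm(cfg$n_samples * cfg$n_genes, 0, cfg$noise_sd),
           cfg$n_samples, cfg$n_genes)
  colnames(expr) <- gene_ids
  rownames(expr) <- sprintf("S%03d", seq_len(cfg$n_samples))

  response <- as.numeric(beta %*% B_true) +
    stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
  names(response) <- gene_ids

  # Hi-C: contacts between observed peaks and promoters, decaying in distance
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  contacts <- list()
  for (i in seq_along(gene_ids)) {
    lo <- tssv[i] - 50000L; hi <- tssv[i] + 50000L
    inwin <- which(mid >= lo & mid <= hi)
    if (!length(inwin)) next
    d <- abs(mid[inwin] - tssv[i])
    lam <- 30 * exp(-d / cfg$hic_decay_bp)
    cc <- stats::rpois(length(inwin), lam)
    pos <- cc > 0
    if (!any(pos)) next
    contacts[[length(contacts) + 1L]] <- data.frame(
      chrom = .simChrom,
      peak_start = GenomicRanges::start(peaks)[inwin[pos]],
      peak_end = GenomicRanges::end(peaks)[inwin[pos]],
      tf = as.character(peaks$tf)[inwin[pos]],
      gene_id = gene_ids[i],
      kr_contacts = cc[pos] * stats::runif(sum(pos), 0.85, 1.15),
      stringsAsFactors = FALSE)
  }
  contacts <- do.call(rbind, contacts)

  list(peaks = peaks, ctcf = ctcf, ppi = ppi, expression = expr,
       contacts = contacts,
       truth = list(beta = beta, B_true = B_true, modules = sim$modules,
                    response = response, sites_observed = obs))
}

#' Simulate genotypes, phenotypes, covariates and binding z-scores
#'
#' Places rare variants (MAF drawn from a Beta distribution skewed below
#' 0.01) inside and outside the observed TF binding sites of every gene. In
#' causal genes, variants inside sites of large-effect TFs disrupt binding
#' (large |z|) and shift the gene's phenotype in proportion to the planted TF
#' effect; decoy variants inside near-zero-effect TF sites disrupt binding
#' equally strongly but have no phenotype consequence — the contrast the
#' effect-weighted kernel test is designed to exploit. z-scores carry
#' two-sided normal p-values.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param sim output of \code{\link{simulateAnnotation}}.
#' @param reg output of \code{\link{simulateRegulation}}.
#' @return list: \code{variants}, \code{genotypes} (individuals x variants),
#'   \code{phenotypes} (individuals x genes), \code{covariates},
#'   \code{zscores}, \code{causal_genes}.
#' @export
simulateGenotypes <- function(cfg, sim, reg) {
  set.seed(cfg$seed + 33L)
  ann <- sim$annotation
  gene_ids <- ann@genes$gene_id
  beta <- reg$truth$beta
  obs <- reg$truth$sites_observed
  nI <- cfg$n_individuals

  big_tfs <- names(beta)[abs(beta) >= 0.3]
  nil_tfs <- names(beta)[abs(beta) < 0.1]
  eligible <- gene_ids[gene_ids %in% obs$gene_id[obs$tf %in% big_tfs]]
  n_causal <- min(length(eligible),
                  max(1L, floor(cfg$causal_fraction * cfg$n_genes)))
  causal_genes <- sample(eligible, n_causal)

  covariates <- cbind(cov_age = stats::rnorm(nI),
                      cov_sex = stats::rbinom(nI, 1, 0.5))

  vrec <- list(); zrec <- list(); geno <- list(); phen <- list()
  vid_counter <- 0L
  for (gidx in seq_along(gene_ids)) {
    gid <- gene_ids[gidx]
    gsites <- obs[obs$gene_id == gid, , drop = FALSE]
    tss <- as.integer(geneTSS(ann, gid))
    nv <- cfg$n_variants_per_gene
    n_in <- if (nrow(gsites)) min(nv %/% 2, nrow(gsites) * 2L) else 0L
    site_pick <- if (n_in) sample.int(nrow(gsites), n_in, replace = TRUE)
                 else integer(0)
    pos_in <- if (n_in) gsites$pos[site_pick] + sample(0:7, n_in, TRUE)
              else integer(0)
    pos_out <- tss + sample(c(-45000:-6000, 6000:45000), nv - n_in)
    pos <- pmax(1L, c(pos_in, pos_out))
    in_tf <- c(gsites$tf[site_pick], rep(NA_character_, nv - n_in))
    maf <- pmax(1 / (2 * nI), 0.01 * stats::rbeta(nv, 1.2, 4))
    ids <- sprintf("v%06d", vid_counter + seq_len(nv)); vid_counter <- vid_counter + nv
    G <- vapply(maf, function(p) stats::rbinom(nI, 2, p), numeric(nI))
    colnames(G) <- ids

    is_causal_gene <- gid %in% causal_genes
    zt <- numeric(nv); causal_v <- logical(nv)
    for (k in seq_len(n_in)) {
      tfk <- in_tf[k]
      if (is_causal_gene && tfk %in% big_tfs) {
        zt[k] <- sample(c(-1, 1), 1) * (4.5 + stats::rexp(1))
        causal_v[k] <- TRUE
      } else if (tfk %in% nil_tfs && stats::runif(1) < 0.7) {
        zt[k] <- sample(c(-1, 1), 1) * (4.5 + stats::rexp(1))  # decoy
      } else {
        zt[k] <- stats::rnorm(1)
      }
    }
    z <- zt + stats::rnorm(nv, 0, 0.3)
    gamma <- ifelse(causal_v, -cfg$variant_effect * beta[in_tf] * sign(zt),
                    0)
    gamma[is.na(gamma)] <- 0
    y <- as.numeric(covariates %*% c(0.3, 0.2) + G %*% gamma +
                      stats::rnorm(nI))

    vrec[[gidx]] <- data.frame(variant_id = ids, chrom = .simChrom,
                               pos = pos, ref = "A", alt = "G", maf = maf,
                               gene_id = gid, tf = in_tf,
                               causal = causal_v, stringsAsFactors = FALSE)
    inw <- which(seq_len(nv) <= n_in)
    if (length(inw))
      zrec[[gidx]] <- data.frame(
        variant_id = ids[inw], tf = in_tf[inw], gene_id = gid,
        peak_start = pmax(1L, gsites$pos[site_pick[inw]] - 150L),
        peak_end = gsites$pos[site_pick[inw]] + 149L,
        zscore = z[inw],
        pvalue = pmax(2 * stats::pnorm(-abs(z[inw])), 1e-300),
        stringsAsFactors = FALSE)
    geno[[gidx]] <- G
    phen[[gidx]] <- y
  }
  variants <- do.call(rbind, vrec)
  zscores <- do.call(rbind, zrec)
  genotypes <- do.call(cbind, geno)
  phenotypes <- do.call(cbind, phen)
  colnames(phenotypes) <- gene_ids
  ind <- sprintf("I%04d", seq_len(nI))
  rownames(genotypes) <- ind
  rownames(phenotypes) <- ind
  rownames(covariates) <- ind

  list(variants = variants, genotypes = genotypes, phenotypes = phenotypes,
       covariates = covariates, zscores = zscores,
       causal_genes = causal_genes)
}
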