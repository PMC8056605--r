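#' Positional TF binding evidence: peaks within regulatory windows
#'
#' One record per peak x gene overlap with the CTCF-bounded windows; a peak
#' inside two genes' windows yields two records. The unique (tf, gene) pairs
#' of the result define the unweighted positional motif prior.
#'
#' @param peaks \code{GRanges} with mcols \code{tf} and \code{signal}.
#' @param rw a \code{\linkS4class{RegulatoryWindows}}.
#' @return data.frame: \code{tf}, \code{gene_id}, \code{peak_chrom},
#'   \code{peak_start}, \code{peak_end}, \code{signal}.
#' @export
positionalTFBS <- function(peaks, rw) {
  b <- boundedWindows(rw)
  hits <- findOverlaps(peaks, b, ignore.strand = TRUE)
  pk <- queryHits(hits)
  data.frame(
    tf = as.character(peaks$tf)[pk],
    gene_id = b$gene_id[subjectHits(hits)],
    peak_chrom = as.character(seqnames(peaks))[pk],
    peak_start = GenomicRanges::start(peaks)[pk],
    peak_end = GenomicRanges::end(peaks)[pk],
    signal = as.numeric(peaks$signal)[pk],
    stringsAsFactors = FALSE)
}

#' Read a minimal MEME-format motif file
#'
#' Parses MOTIF blocks with letter-probability matrices (alphabet ACGT) and
#' an optional "Background letter frequencies" line; anything else in the
#' full MEME grammar is ignored.
#'
#' @param file path to a MEME-like motif text file.
#' @return named list of PWMs; each is \code{list(tf, probs, background)}
#'   with \code{probs} an L x 4 row-stochastic matrix (columns A,C,G,T).
#' @export
readMEME <- function(file) {
  lines <- readLines(file)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgline <- grep("^Background letter frequencies", lines)
  if (length(bgline) && bgline[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgline[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      v <- as.numeric(toks[c(2, 4, 6, 8)])
      names(v) <- toks[c(1, 3, 5, 7)]
      bg <- v[c("A", "C", "G", "T")]
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    i <- s + 1L
    while (i <= length(lines) && !grepl("^letter-probability matrix", lines[i]))
      i <- i + 1L
    if (i > length(lines)) stop("MOTIF ", nm, " without probability matrix")
    rows <- list(); i <- i + 1L
    while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1L
    }
    probs <- do.call(rbind, rows)
    colnames(probs) <- c("A", "C", "G", "T")
    out[[nm]] <- newPWM(nm, probs, bg)
  }
  out
}

#' Construct (and validate) a PWM object
#'
#' @param tf TF name.
#' @param probs L x 4 matrix, rows summing to 1, columns A,C,G,T.
#' @param background length-4 base frequencies summing to 1.
#' @return \code{list(tf, probs, background)} of class \code{"PWM"}.
#' @export
newPWM <- function(tf, probs, background = c(A = .25, C = .25, G = .25, T = .25)) {
  probs <- as.matrix(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(tf = tf, probs = probs,
                 background = stats::setNames(as.numeric(background),
                                              c("A", "C", "G", "T"))),
            class = "PWM")
}

#' Write motifs in minimal MEME format
#' @param pwms list of PWMs from \code{\link{newPWM}}.
#' @param file output path.
#' @export
writeMEME <- function(pwms, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste("A", 0.25, "C", 0.25, "G", 0.25, "T", 0.25), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$probs)), con)
    apply(p$probs, 1, function(r)
      writeLines(paste(sprintf("%.6f", r), collapse = " "), con))
    writeLines("", con)
  }
  invisible(file)
}

# integer score table (units of `res` bits) for a PWM with pseudocount
.pwmScoreTable <- function(pwm, pseudocount = 1e-3, res = 1e-3) {
  p <- pwm$probs + pseudocount
  p <- p / rowSums(p)
  bits <- log2(sweep(p, 2, pwm$background, "/"))
  round(bits / res)
}

# exact null of the integer score sum under the background, by DP convolution.
# Returns list(offset, tail): P(S >= k) = tail[k - offset + 1].
.pwmNull <- function(ktab, background) {
  lo <- sum(apply(ktab, 1, min)); hi <- sum(apply(ktab, 1, max))
  dist <- rep(0, hi - lo + 1)
  cur_lo <- 0; cur <- 1  # distribution of partial sums, offset cur_lo
  for (i in seq_len(nrow(ktab))) {
    krow <- ktab[i, ]
    new_lo <- cur_lo + min(krow)
    new <- rep(0, length(cur) + (max(krow) - min(krow)))
    for (b in 1:4) {
      sh <- krow[b] - min(krow)
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  list(offset = cur_lo, tail = tail,
       pvalue = function(k) {
         i <- k - cur_lo + 1L
         if (i <= 1L) 1 else if (i > length(tail)) 0 else tail[i]
       })
}

.revcompPWM <- function(pwm) {
  probs <- pwm$probs[rev(seq_len(nrow(pwm$probs))), c("T", "G", "C", "A"),
                     drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  newPWM(pwm$tf, probs, pwm$background)
}

#' Scan a sequence with a PWM (FIMO-style, exact p-values)
#'
#' Log-odds scores (base 2, pseudocount 1e-3) are computed at every position
#' on both strands; the per-position p-value is the exact probability, under
#' the background model, of a score at least as large, obtained by dynamic
#' programming over the discretized score distribution (1e-3 bit resolution).
#' Windows containing N are skipped. When forward and reverse hits share a
#' start position only the better-scoring strand is kept.
#'
#' @param sequence character string or \code{DNAString} over A,C,G,T,N.
#' @param pwm a PWM from \code{\link{newPWM}} / \code{\link{readMEME}}.
#' @param p_threshold significance threshold on the exact p-value
#'   (default 0.01).
#' @return data.frame: \code{start}, \code{end} (1-based closed),
#'   \code{strand}, \code{score} (bits), \code{pvalue}; zero rows when the
#'   sequence is shorter than the motif.
#' @export
scanPWM <- function(sequence, pwm, p_threshold = 0.01) {
  seqc <- toupper(as.character(sequence))
  L <- nrow(pwm$probs)
  n <- nchar(seqc)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  codes <- base_idx[strsplit(seqc, "")[[1]]]  # NA for N / other
  res <- 1e-3
  scanOne <- function(pw, strand_lab) {
    ktab <- .pwmScoreTable(pw, res = res)
    null <- .pwmNull(ktab, pw$background)
    starts <- seq_len(n - L + 1L)
    out <- lapply(starts, function(s) {
      idx <- codes[s:(s + L - 1L)]
      if (anyNA(idx)) return(NULL)
      k <- sum(ktab[cbind(seq_len(L), idx)])
      pv <- null$pvalue(k)
      if (pv <= p_threshold)
        data.frame(start = s, end = s + L - 1L, strand = strand_lab,
                   score = k * res, pvalue = pv, stringsAsFactors = FALSE)
      else NULL
    })
    do.call(rbind, c(list(empty), out))
  }
  fwd <- scanOne(pwm, "+")
  rev <- scanOne(.revcompPWM(pwm), "-")
  hits <- rbind(fwd, rev)
  if (nrow(hits) == 0L) return(hits)
  # deduplicate same-start hits to the best strand (palindromes)
  hits <- hits[order(hits$start, -hits$score, hits$strand), , drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' TEPIC-style binding affinity of a TF for a gene
#'
#' Aggregates per-site binding strengths with exponential decay in distance
#' from the TSS: \code{sum_i a_i * exp(-|center_i - tss| / d0)}. Site strength
#' is a PWM-derived probability in (0,1] or a normalized peak signal; absent
#' sites give 0. Translation-invariant and strictly increasing in each added
#' site.
#'
#' @param centers numeric vector of site center positions.
#' @param strengths per-site binding strengths (same length; all > 0).
#' @param tss TSS position.
#' @param d0 decay length in bp (default 5000).
#' @return non-negative affinity score.
#' @export
affinityScore <- function(centers, strengths, tss, d0 = 5000) {
  if (length(centers) == 0L) return(0)
  stopifnot(length(centers) == length(strengths), all(strengths >= 0), d0 > 0)
  sum(strengths * exp(-abs(centers - tss) / d0))
}

#' Affinity scores for every TF x gene combination
#'
#' Applies \code{\link{affinityScore}} to positional binding records (e.g.
#' from \code{\link{positionalTFBS}}), using the peak midpoint as the site
#' center and the peak signal, normalized to (0, 1] by the global maximum, as
#' the site strength.
#'
#' @param tfbs data.frame from \code{\link{positionalTFBS}}.
#' @param rw a \code{RegulatoryWindows} (provides each gene's TSS).
#' @param d0 decay length in bp.
#' @return data.frame: \code{tf}, \code{gene_id}, \code{value}.
#' @export
affinityTable <- function(tfbs, rw, d0 = 5000) {
  b <- boundedWindows(rw)
  tssmap <- stats::setNames(b$tss, b$gene_id)
  smax <- max(tfbs$signal, 0)
  a <- if (smax > 0) tfbs$signal / smax else rep(1, nrow(tfbs))
  a[a <= 0] <- min(a[a > 0], 1)  # zero-signal sites still count minimally
  mid <- floor((tfbs$peak_start + tfbs$peak_end) / 2)
  dec <- a * exp(-abs(mid - tssmap[tfbs$gene_id]) / d0)
  agg <- stats::aggregate(dec,
                          by = list(tf = tfbs$tf, gene_id = tfbs$gene_id),
                          FUN = sum)
  names(agg)[3] <- "value"
  agg
}
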