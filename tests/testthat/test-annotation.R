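test_that("longestTranscript picks maximal span with tx_id tie-break", {
  ann <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = c("T1", "T2"),
                    start = c(1000, 1000), end = c(1999, 2999),
                    strand = "+"),
    exons = data.frame(tx = c("T1", "T2"), start = c(1000, 1000),
                       end = c(1999, 2999)))
  expect_equal(longestTranscript(ann, "G1")$tx_id, "T2")

  # tie on length: lexicographically smallest tx_id wins
  ann2 <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = c("Tb", "Ta"),
                    start = c(1000, 1500), end = c(1499, 1999),
                    strand = "+"),
    exons = data.frame(tx = c("Tb", "Ta"), start = c(1000, 1500),
                       end = c(1499, 1999)))
  expect_equal(longestTranscript(ann2, "G1")$tx_id, "Ta")
  expect_error(longestTranscript(ann2, "nope"), "no transcripts")
})

test_that("candidateWindow is strand-aware and clipped at the origin", {
  expect_equal(
    as.data.frame(candidateWindow(plusGene(), "G1"))[, c("start", "end")],
    data.frame(start = 50001, end = 160000))
  # minus strand: TSS at the right end, mirrored arithmetic, same interval
  expect_equal(
    as.data.frame(candidateWindow(minusGene(), "G1"))[, c("start", "end")],
    data.frame(start = 50001, end = 160000))
  # clipping
  annc <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = "T1", start = 10001, end = 12000,
                    strand = "+"),
    exons = data.frame(tx = "T1", start = 10001, end = 12000))
  expect_equal(GenomicRanges::start(candidateWindow(annc, "G1")), 1)
  expect_error(candidateWindow(plusGene(), "G1", flank = -1), "non-negative")
})

test_that("ctcfBoundedWindow uses the most distant flanking peak midpoint", {
  ann <- plusGene()
  cand <- candidateWindow(ann, "G1")
  body <- ann@genes[1]
  # no CTCF peaks: candidate unchanged
  out <- ctcfBoundedWindow(cand, body, GRanges())
  expect_equal(GenomicRanges::start(out), GenomicRanges::start(cand))
  expect_equal(GenomicRanges::end(out), GenomicRanges::end(cand))
  # two upstream peaks: most distant from the body (midpoint 60000) bounds
  ctcf <- peakGR(c(59900, 79900), c(60100, 80100), tf = "CTCF")
  out2 <- ctcfBoundedWindow(cand, body, ctcf)
  expect_equal(GenomicRanges::start(out2), 60000)
  expect_equal(GenomicRanges::end(out2), GenomicRanges::end(cand))
  # peak inside the gene body only: ignored
  inbody <- peakGR(104900, 105100, tf = "CTCF")
  out3 <- ctcfBoundedWindow(cand, body, inbody)
  expect_equal(GenomicRanges::start(out3), GenomicRanges::start(cand))
  # brute-force oracle: bound = midpoint minimizing distance to candidate edge
  set.seed(11)
  for (rep in 1:20) {
    mids <- sample(45000:165000, 6)
    ctcfr <- peakGR(mids - 100, mids + 100, tf = "CTCF")
    res <- ctcfBoundedWindow(cand, body, ctcfr)
    mid <- floor(((mids - 100) + (mids + 100)) / 2)
    up <- mid[mid >= GenomicRanges::start(cand) &
                mid < GenomicRanges::start(body)]
    dn <- mid[mid <= GenomicRanges::end(cand) &
                mid > GenomicRanges::end(body)]
    expect_equal(GenomicRanges::start(res),
                 if (length(up)) min(up) else GenomicRanges::start(cand))
    expect_equal(GenomicRanges::end(res),
                 if (length(dn)) max(dn) else GenomicRanges::end(cand))
    # always contains the body, always within candidate
    expect_lte(GenomicRanges::start(res), GenomicRanges::start(body))
    expect_gte(GenomicRanges::end(res), GenomicRanges::end(body))
  }
})

test_that("promoterRegion is the 5 kb upstream of the TSS, strand-aware", {
  p <- promoterRegion(plusGene(), "G1")
  expect_equal(c(GenomicRanges::start(p), GenomicRanges::end(p)),
               c(95001, 100000))
  pm <- promoterRegion(minusGene(), "G1")
  expect_equal(c(GenomicRanges::start(pm), GenomicRanges::end(pm)),
               c(110001, 115000))
  annc <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = "T1", start = 2001, end = 4000,
                    strand = "+"),
    exons = data.frame(tx = "T1", start = 2001, end = 4000))
  pc <- promoterRegion(annc, "G1")
  expect_equal(GenomicRanges::start(pc), 1)
  expect_equal(GenomicRanges::end(pc), 2000)
})

test_that("intronicRegions subtracts exon unions and merges across transcripts", {
  # single exon: no introns
  single <- plusGene()
  expect_length(intronicRegions(single, "G1"), 0)
  # span [1,100] with exons [1,20], [81,100] -> intron [21,80]
  ann <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = "T1", start = 1, end = 100,
                    strand = "+"),
    exons = data.frame(tx = c("T1", "T1"), start = c(1, 81), end = c(20, 100)))
  intr <- intronicRegions(ann, "G1")
  expect_equal(as.data.frame(intr)[, c("start", "end")],
               data.frame(start = 21, end = 80))
  # two transcripts with introns [21,80] and [51,120] -> union [21,120]
  ann2 <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = c("T1", "T2"),
                    start = c(1, 31), end = c(100, 140), strand = "+"),
    exons = data.frame(tx = c("T1", "T1", "T2", "T2"),
                       start = c(1, 81, 31, 121), end = c(20, 100, 50, 140)))
  intr2 <- intronicRegions(ann2, "G1")
  expect_equal(as.data.frame(intr2)[, c("start", "end")],
               data.frame(start = 21, end = 120))
  # base-set oracle: intronic bases = union over tx of (span \ exons)
  base_oracle <- union(setdiff(1:100, c(1:20, 81:100)),
                       setdiff(31:140, c(31:50, 121:140)))
  got <- unlist(mapply(`:`, GenomicRanges::start(intr2),
                       GenomicRanges::end(intr2)))
  expect_setequal(got, base_oracle)
  # a transcript's own exonic bases never appear among its own introns:
  # T1 contributes [21,80] which avoids T1 exons; likewise T2
  expect_length(intersect(setdiff(1:100, c(1:20, 81:100)), c(1:20, 81:100)), 0)
  expect_length(intersect(setdiff(31:140, c(31:50, 121:140)),
                          c(31:50, 121:140)), 0)
})

test_that("partitionPeaks assigns one category with promoter precedence", {
  ann <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = "T1", start = 100001, end = 110000,
                    strand = "+"),
    exons = data.frame(tx = c("T1", "T1"), start = c(100001, 106001),
                       end = c(103000, 110000)))  # intron [103001,106000]
  rw <- regulatoryWindows(ann)
  peaks <- peakGR(
    starts = c(96000, 99900, 104000, 120000, 170000),
    ends   = c(96200, 100200, 104200, 120200, 170200),
    tf = "TFA")
  part <- partitionPeaks(peaks, rw)
  # peak straddling promoter/gene boundary -> promoter (precedence)
  expect_equal(as.character(part$category[part$peak_start == 99900]),
               "promoter")
  expect_equal(as.character(part$category[part$peak_start == 96000]),
               "promoter")
  expect_equal(as.character(part$category[part$peak_start == 104000]),
               "intronic")
  expect_equal(as.character(part$category[part$peak_start == 120000]),
               "distal")
  # peak outside the bounded window excluded entirely
  expect_false(170000 %in% part$peak_start)
  # disjoint cover: every in-window peak appears exactly once per gene
  expect_equal(anyDuplicated(part[, c("peak_start", "gene_id")]), 0L)
})

test_that("windows and promoters are strand-reflection symmetric", {
  # reflecting all coordinates about a point and flipping strand must
  # reflect the derived regions
  L <- 300000
  refl <- function(s, e) c(L - e + 1, L - s + 1)
  annp <- plusGene()
  annm <- makeAnnotation(
    tx = data.frame(gene = "G1", tx = "G1.t1",
                    start = refl(100001, 110000)[1],
                    end = refl(100001, 110000)[2], strand = "-"),
    exons = data.frame(tx = "G1.t1", start = refl(100001, 110000)[1],
                       end = refl(100001, 110000)[2]))
  cw_p <- candidateWindow(annp, "G1")
  cw_m <- candidateWindow(annm, "G1")
  expect_equal(c(GenomicRanges::start(cw_m), GenomicRanges::end(cw_m)),
               refl(GenomicRanges::start(cw_p), GenomicRanges::end(cw_p)))
  pr_p <- promoterRegion(annp, "G1")
  pr_m <- promoterRegion(annm, "G1")
  expect_equal(c(GenomicRanges::start(pr_m), GenomicRanges::end(pr_m)),
               refl(GenomicRanges::start(pr_p), GenomicRanges::end(pr_p)))
})

test_that("GTF round trip preserves the annotation", {
  ann <- makeAnnotation(
    tx = data.frame(gene = c("G1", "G2"), tx = c("T1", "T2"),
                    start = c(1000, 50000), end = c(4999, 56000),
                    strand = c("+", "-")),
    exons = data.frame(tx = c("T1", "T1", "T2"),
                       start = c(1000, 3000, 50000),
                       end = c(1999, 4999, 56000)))
  f <- tempfile(fileext = ".gtf")
  writeGeneAnnotationGTF(ann, f)
  back <- readGeneAnnotation(f)
  expect_equal(sort(back@genes$gene_id), c("G1", "G2"))
  expect_equal(GenomicRanges::start(back@transcripts[back@transcripts$tx_id == "T1"]), 1000)
  expect_equal(length(back@exons), 3L)
  expect_equal(as.character(GenomicRanges::strand(back@genes[back@genes$gene_id == "G2"])), "-")
})
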