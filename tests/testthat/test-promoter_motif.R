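test_that("IUPAC matcher implements the degeneracy classes", {
  m <- iupac_matcher("GYGGGG")
  expect_true(m("GCGGGG"))
  expect_true(m("GTGGGG"))
  expect_false(m("GAGGGG"))
  g <- iupac_matcher("GATAA")
  expect_true(g("GATAA"))
  expect_false(g("GATAC"))
  expect_false(g("GATA"))
  n <- iupac_matcher("NNNNN")
  subj <- "ACGTACGTAC"
  hits <- sum(vapply(1:6, function(i) n(substr(subj, i, i + 4)), logical(1)))
  expect_equal(hits, 6L)
  expect_error(iupac_matcher("GAZAA"), "invalid IUPAC")
  expect_error(iupac_matcher(""), "non-empty")
})

test_that("window scanning finds motifs on both strands with gene-frame offsets", {
  # TTATC is the reverse complement of GATAA
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTATCGATAA"))
  gene <- data.frame(gene_id = "g1", contig = "chr1", strand = "+", tss = 0L)
  occ <- scan_window(genome, gene, c(0L, 10L), "GATAA")
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$signed_offset, c(0L, 5L))
  expect_equal(occ$genome_strand, c("-", "+"))
  expect_false(attr(occ, "clipped"))
  # clipping at the contig edge
  genome2 <- Biostrings::DNAStringSet(
    c(chr1 = paste(rep("A", 100), collapse = "")))
  gene2 <- data.frame(gene_id = "g2", contig = "chr1", strand = "+", tss = 50L)
  occ2 <- scan_window(genome2, gene2, c(-200L, 0L), "GATAA")
  expect_true(attr(occ2, "clipped"))
  expect_error(scan_window(genome, gene, c(-5L, 5L), "GATAA"), "one-sided")
  gene_off <- data.frame(gene_id = "g", contig = "chr1", strand = "+",
                         tss = 500L)
  expect_error(scan_window(genome, gene_off, c(0L, 5L), "GATAA"), "off contig")
})

test_that("minus-strand genes map upstream to genomic rightward", {
  # gene on -, TSS at 0-based 14; gene-frame offset o maps to genomic 14 - o
  seq <- paste0(strrep("A", 15), "GATAA", strrep("A", 10))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gene <- data.frame(gene_id = "g1", contig = "chr1", strand = "-", tss = 14L)
  occ <- scan_window(genome, gene, c(-10L, 0L), "GATAA")
  expect_equal(nrow(occ), 1L)
  # site occupies genomic [15,20); 5'-most base in gene frame = 14 - 19 = -5
  expect_equal(occ$genomic_start, 15L)
  expect_equal(occ$signed_offset, -5L)
})

test_that("window scan equals a positionwise brute-force scanner", {
  set.seed(71)
  for (i in 1:60) {
    len <- sample(80:200, 1)
    dna <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(dna, "c1"))
    strand <- sample(c("+", "-"), 1)
    tss <- sample(20:(len - 20), 1)
    gene <- data.frame(gene_id = "g", contig = "c1", strand = strand,
                       tss = tss)
    motif <- sample(c("GATAA", "GYGGGG", "TGA"), 1)
    for (win in list(c(-15L, 0L), c(0L, 15L))) {
      occ <- scan_window(genome, gene, win, motif)
      # oracle: extract the genomic window by first principles and scan
      if (strand == "+") {
        lo <- tss + win[1]; hi <- tss + win[2]
      } else {
        lo <- tss - win[2] + 1; hi <- tss - win[1] + 1
      }
      lo <- max(lo, 0); hi <- min(hi, len)
      wseq <- substr(dna, lo + 1, hi)
      want <- brute_force_motif_scan(wseq, motif)
      want$genomic_start <- lo + want$start
      expect_setequal(paste(occ$genomic_start, occ$genome_strand),
                      paste(want$genomic_start, want$strand))
      # offsets consistent with strand arithmetic
      if (nrow(occ) > 0) {
        want_off <- if (strand == "+") occ$genomic_start - tss else {
          tss - (occ$genomic_end - 1)
        }
        expect_equal(occ$signed_offset, want_off)
      }
    }
  }
})

test_that("count matrix caps at 2, is monotone, and respects planted truth", {
  fx <- small_fixture()
  sim <- fx$sim
  wcm <- count_matrix(sim$genome, sim$genes, "GATAA")
  offs <- sim$truth$planted$GATAA$offsets
  for (i in seq_len(nrow(wcm$intervals))) {
    f <- wcm$intervals$from[i]; t <- wcm$intervals$to[i]
    want <- vapply(sim$genes$gene_id, function(g) {
      min(sum(offs[[g]] >= f & offs[[g]] < t), 2L)
    }, integer(1))
    expect_equal(unname(wcm$category[, i]), unname(want))
  }
  # monotone non-decreasing as upstream windows widen
  up <- wcm$category[, wcm$intervals$from < 0]
  up <- up[, order(-wcm$intervals$from[wcm$intervals$from < 0])]
  expect_true(all(apply(up, 1, function(r) all(diff(r) >= 0))))
  # uncapped counts monotone too
  upc <- (wcm$counts_plus + wcm$counts_minus)[, wcm$intervals$from < 0]
  upc <- upc[, order(-wcm$intervals$from[wcm$intervals$from < 0])]
  expect_true(all(apply(upc, 1, function(r) all(diff(r) >= 0))))
  # no window clipped in this fixture (genes placed away from edges)
  expect_false(any(wcm$clipped))
  expect_error(count_matrix(sim$genome, sim$genes, "GATAA", step = 0L),
               "positive")
  expect_error(count_matrix(sim$genome, sim$genes, "GATAA",
                            max_distance = 2000L, step = 300L), "divide")
})

test_that("three planted sites in one window give category 2", {
  site <- "GATAA"
  parts <- c(strrep("C", 30), site, strrep("C", 20), site, strrep("C", 20),
             site, strrep("C", 100))
  seq <- paste(parts, collapse = "")
  tss <- nchar(seq) - 100L
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "c1"))
  gene <- data.frame(gene_id = "g", contig = "c1", strand = "+", tss = tss)
  wcm <- count_matrix(genome, gene, "GATAA", max_distance = 200L, step = 200L)
  expect_equal(unname(wcm$category[, "[-200,0)"]), 2L)
  expect_equal(unname(wcm$counts_plus[, "[-200,0)"]), 3L)
  expect_equal(unname(wcm$category[, "[0,200)"]), 0L)
  expect_true(wcm$clipped[, "[-200,0)"])   # only 105 bp upstream exist
})

test_that("strand symmetry: reverse-complementing the genome preserves counts", {
  fx <- small_fixture()
  sim <- fx$sim
  wcm <- count_matrix(sim$genome, sim$genes, "GATAA")
  rc <- Biostrings::reverseComplement(sim$genome[[1]])
  genome_rc <- Biostrings::DNAStringSet(stats::setNames(
    as.character(rc), names(sim$genome)[1]))
  L <- length(sim$genome[[1]])
  genes_rc <- sim$genes
  genes_rc$strand <- ifelse(sim$genes$strand == "+", "-", "+")
  genes_rc$tss <- L - 1L - sim$genes$tss
  wcm_rc <- count_matrix(genome_rc, genes_rc, "GATAA")
  expect_equal(wcm_rc$category, wcm$category)
  expect_equal(wcm_rc$clipped, wcm$clipped)
})

test_that("per-strand categories are available via the config switch", {
  fx <- small_fixture()
  sim <- fx$sim
  wcm <- count_matrix(sim$genome, sim$genes, "GATAA")
  both <- category_matrix(wcm, "both")
  plus <- category_matrix(wcm, "plus")
  minus <- category_matrix(wcm, "minus")
  expect_equal(both, wcm$category)
  expect_true(all(plus <= both & minus <= both))
  expect_equal(pmin(wcm$counts_plus + wcm$counts_minus, 2L), both)
})

test_that("BED export round-trips coordinates exactly", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTATCGATAA"))
  gene <- data.frame(gene_id = "g1", contig = "chr1", strand = "+", tss = 0L)
  occ <- scan_window(genome, gene, c(0L, 10L), "GATAA")
  tmp <- tempfile(fileext = ".bed")
  export_sites(occ, tmp)
  back <- read_sites_bed(tmp)
  expect_equal(back$genomic_start, occ$genomic_start)
  expect_equal(back$genomic_end, occ$genomic_end)
  expect_equal(back$strand, occ$genome_strand)
  expect_equal(back$name, paste0(occ$gene_id, ":", occ$motif_name))
  # empty export: header-only file, empty parse
  export_sites(occ[0, ], tmp)
  expect_equal(readLines(tmp)[1], "# contig\tstart\tend\tname\tscore\tstrand")
  expect_equal(nrow(read_sites_bed(tmp)), 0L)
  unlink(tmp)
})

test_that("gene models load from GFF3 and BED with correct TSS", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t600\t.\t+\t.\tID=gp",
               "c1\tsrc\tgene\t901\t1400\t.\t-\t.\tID=gm"), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$tss[gm$gene_id == "gp"], 100L)   # 0-based start
  expect_equal(gm$tss[gm$gene_id == "gm"], 1399L)  # 0-based end-1
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t600\tgp\t0\t+", "c1\t900\t1400\tgm\t0\t-"), bed)
  gb <- read_gene_models(bed)
  expect_equal(gb$tss, gm$tss)
  unlink(c(gff, bed))
})
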