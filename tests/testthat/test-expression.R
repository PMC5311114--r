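mk_expr <- function(fpkm_list, conditions = NULL) {
  # fpkm_list: named list gene -> named numeric per sample
  genes <- names(fpkm_list)
  fpkm <- do.call(rbind, fpkm_list)
  rownames(fpkm) <- genes
  samp <- colnames(fpkm)
  parts <- strsplit(samp, "_")
  samples <- data.frame(sample = samp,
                        strain = vapply(parts, `[`, "", 1),
                        condition = vapply(parts, `[`, "", 2),
                        replicate = as.integer(vapply(parts, `[`, "", 3)),
                        stringsAsFactors = FALSE)
  expression_matrix(fpkm, samples)
}

test_that("log2 fold change recovers known ratios and is antisymmetric", {
  expr <- mk_expr(list(
    dga1 = c(WT_amm_1 = 14, WT_amm_2 = 14, WT_pep_1 = 1, WT_pep_2 = 1),
    flat = c(WT_amm_1 = 5, WT_amm_2 = 5, WT_pep_1 = 5, WT_pep_2 = 5)))
  lfc <- log2_fold_change(expr, list(condition = "amm"),
                          list(condition = "pep"), pseudocount = 1e-9)
  # a 14-fold ammonium-vs-peptone ratio: log2(14) = 3.807
  expect_equal(unname(lfc["dga1"]), log2(14), tolerance = 1e-6)
  expect_equal(unname(lfc["flat"]), 0)
  swapped <- log2_fold_change(expr, list(condition = "pep"),
                              list(condition = "amm"), pseudocount = 1e-9)
  expect_equal(as.numeric(swapped), -as.numeric(lfc))
  expect_error(log2_fold_change(expr, list(condition = "urea"),
                                list(condition = "pep")), "no samples")
  expect_error(log2_fold_change(expr, list(nope = "x"),
                                list(condition = "pep")), "unknown")
})

test_that("pseudocount keeps fold changes finite at zero FPKM", {
  expr <- mk_expr(list(off = c(A_x_1 = 0, B_x_1 = 8)))
  lfc <- log2_fold_change(expr, list(strain = "A"), list(strain = "B"))
  expect_true(is.finite(lfc[["off"]]))
  expect_equal(lfc[["off"]], log2(0.1 / 8.1))
})

test_that("replicate aggregation modes agree on noise-free data", {
  expr <- mk_expr(list(g1 = c(M_x_1 = 8, M_x_2 = 8, W_x_1 = 2, W_x_2 = 2)))
  a <- log2_fold_change(expr, list(strain = "M"), list(strain = "W"),
                        pseudocount = 1e-9)
  b <- log2_fold_change(expr, list(strain = "M"), list(strain = "W"),
                        pseudocount = 1e-9, aggregate = "mean_ratio")
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
})

test_that("binning by motif count partitions genes and recovers means", {
  fx <- small_fixture()
  wcm <- count_matrix(fx$sim$genome, fx$sim$genes, "GATAA")
  lfc <- log2_fold_change(fx$expr, list(strain = "mutant"),
                          list(strain = "WT"))
  bins <- bin_by_motif_count(lfc, wcm)
  # conservation: per-interval bin sizes sum to the gene count
  for (lab in unique(bins$interval)) {
    expect_equal(sum(bins$n[bins$interval == lab]), length(fx$sim$genes$gene_id))
  }
  # weighted mean of bin means equals the overall mean
  b1 <- bins[bins$interval == "[-2000,0)" & bins$n > 0, ]
  expect_equal(sum(b1$mean_delta * b1$n) / sum(b1$n), mean(lfc),
               tolerance = 1e-12)
  # per-category means equal direct aggregation
  cats <- wcm$category[names(lfc), "[-2000,0)"]
  for (k in 0:2) {
    if (sum(cats == k) > 0) {
      expect_equal(b1$mean_delta[b1$category == k],
                   mean(lfc[cats == k]))
    }
  }
  expect_error(bin_by_motif_count(stats::setNames(1, "zzz"), wcm), "shared")
})

test_that("planted linear effect is recovered within simulation tolerance", {
  fx <- small_fixture()   # beta = 0.5, sigma = 0.5, 4 replicates
  wcm <- count_matrix(fx$sim$genome, fx$sim$genes, "GATAA")
  lfc <- log2_fold_change(fx$expr, list(strain = "mutant"),
                          list(strain = "WT"))
  bins <- bin_by_motif_count(lfc, wcm)
  b <- bins[bins$interval == "[-2000,0)" & bins$n > 0, ]
  # each bin mean within 3 sigma / sqrt(n) of beta * category
  # (per-gene lfc variance: 2 sigma^2 / replicates, under 0.5^2 here)
  for (r in seq_len(nrow(b))) {
    expect_lt(abs(b$mean_delta[r] - 0.5 * b$category[r]),
              3 * 0.5 / sqrt(b$n[r]))
  }
})

test_that("no-effect motif shows a flat profile where the causal one rises", {
  fx <- small_fixture()
  lfc <- log2_fold_change(fx$expr, list(strain = "mutant"),
                          list(strain = "WT"))
  counts <- list(
    GATAA = count_matrix(fx$sim$genome, fx$sim$genes, "GATAA"),
    GYGGGG = count_matrix(fx$sim$genome, fx$sim$genes, "GYGGGG"))
  summ <- motif_promoter_summary(lfc, counts)
  expect_equal(nrow(summ),
               nrow(bin_by_motif_count(lfc, counts$GATAA)) * 2)
  s_gata <- category_effect_slope(summ[summ$motif == "GATAA", ], "[-2000,0)")
  s_cre <- category_effect_slope(summ[summ$motif == "GYGGGG", ], "[-2000,0)")
  expect_gt(s_gata, 0.3)
  expect_lt(abs(s_cre), 0.2)
  expect_error(motif_promoter_summary(lfc, list()), "at least one")
})

test_that("rank-sum shift test matches exact enumeration on small samples", {
  set.seed(81)
  for (i in 1:12) {
    nx <- sample(3:6, 1); ny <- sample(3:8, 1)
    x <- round(stats::rnorm(nx), 3)
    y <- round(stats::rnorm(ny, 0.5), 3)
    if (any(duplicated(c(x, y)))) next
    lfc <- stats::setNames(c(x, y), paste0("g", seq_len(nx + ny)))
    st <- gene_set_shift_test(lfc, paste0("g", seq_len(nx)))
    expect_equal(st$p, enumerate_ranksum_p(x, y), tolerance = 1e-12)
    expect_equal(st$U, sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
  }
})

test_that("extreme separation gives the maximal U and minimal p", {
  lfc <- stats::setNames(c(10, 11, 12, 1:20 / 100), c(paste0("s", 1:3),
                                                      paste0("b", 1:20)))
  st <- gene_set_shift_test(lfc, paste0("s", 1:3))
  expect_equal(st$U, 60)            # 3 * 20, all pairs won
  expect_equal(st$direction, 1)
  expect_lt(st$p, 0.005)
  expect_error(gene_set_shift_test(lfc, "absent"), "at least one")
})

test_that("top-N selection respects n, direction, and id tie-breaks", {
  lfc <- stats::setNames(c(3, 1, 2, 1), c("d", "b", "a", "c"))
  expect_equal(top_n_genes(lfc, 500), c("d", "a", "b", "c"))
  expect_equal(top_n_genes(lfc, 2, direction = "down"), c("b", "c"))
  expect_equal(top_n_genes(lfc, 1), "d")
})

test_that("enrichment matches the combinatorial oracle with Bonferroni", {
  # N = 20 exhaustive check across all k for several (K, n)
  universe <- sprintf("u%02d", 1:20)
  for (K in c(3, 5, 8)) {
    for (n in c(4, 7)) {
      gs <- gene_set_collection(universe, list(S = universe[1:K]))
      for (k in 0:min(n, K)) {
        lst <- c(universe[seq_len(k)],
                 if (k < n) universe[(K + 1):(K + n - k)])
        row <- enrich(lst, gs)
        expect_equal(row$p_raw, enumerate_hyper_p(k, K, 20, n),
                     tolerance = 1e-12)
        expect_equal(row$fold_enrichment, (k / n) / (K / 20))
      }
    }
  }
  # Bonferroni multiplies by the number of sets, capped at 1
  sets10 <- stats::setNames(lapply(1:10, function(i) universe[i]),
                            paste0("T", 1:10))
  gs10 <- gene_set_collection(universe, sets10)
  res <- enrich(universe[1:4], gs10)
  expect_equal(res$p_corrected, pmin(1, res$p_raw * 10))
  # null enrichment: k/n = K/N gives fold enrichment 1, universe vs itself p = 1
  gsu <- gene_set_collection(universe, list(all = universe))
  ru <- enrich(universe, gsu)
  expect_equal(ru$fold_enrichment, 1)
  expect_equal(ru$p_raw, 1)
  expect_error(enrich(c(universe[1], "zzz"), gs10), "outside")
})

test_that("gene-set IO accepts GMT and two-column TSV", {
  universe <- paste0("g", 1:10)
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), gmt)
  gs <- read_gene_sets(gmt, universe)
  expect_equal(gs$sets$setA, c("g1", "g2", "g3"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("setA\tg1", "setA\tg2", "setB\tg9"), tsv)
  gs2 <- read_gene_sets(tsv, universe)
  expect_equal(gs2$sets$setB, "g9")
  unlink(c(gmt, tsv))
})

test_that("expression matrix validation catches malformed inputs", {
  fpkm <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  samples <- data.frame(sample = c("s1", "s2"), strain = "W",
                        condition = "x", replicate = 1:2)
  expect_error(expression_matrix(fpkm, samples), "unique")
  fpkm2 <- matrix(-1, 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(expression_matrix(fpkm2, samples), "non-negative")
})
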