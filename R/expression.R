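# Expression-response statistics: fold changes from FPKM tables, motif-count
# binning of mutant-vs-wild-type differences, gene-set distribution-shift
# tests, and top-N gene-list enrichment with Bonferroni correction.

#' Construct an expression matrix
#'
#' @param fpkm non-negative numeric matrix, rows = genes (rownames = unique
#'   gene ids), columns = samples.
#' @param samples data.frame with columns sample, strain, condition,
#'   replicate; `sample` must match the fpkm column names.
#' @return list of class `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, samples) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)))
  if (anyDuplicated(rownames(fpkm))) stop("gene ids must be unique")
  if (anyDuplicated(samples$sample)) stop("sample labels must be unique")
  if (!identical(sort(colnames(fpkm)), sort(samples$sample))) {
    stop("fpkm columns and sample metadata do not match")
  }
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  structure(list(fpkm = fpkm[, samples$sample, drop = FALSE],
                 samples = samples),
            class = "expression_matrix")
}

#' Read an expression TSV plus sample metadata
#'
#' @param expr_path TSV with a gene_id column and one numeric column per
#'   sample.
#' @param meta_path TSV with columns sample, strain, condition, replicate.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(expr_path, meta_path) {
  expr <- read_tsv(expr_path)
  meta <- read_tsv(meta_path)
  fpkm <- as.matrix(expr[, setdiff(colnames(expr), "gene_id"), drop = FALSE])
  rownames(fpkm) <- expr$gene_id
  expression_matrix(fpkm, meta)
}

select_samples <- function(expr, group) {
  keep <- rep(TRUE, nrow(expr$samples))
  for (field in names(group)) {
    if (!field %in% colnames(expr$samples)) {
      stop("unknown sample metadata field: ", field)
    }
    keep <- keep & expr$samples[[field]] == group[[field]]
  }
  if (!any(keep)) {
    stop("no samples match group: ",
         paste(names(group), unlist(group), sep = "=", collapse = ","))
  }
  expr$samples$sample[keep]
}

#' Per-gene log2 fold change between two sample groups
#'
#' Fold change is computed on group-mean FPKM with a pseudocount:
#' `lfc = log2((mean_num + eps) / (mean_den + eps))`. With
#' `aggregate = "mean_ratio"` the mean of per-replicate log2 ratios is used
#' instead (requires equal replicate counts).
#'
#' @param expr an `expression_matrix`.
#' @param numerator,denominator named lists selecting sample groups on the
#'   metadata columns, e.g. `list(strain = "gzf3", condition = "ammonium")`.
#' @param pseudocount FPKM pseudocount eps > 0 (default 0.1).
#' @param aggregate replicate aggregation: `"mean_fpkm"` (default) averages
#'   FPKM within each group before the ratio; `"mean_ratio"` averages
#'   per-replicate log2 ratios.
#' @return named numeric vector of per-gene log2 fold changes, with the
#'   contrast and pseudocount stored as attributes.
#' @export
log2_fold_change <- function(expr, numerator, denominator, pseudocount = 0.1,
                             aggregate = c("mean_fpkm", "mean_ratio")) {
  stopifnot(inherits(expr, "expression_matrix"), pseudocount > 0)
  aggregate <- match.arg(aggregate)
  num_s <- select_samples(expr, numerator)
  den_s <- select_samples(expr, denominator)
  num <- expr$fpkm[, num_s, drop = FALSE]
  den <- expr$fpkm[, den_s, drop = FALSE]
  if (aggregate == "mean_fpkm") {
    lfc <- log2((rowMeans(num) + pseudocount) /
                (rowMeans(den) + pseudocount))
  } else {
    if (ncol(num) != ncol(den)) {
      stop("mean_ratio aggregation requires equal replicate counts")
    }
    lfc <- rowMeans(log2((num + pseudocount) / (den + pseudocount)))
  }
  structure(lfc,
            contrast = list(numerator = numerator, denominator = denominator),
            pseudocount = pseudocount)
}

#' Bin fold changes by capped promoter motif count
#'
#' For every (window, category) cell, averages the log2 fold change of the
#' member genes. A positive mean indicates higher expression in the contrast
#' numerator (e.g. the mutant strain).
#'
#' @param lfc named numeric vector of per-gene log2 fold changes.
#' @param wcm a `window_count_matrix` for one motif.
#' @param drop_clipped exclude a gene from a window's bins when that window
#'   was truncated at a contig edge (default TRUE).
#' @return data.frame with columns interval, from, to, category, mean_delta,
#'   n; `mean_delta` is NA when a bin is empty (n = 0).
#' @export
bin_by_motif_count <- function(lfc, wcm, drop_clipped = TRUE) {
  common <- intersect(names(lfc), wcm$genes)
  if (length(common) == 0) stop("no genes shared between lfc and counts")
  cat_m <- wcm$category[common, , drop = FALSE]
  clip <- wcm$clipped[common, , drop = FALSE]
  vals <- lfc[common]
  out <- list()
  for (i in seq_len(nrow(wcm$intervals))) {
    use <- if (drop_clipped) !clip[, i] else rep(TRUE, length(common))
    for (k in 0:2) {
      members <- use & cat_m[, i] == k
      n <- sum(members)
      out[[length(out) + 1L]] <- data.frame(
        interval = wcm$intervals$label[i],
        from = wcm$intervals$from[i], to = wcm$intervals$to[i],
        category = k,
        mean_delta = if (n > 0) mean(vals[members]) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Slope of bin mean fold change against motif-count category
#'
#' Weighted least-squares slope of `mean_delta` on `category` (weights = bin
#' sizes) for one window; recovers the per-site effect size on synthetic
#' data with a linear planted effect.
#'
#' @param bins output of [bin_by_motif_count()].
#' @param interval window label to use (e.g. `"[-2000,0)"`).
#' @return numeric slope (lfc units per capped motif count).
#' @export
category_effect_slope <- function(bins, interval) {
  b <- bins[bins$interval == interval & bins$n > 0, ]
  if (nrow(b) < 2) stop("need at least two non-empty categories in ", interval)
  stats::coef(stats::lm(mean_delta ~ category, data = b, weights = b$n))[["category"]]
}

#' Long-form motif/window/category summary across motifs
#'
#' Concatenates [bin_by_motif_count()] across motifs into a tidy table
#' (motif, interval, from, to, category, mean_delta, n) — the plotting
#' surface for motif-count response profiles.
#'
#' @param lfc named numeric vector of log2 fold changes.
#' @param counts_by_motif named list of `window_count_matrix` objects.
#' @param drop_clipped see [bin_by_motif_count()].
#' @return data.frame in long form.
#' @export
motif_promoter_summary <- function(lfc, counts_by_motif, drop_clipped = TRUE) {
  if (length(counts_by_motif) == 0) stop("supply at least one motif's counts")
  out <- lapply(names(counts_by_motif), function(m) {
    b <- bin_by_motif_count(lfc, counts_by_motif[[m]],
                            drop_clipped = drop_clipped)
    cbind(motif = m, b, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank-sum test for a fold-change distribution shift in a gene set
#'
#' Mann-Whitney U comparison of the set's fold changes against the
#' complement of the set within the background (using the complement keeps
#' the null exact). Exact enumeration is used for small, tie-free samples
#' (both groups <= 20); otherwise the normal approximation with tie
#' correction.
#'
#' @param lfc named numeric vector of log2 fold changes.
#' @param set character vector of gene ids.
#' @param background character vector of gene ids (default: all genes in
#'   `lfc`).
#' @param exact_max largest group size for which the exact distribution is
#'   used (default 20).
#' @return list with `U`, `p` (two-sided), `direction` (-1/0/1: sign of the
#'   set-vs-complement median difference), `n_set`, `n_background`.
#' @export
gene_set_shift_test <- function(lfc, set, background = names(lfc),
                                exact_max = 20) {
  set <- intersect(set, names(lfc))
  background <- intersect(background, names(lfc))
  x <- lfc[intersect(set, background)]
  y <- lfc[setdiff(background, set)]
  if (length(x) == 0 || length(y) == 0) {
    stop("set and complement must each contain at least one gene")
  }
  use_exact <- max(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value,
       direction = sign(stats::median(x) - stats::median(y)),
       n_set = length(x), n_background = length(y))
}

#' Top-N genes by fold change
#'
#' @param lfc named numeric vector of log2 fold changes.
#' @param n list size (default 500); if fewer genes exist, all are returned.
#' @param direction `"up"` (descending lfc) or `"down"` (ascending).
#' @return character vector of gene ids; ties break by gene id.
#' @export
top_n_genes <- function(lfc, n = 500, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  ord <- if (direction == "up") {
    order(-lfc, names(lfc))
  } else {
    order(lfc, names(lfc))
  }
  names(lfc)[ord][seq_len(min(n, length(lfc)))]
}

#' Construct a gene-set collection
#'
#' @param universe character vector of gene ids (the background).
#' @param sets named list of character vectors, each a subset of the
#'   universe.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(universe, sets) {
  universe <- unique(universe)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names")
  }
  sets <- lapply(sets, unique)
  outside <- lapply(sets, setdiff, universe)
  bad <- names(sets)[vapply(outside, length, integer(1)) > 0]
  if (length(bad) > 0) {
    stop("set(s) contain genes outside the universe: ",
         paste(bad, collapse = ", "))
  }
  structure(list(universe = universe, sets = sets),
            class = "gene_set_collection")
}

#' Read gene sets from GMT or two-column TSV
#'
#' @param path `.gmt` file (set, description, genes...) or a two-column TSV
#'   (set name, gene id).
#' @param universe background gene ids; sets are intersected with it.
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path, universe) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- strsplit(readLines(path), "\t")
    sets <- stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                            vapply(lines, `[`, character(1), 1))
  } else {
    df <- read.table(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    sets <- split(df[[2]], df[[1]])
  }
  gene_set_collection(universe, lapply(sets, intersect, universe))
}

#' Hypergeometric gene-list enrichment with Bonferroni correction
#'
#' For each set: k = list members in the set, n = list size, K = set size,
#' N = universe size; fold enrichment = (k/n) / (K/N); p_raw = upper-tail
#' hypergeometric P(X >= k); p_corrected = min(1, p_raw * number of sets).
#' Rows with k = 0 are retained (fold enrichment 0).
#'
#' @param gene_list character vector of gene ids, a subset of the universe.
#' @param collection a `gene_set_collection`.
#' @return data.frame with columns set, k, n, K, N, fold_enrichment, p_raw,
#'   p_corrected, sorted by (p_corrected, set).
#' @export
enrich <- function(gene_list, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, collection$universe)
  if (length(outside) > 0) {
    stop("gene list contains ids outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  }
  N <- length(collection$universe)
  n <- length(gene_list)
  m <- length(collection$sets)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    K <- length(s)
    k <- length(intersect(gene_list, s))
    p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_raw = p_raw,
               p_corrected = min(1, p_raw * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_corrected, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
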