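# Orientation-aware promoter motif counting around transcription start sites.
#
# Coordinates: genomic positions are 0-based, end-exclusive (BED convention).
# The gene-oriented frame puts the TSS at 0 with upstream negative; for a
# minus-strand gene "upstream" is genomic rightward. A motif occurrence's
# position in the gene frame is its 5'-most base in that frame, and an
# occurrence counts toward a window iff that base lies inside the window.

#' Build a predicate for an IUPAC motif
#'
#' @param iupac motif string over the IUPAC nucleotide alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return function taking a DNA string and returning TRUE iff it matches the
#'   motif exactly (same length, every base in the position's IUPAC class).
#' @export
iupac_matcher <- function(iupac) {
  code <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(toupper(iupac), "")[[1]]
  if (length(letters) == 0) stop("motif must be non-empty")
  bad <- setdiff(letters, names(code))
  if (length(bad) > 0) {
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  }
  classes <- strsplit(unname(code[letters]), "")
  function(dna) {
    x <- strsplit(toupper(dna), "")[[1]]
    if (length(x) != length(classes)) return(FALSE)
    all(mapply(function(base, cls) base %in% cls, x, classes))
  }
}

#' Read a genome FASTA
#'
#' @param path FASTA file of contigs.
#' @return a `DNAStringSet`; names are truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read gene models with TSS from GFF3 or BED
#'
#' The TSS is the annotated transcript 5' end: for plus-strand genes the
#' feature start, for minus-strand genes the feature end.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return data.frame with columns gene_id, contig, strand, tss (0-based
#'   genomic coordinate), start, end (0-based half-open span).
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    gr <- gr[gr$type == feature_type]
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  } else {
    ids <- gr$name
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("gene models must have a defined strand")
  start0 <- BiocGenerics::start(gr) - 1L           # to 0-based
  end0 <- BiocGenerics::end(gr)                    # half-open
  data.frame(gene_id = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             tss = ifelse(strand == "+", start0, end0 - 1L),
             start = start0, end = end0,
             stringsAsFactors = FALSE)
}

# Internal: map a gene-frame interval [from, to) to genomic coordinates,
# clip at contig edges, and scan both genome strands for the motif.
# Returns list(occ = data.frame, clipped_left, clipped_right) where
# left/right refer to the gene frame (left = more upstream).
scan_gene_frame <- function(genome, gene, from, to, motif,
                            motif_name = motif) {
  if (!(gene$contig %in% names(genome))) {
    stop("contig not in genome: ", gene$contig)
  }
  contig <- genome[[gene$contig]]
  len <- length(contig)
  t <- gene$tss
  if (t < 0 || t >= len) stop("gene ", gene$gene_id, " TSS off contig")
  if (gene$strand == "+") {
    gs <- t + from; ge <- t + to              # 0-based half-open genomic
  } else {
    gs <- t - to + 1L; ge <- t - from + 1L
  }
  clip_lo <- max(gs, 0L); clip_hi <- min(ge, len)
  if (gene$strand == "+") {
    clipped_left <- clip_lo > gs; clipped_right <- clip_hi < ge
  } else {
    clipped_left <- clip_hi < ge; clipped_right <- clip_lo > gs
  }
  occ <- empty_occurrences()
  if (clip_hi - clip_lo >= nchar(motif)) {
    s <- Biostrings::subseq(contig, start = clip_lo + 1L, end = clip_hi)
    pat <- Biostrings::DNAString(motif)
    fwd <- Biostrings::matchPattern(pat, s, fixed = FALSE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), s,
                                    fixed = FALSE)
    mk <- function(m, strand_chr) {
      if (length(m) == 0) return(empty_occurrences())
      g0 <- clip_lo + BiocGenerics::start(m) - 1L      # genomic 0-based start
      g1 <- g0 + nchar(motif)
      off <- if (gene$strand == "+") g0 - t else t - (g1 - 1L)
      data.frame(gene_id = gene$gene_id, motif_name = motif_name,
                 contig = gene$contig,
                 genomic_start = g0, genomic_end = g1,
                 genome_strand = strand_chr, signed_offset = off,
                 stringsAsFactors = FALSE)
    }
    occ <- rbind(mk(fwd, "+"), mk(rev, "-"))
    occ <- occ[order(occ$signed_offset, occ$genome_strand), , drop = FALSE]
    rownames(occ) <- NULL
  }
  list(occ = occ, clipped_left = clipped_left, clipped_right = clipped_right)
}

empty_occurrences <- function() {
  data.frame(gene_id = character(), motif_name = character(),
             contig = character(), genomic_start = integer(),
             genomic_end = integer(), genome_strand = character(),
             signed_offset = integer(), stringsAsFactors = FALSE)
}

#' Scan one promoter window of a gene for a motif on both strands
#'
#' The window is given in the gene-oriented frame (TSS = 0, upstream
#' negative) and must be one-sided: `[-d, 0)` or `[0, d)`. The corresponding
#' genomic window is scanned on both strands; every overlapping occurrence
#' fully inside the window is reported. Windows truncated at a contig edge
#' are flagged via the `"clipped"` attribute.
#'
#' @param genome `DNAStringSet` of contigs.
#' @param gene one-row data.frame (or list) with gene_id, contig, strand, tss.
#' @param window length-2 integer vector `c(from, to)`, half-open, either
#'   `c(-d, 0)` or `c(0, d)` with d > 0.
#' @param motif IUPAC motif string.
#' @param motif_name label recorded in the output (defaults to the motif).
#' @return data.frame of occurrences (gene_id, motif_name, contig,
#'   genomic_start, genomic_end, genome_strand, signed_offset) with a logical
#'   `"clipped"` attribute.
#' @export
scan_window <- function(genome, gene, window, motif, motif_name = motif) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!(window[2] == 0 && window[1] < 0) && !(window[1] == 0 && window[2] > 0)) {
    stop("window must be one-sided: [-d, 0) or [0, d)")
  }
  res <- scan_gene_frame(genome, gene, as.integer(window[1]),
                         as.integer(window[2]), motif, motif_name)
  structure(res$occ, clipped = res$clipped_left || res$clipped_right)
}

#' Per-gene capped motif counts over a grid of TSS windows
#'
#' For each gene, counts motif occurrences (both genome strands) in the
#' windows `[-d, 0)` and `[0, d)` for d = step, 2*step, ..., max_distance,
#' assigning an occurrence to a window iff its 5'-most base in the gene frame
#' lies inside it. Counts are categorised as 0, 1, or 2 (= "2 or more").
#' Windows truncated at a contig edge are flagged in `clipped`.
#'
#' @param genome `DNAStringSet` of contigs.
#' @param genes data.frame of gene models (see [read_gene_models()]).
#' @param motif IUPAC motif string.
#' @param max_distance largest window extent in bp (default 2000).
#' @param step window grid step in bp (default 200); must divide max_distance.
#' @param motif_name label for the motif.
#' @return object of class `window_count_matrix`: list with `genes`,
#'   `motif_name`, `intervals` (data.frame label/from/to), `counts_plus`,
#'   `counts_minus` (uncapped per-strand integer matrices), `category`
#'   (combined both-strand count capped at 2) and `clipped` (logical matrix).
#'   Use [category_matrix()] for per-strand capped categories.
#' @export
count_matrix <- function(genome, genes, motif, max_distance = 2000L,
                         step = 200L, motif_name = motif) {
  if (step <= 0) stop("step must be positive")
  if (max_distance %% step != 0) stop("step must divide max_distance")
  ds <- seq(step, max_distance, by = step)
  intervals <- data.frame(
    label = c(paste0("[-", ds, ",0)"), paste0("[0,", ds, ")")),
    from = c(-ds, rep(0L, length(ds))),
    to = c(rep(0L, length(ds)), ds),
    stringsAsFactors = FALSE)
  ng <- nrow(genes); ni <- nrow(intervals)
  mlen <- nchar(motif)
  cp <- cm <- matrix(0L, ng, ni,
                     dimnames = list(genes$gene_id, intervals$label))
  clipped <- matrix(FALSE, ng, ni,
                    dimnames = list(genes$gene_id, intervals$label))
  for (g in seq_len(ng)) {
    gene <- genes[g, ]
    # one broad scan; + mlen - 1 so occurrences whose 5'-most base sits just
    # inside the outermost downstream window are fully covered
    res <- scan_gene_frame(genome, gene, -max_distance,
                           max_distance + mlen - 1L, motif, motif_name)
    off <- res$occ$signed_offset
    str <- res$occ$genome_strand
    contig_len <- length(genome[[gene$contig]])
    avail_up <- if (gene$strand == "+") gene$tss else contig_len - 1L - gene$tss
    avail_down <- if (gene$strand == "+") contig_len - gene$tss else gene$tss + 1L
    for (i in seq_len(ni)) {
      inside <- off >= intervals$from[i] & off < intervals$to[i]
      cp[g, i] <- sum(inside & str == "+")
      cm[g, i] <- sum(inside & str == "-")
      d <- if (intervals$from[i] < 0) -intervals$from[i] else intervals$to[i]
      clipped[g, i] <- if (intervals$from[i] < 0) d > avail_up else d > avail_down
    }
  }
  structure(list(genes = genes$gene_id, motif_name = motif_name,
                 intervals = intervals, counts_plus = cp, counts_minus = cm,
                 category = pmin(cp + cm, 2L), clipped = clipped),
            class = "window_count_matrix")
}

#' Capped category matrix from a window count matrix
#'
#' @param wcm a `window_count_matrix`.
#' @param strand `"both"` (combined count, the default reading of the 0/1/2+
#'   categories), `"plus"` or `"minus"` for per-strand categories.
#' @param cap category cap (default 2 = "2 or more").
#' @return integer matrix gene x interval with values 0..cap.
#' @export
category_matrix <- function(wcm, strand = c("both", "plus", "minus"),
                            cap = 2L) {
  strand <- match.arg(strand)
  counts <- switch(strand,
                   both = wcm$counts_plus + wcm$counts_minus,
                   plus = wcm$counts_plus,
                   minus = wcm$counts_minus)
  pmin(counts, as.integer(cap))
}

#' @export
print.window_count_matrix <- function(x, ...) {
  cat("window_count_matrix:", length(x$genes), "genes x",
      nrow(x$intervals), "windows; motif", x$motif_name, "\n")
  cat("category distribution:",
      paste(names(table(x$category)), table(x$category),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a window count matrix to TSV
#'
#' @param wcm a `window_count_matrix`.
#' @param path output file; categories 0/1/2 per window plus a
#'   `clipped_<label>` column per window.
#' @export
write_count_matrix <- function(wcm, path) {
  df <- data.frame(gene_id = wcm$genes, wcm$category, check.names = FALSE)
  cl <- wcm$clipped
  colnames(cl) <- paste0("clipped_", wcm$intervals$label)
  write_tsv(cbind(df, cl), path,
            comment = paste0("motif=", wcm$motif_name,
                             "; categories capped at 2 (2 = two or more)"))
  invisible(path)
}

#' Export motif occurrences as BED6
#'
#' Emits 0-based half-open records (contig, start, end, name =
#' `gene_id:motif`, score 0, strand), sorted by (contig, start), preceded by
#' a '#' header comment.
#'
#' @param occurrences data.frame of occurrences from [scan_window()].
#' @param path output BED file.
#' @export
export_sites <- function(occurrences, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# contig\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(occurrences) > 0) {
    o <- occurrences[order(occurrences$contig, occurrences$genomic_start), ]
    writeLines(paste(o$contig, o$genomic_start, o$genomic_end,
                     paste0(o$gene_id, ":", o$motif_name), 0L,
                     o$genome_strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED6 sites file back into genomic intervals
#'
#' @param path BED file written by [export_sites()].
#' @return data.frame with contig, genomic_start, genomic_end, name, strand
#'   (0-based half-open).
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), genomic_start = integer(),
                      genomic_end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  tmp <- tempfile(fileext = ".bed")
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  unlink(tmp)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             genomic_start = BiocGenerics::start(gr) - 1L,
             genomic_end = BiocGenerics::end(gr),
             name = gr$name,
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}
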