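# Synthetic-data generators with machine-readable ground truth.
#
# Every generator is deterministic given (parameters, seed): a master seed is
# fanned out to per-component child seeds with derive_seed(). Backgrounds are
# motif-free by construction (iterative rescan-and-redraw), so planted-count
# recovery is exact rather than statistical.

DNA_BASES <- c("A", "C", "G", "T")

# Genomes are manipulated internally as raw byte vectors (one base per
# byte), which makes the redraw/replant edits O(bases touched) instead of
# copying a multi-megabase string.
rand_bases_raw <- function(n) {
  charToRaw("ACGT")[sample.int(4L, n, replace = TRUE)]
}

# Redraw bases until the contig contains zero occurrences (either strand) of
# any of the motifs. Works on a raw vector of bases.
scrub_motifs <- function(bytes, motifs, max_pass = 50) {
  for (pass in seq_len(max_pass)) {
    dna <- Biostrings::DNAString(rawToChar(bytes))
    hit_pos <- integer(0)
    for (m in motifs) {
      for (pat in list(Biostrings::DNAString(m),
                       Biostrings::reverseComplement(Biostrings::DNAString(m)))) {
        mt <- Biostrings::matchPattern(pat, dna, fixed = FALSE)
        if (length(mt) > 0) {
          hit_pos <- c(hit_pos,
                       sequence(BiocGenerics::width(mt),
                                from = BiocGenerics::start(mt)))
        }
      }
    }
    hit_pos <- unique(hit_pos)
    if (length(hit_pos) == 0) return(bytes)
    bytes[hit_pos] <- rand_bases_raw(length(hit_pos))
  }
  stop("motif scrubbing did not converge after ", max_pass, " passes")
}

#' Generate a motif-free genome with gene models
#'
#' One random contig whose background contains zero occurrences of the
#' configured motifs on either strand (iterative rescan-and-redraw), with
#' genes placed on both strands at least `intergenic_min` bp apart. Gene
#' bodies are `gene_length` bp downstream of the TSS.
#'
#' @param n_genes number of genes (>= 1).
#' @param intergenic_min minimum TSS-to-TSS separation in bp; the default
#'   4200 keeps +/-2000 bp promoter windows of neighbouring genes disjoint.
#' @param motifs character vector of IUPAC motifs the background must avoid.
#' @param seed integer seed.
#' @param contig_length optional; defaults to a length that fits the genes,
#'   errors if too small for the packing.
#' @param gene_length gene body length in bp (default 500).
#' @param jitter maximal random shift of each TSS inside its slot (default
#'   400 bp).
#' @return list of class `synthetic_genome`: `genome` (DNAStringSet),
#'   `genes` (gene-model data.frame as in [read_gene_models()]), and `truth`
#'   (parameters, seed, per-gene planted-site records, initially empty).
#' @export
gen_genome_and_genes <- function(n_genes, intergenic_min = 4200L,
                                 motifs = c("GATAA", "GYGGGG"),
                                 seed = 1L, contig_length = NULL,
                                 gene_length = 500L, jitter = 400L) {
  stopifnot(n_genes >= 1, intergenic_min > 0)
  set.seed(derive_seed(seed, 1L))
  flank <- 2600L
  slot <- intergenic_min + jitter
  needed <- 2L * flank + n_genes * slot
  if (is.null(contig_length)) contig_length <- needed
  if (contig_length < needed) {
    stop("contig_length ", contig_length, " cannot pack ", n_genes,
         " genes (need >= ", needed, ")")
  }
  bytes <- rand_bases_raw(contig_length)
  bytes <- scrub_motifs(bytes, motifs)
  tss <- flank + (seq_len(n_genes) - 1L) * slot +
    sample.int(jitter + 1L, n_genes, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - gene_length + 1L)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    contig = "chrS1", strand = strand, tss = tss,
    start = start, end = start + gene_length,
    stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(rawToChar(bytes))
  names(genome) <- "chrS1"
  truth <- list(seed = seed, motifs = motifs, n_genes = n_genes,
                intergenic_min = intergenic_min, gene_length = gene_length,
                planted = list())
  structure(list(genome = genome, genes = genes, truth = truth),
            class = "synthetic_genome")
}

# Sample a concrete realization of an IUPAC motif.
realize_iupac <- function(iupac) {
  code <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(toupper(iupac), "")[[1]], function(l) {
    sample(strsplit(code[[l]], "")[[1]], 1)
  }, character(1)), collapse = "")
}

#' Plant motif occurrences in promoters at known offsets
#'
#' For each gene, draws a site count from `count_probs` (counts 0-3), places
#' that many non-overlapping occurrences at uniform gene-frame offsets in
#' `[offset_min, offset_max]` on a uniformly chosen genome strand, and
#' verifies by rescanning that the gene's +/- `max_distance` region contains
#' exactly the planted occurrences of every configured motif (redrawing on
#' collision). The updated truth records counts, offsets and strands.
#'
#' @param sim a `synthetic_genome`.
#' @param motif IUPAC motif to plant.
#' @param count_probs probabilities for counts 0,1,2,3 (default uniform).
#' @param offset_min,offset_max inclusive range of gene-frame offsets of the
#'   site's 5'-most base; the default plants fully upstream within 2 kb.
#' @param max_distance promoter extent used for the verification rescan.
#' @param seed integer seed.
#' @param max_retries redraw attempts per gene before failing.
#' @return the `synthetic_genome` with modified genome and extended truth.
#' @export
plant_motifs <- function(sim, motif, count_probs = rep(0.25, 4),
                         offset_min = -2000L, offset_max = NULL,
                         max_distance = 2000L, seed = 1L, max_retries = 50L) {
  stopifnot(inherits(sim, "synthetic_genome"))
  set.seed(derive_seed(seed, 2L))
  mlen <- nchar(motif)
  if (is.null(offset_max)) offset_max <- -mlen
  stopifnot(offset_min <= offset_max, offset_max <= max_distance)
  bytes <- charToRaw(as.character(sim$genome[[1]]))
  contig_len <- length(bytes)
  genes <- sim$genes
  counts <- sample(0:3, nrow(genes), replace = TRUE, prob = count_probs)
  planted <- vector("list", nrow(genes))

  all_motifs <- unique(c(sim$truth$motifs, motif))
  maxlen <- max(nchar(all_motifs))

  frame_to_genomic <- function(gene, o) {
    # genomic half-open interval of an occurrence at gene-frame offset o
    if (gene$strand == "+") c(gene$tss + o, gene$tss + o + mlen)
    else c(gene$tss - o - mlen + 1L, gene$tss - o + 1L)
  }

  # gene-frame offsets (5'-most base) of occurrences of motif m, both genome
  # strands, within a region slice [reg_lo, reg_hi) (0-based genomic)
  region_offsets <- function(region_bytes, reg_lo, gene, m) {
    s <- Biostrings::DNAString(rawToChar(region_bytes))
    pat <- Biostrings::DNAString(m)
    offs <- integer(0)
    for (p in list(pat, Biostrings::reverseComplement(pat))) {
      mt <- Biostrings::matchPattern(p, s, fixed = FALSE)
      if (length(mt) > 0) {
        g0 <- reg_lo + BiocGenerics::start(mt) - 1L
        g1 <- g0 + nchar(m)
        o <- if (gene$strand == "+") g0 - gene$tss else gene$tss - (g1 - 1L)
        offs <- c(offs, o)
      }
    }
    sort(offs[offs >= -max_distance & offs < max_distance])
  }

  prior_offsets <- function(gid, m) {
    rec <- sim$truth$planted[[m]]
    if (is.null(rec)) return(integer(0))
    sort(as.integer(rec$offsets[[gid]]))
  }

  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    reg_lo <- max(0L, gene$tss - (max_distance + maxlen + 2L))
    reg_hi <- min(contig_len, gene$tss + max_distance + maxlen + 2L)
    region0 <- bytes[(reg_lo + 1L):reg_hi]
    k <- counts[g]
    ok <- FALSE
    for (attempt in seq_len(max_retries)) {
      region <- region0
      offs <- integer(0)
      if (k > 0) {
        # rejection-sample non-overlapping offsets
        tries <- 0
        while (length(offs) < k && tries < 200) {
          o <- sample(offset_min:offset_max, 1L)
          if (all(abs(o - offs) >= mlen)) offs <- c(offs, o)
          tries <- tries + 1
        }
        if (length(offs) < k) next
        offs <- sort(offs)
        fail <- FALSE
        for (o in offs) {
          site <- realize_iupac(motif)
          strand <- sample(c("+", "-"), 1L)
          gi <- frame_to_genomic(gene, o)
          if (gi[1] < reg_lo || gi[2] > reg_hi) { fail <- TRUE; break }
          s <- if (strand == "+") site else {
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
          }
          region[(gi[1] - reg_lo + 1L):(gi[2] - reg_lo)] <- charToRaw(s)
        }
        if (fail) next
      }
      verified <- TRUE
      for (m in all_motifs) {
        expect <- if (m == motif) offs else integer(0)
        expect <- sort(c(expect, prior_offsets(gene$gene_id, m)))
        got <- region_offsets(region, reg_lo, gene, m)
        if (!identical(got, as.integer(expect))) { verified <- FALSE; break }
      }
      if (verified) {
        bytes[(reg_lo + 1L):reg_hi] <- region
        planted[[g]] <- offs
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not plant ", k, " sites for gene ", gene$gene_id,
                  " after ", max_retries, " attempts")
  }
  genome <- Biostrings::DNAStringSet(rawToChar(bytes))
  names(genome) <- names(sim$genome)
  sim$genome <- genome
  sim$truth$motifs <- all_motifs
  sim$truth$planted[[motif]] <- list(
    counts = stats::setNames(counts, genes$gene_id),
    offsets = stats::setNames(planted, genes$gene_id))
  sim
}

#' Generate an FPKM expression table with a motif-dependent mutant effect
#'
#' Baseline per-gene log2 FPKM is Normal(mu0, s0). Wild-type samples add
#' Normal(0, sigma) replicate noise; mutant samples are additionally shifted
#' by `sum over motifs of beta_motif * min(planted count, 2)`. FPKM is 2 to
#' the simulated log2 value.
#'
#' @param sim a `synthetic_genome` with planted motifs.
#' @param beta named numeric: effect per capped site count (lfc units) for
#'   each planted motif.
#' @param sigma replicate noise SD in lfc units (default 0.5).
#' @param replicates per-strain replicate count (default 4).
#' @param strains two strain labels, denominator first (default WT, mutant).
#' @param condition condition label for all samples.
#' @param mu0,s0 baseline log2-FPKM mean and SD.
#' @param seed integer seed.
#' @return list: `expr` (an `expression_matrix`) and `effect` (named vector
#'   of each gene's true expected mutant-vs-WT lfc).
#' @export
gen_expression <- function(sim, beta, sigma = 0.5, replicates = 4L,
                           strains = c("WT", "mutant"),
                           condition = "ammonium", mu0 = 5, s0 = 2,
                           seed = 1L) {
  stopifnot(inherits(sim, "synthetic_genome"), sigma >= 0, replicates >= 1)
  missing_m <- setdiff(names(beta), names(sim$truth$planted))
  if (length(missing_m) > 0) {
    stop("beta names not among planted motifs: ",
         paste(missing_m, collapse = ", "))
  }
  set.seed(derive_seed(seed, 3L))
  genes <- sim$genes$gene_id
  ng <- length(genes)
  effect <- rep(0, ng)
  for (m in names(beta)) {
    capped <- pmin(sim$truth$planted[[m]]$counts[genes], 2L)
    effect <- effect + beta[[m]] * capped
  }
  baseline <- stats::rnorm(ng, mu0, s0)
  samples <- expand.grid(replicate = seq_len(replicates), strain = strains,
                         stringsAsFactors = FALSE)
  samples$condition <- condition
  samples$sample <- paste(samples$strain, samples$condition,
                          samples$replicate, sep = "_")
  fpkm <- sapply(seq_len(nrow(samples)), function(j) {
    shift <- if (samples$strain[j] == strains[2]) effect else 0
    2^(baseline + shift + stats::rnorm(ng, 0, sigma))
  })
  dimnames(fpkm) <- list(genes, samples$sample)
  expr <- expression_matrix(fpkm, samples[, c("sample", "strain",
                                              "condition", "replicate")])
  list(expr = expr, effect = stats::setNames(effect, genes))
}

# Residues allowed at "any" filler positions: the 19 standard residues
# excluding Cys, so planted proteins carry exactly the cysteines we place.
rand_res <- function(n) {
  cys_free <- setdiff(AA_ALPHABET, c("C", "X"))
  paste(sample(cys_free, n, replace = TRUE), collapse = "")
}

# Construct one domain string. strict = TRUE builds the conserved-residue
# retention pattern (spacing 17); otherwise a plain C-X2-C-Xn-C-X2-C.
# type: "domain", "no_T" (strict layout with T -> G), or custom spacing.
make_domain <- function(spacing, strict = FALSE, no_T = FALSE) {
  if (strict || no_T) {
    core <- paste0("C", rand_res(2), "C", rand_res(4),
                   if (no_T) "G" else "T",
                   sample(c("P", "S"), 1), sample(c("L", "V"), 1),
                   "WR", sample(c("R", "K"), 1), rand_res(7), "CN",
                   rand_res(1), "C")
    return(core)
  }
  paste0("C", rand_res(2), "C", rand_res(spacing), "C", rand_res(2), "C")
}

#' Generate a proteome with planted zinc-finger domains and decoys
#'
#' Backgrounds are cysteine-free random sequences, so a protein's only
#' possible spaced-cysteine hits are the planted ones. Planted specs give a
#' spacing (17-20) and whether the domain follows the strict retention
#' pattern. Decoy types are near-misses: `"spacing_16"` / `"spacing_21"`
#' (wrong spacing, no generic hit), `"no_T"` (strict layout with the
#' conserved Thr mutated, generic hit but strict fail), and `"short_tail"`
#' (strict layout with fewer than 25 trailing residues, generic hit but
#' strict fail).
#'
#' @param n_proteins total proteins; those beyond the planted/decoy specs are
#'   background-only.
#' @param planted data.frame with columns `spacing` (17-20) and `strict`
#'   (logical), one row per planted-domain protein.
#' @param decoys character vector of decoy types.
#' @param seed integer seed.
#' @param min_len,max_len background length range.
#' @return list: `proteins` (list of `protein_record`) and `truth`
#'   (data.frame: protein_id, type, start, spacing, expect_generic,
#'   expect_strict).
#' @export
gen_proteome <- function(n_proteins,
                         planted = data.frame(spacing = c(17L, 18L, 19L, 20L),
                                              strict = c(TRUE, FALSE, FALSE, FALSE)),
                         decoys = c("spacing_16", "spacing_21", "no_T",
                                    "short_tail"),
                         seed = 1L, min_len = 150L, max_len = 400L) {
  n_special <- nrow(planted) + length(decoys)
  stopifnot(n_proteins >= n_special,
            all(planted$spacing %in% VALID_SPACINGS))
  set.seed(derive_seed(seed, 4L))
  proteins <- vector("list", n_proteins)
  truth <- list()
  for (i in seq_len(n_proteins)) {
    id <- sprintf("prot%03d", i)
    L <- sample(min_len:max_len, 1L)
    if (i <= nrow(planted)) {
      sp <- planted$spacing[i]; strict <- planted$strict[i]
      repeat {
        dom <- make_domain(sp, strict = strict)
        # a non-strict X17 domain must not match the strict pattern by chance
        if (strict || sp != 17L) break
        if (!grepl("^C..C....T[PS][LV]WR[RK].{7}CN.C$", dom)) break
      }
      dlen <- nchar(dom)
      start <- sample(0:(L - dlen - 30L), 1L)   # leaves a >= 25 tail
      seq <- paste0(rand_res(start), dom, rand_res(L - start - dlen))
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, type = if (strict) "strict" else "generic",
        start = start, spacing = sp,
        expect_generic = TRUE, expect_strict = strict,
        stringsAsFactors = FALSE)
    } else if (i <= n_special) {
      type <- decoys[i - nrow(planted)]
      if (type %in% c("spacing_16", "spacing_21")) {
        sp <- if (type == "spacing_16") 16L else 21L
        dom <- make_domain(sp)
        dlen <- nchar(dom)
        start <- sample(0:(L - dlen - 30L), 1L)
        seq <- paste0(rand_res(start), dom, rand_res(L - start - dlen))
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, type = type, start = start, spacing = sp,
          expect_generic = FALSE, expect_strict = FALSE,
          stringsAsFactors = FALSE)
      } else if (type == "no_T") {
        dom <- make_domain(17L, no_T = TRUE)
        dlen <- nchar(dom)
        start <- sample(0:(L - dlen - 30L), 1L)
        seq <- paste0(rand_res(start), dom, rand_res(L - start - dlen))
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, type = type, start = start, spacing = 17L,
          expect_generic = TRUE, expect_strict = FALSE,
          stringsAsFactors = FALSE)
      } else {                                   # short_tail
        dom <- make_domain(17L, strict = TRUE)
        dlen <- nchar(dom)
        tail_len <- sample(0:24, 1L)
        start <- L - dlen - tail_len
        seq <- paste0(rand_res(start), dom, rand_res(tail_len))
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, type = type, start = start, spacing = 17L,
          expect_generic = TRUE, expect_strict = FALSE,
          stringsAsFactors = FALSE)
      }
    } else {
      seq <- rand_res(L)
    }
    proteins[[i]] <- protein_record(id, seq, species = "synthetic")
  }
  list(proteins = proteins, truth = do.call(rbind, truth))
}

#' Full synthetic regulon preset
#'
#' The standard study-shaped fixture: a motif-free genome with `n_genes`
#' genes, GATAA planted at counts 0-3 (uniform) with a linear expression
#' effect of `beta_gataa` lfc units per capped count, GYGGGG planted at the
#' same count distribution with no expression effect, and an FPKM table with
#' `replicates` wild-type and mutant replicates at noise `sigma`.
#'
#' @param seed master seed.
#' @param n_genes number of genes (default 2000).
#' @param beta_gataa GATAA effect size in lfc units per capped count
#'   (default 0.5).
#' @param sigma replicate noise SD (default 0.5).
#' @param replicates replicates per strain (default 4).
#' @param plant_gyggggg also plant the carbon response element as a
#'   no-effect control motif (default TRUE).
#' @return list with `sim` (synthetic_genome incl. truth), `expr`,
#'   `effect` (true per-gene lfc), and the generation parameters.
#' @export
simulate_regulon <- function(seed = 1L, n_genes = 2000L, beta_gataa = 0.5,
                             sigma = 0.5, replicates = 4L,
                             plant_gyggggg = TRUE) {
  sim <- gen_genome_and_genes(n_genes, seed = seed)
  sim <- plant_motifs(sim, "GATAA", seed = derive_seed(seed, 11L))
  beta <- c(GATAA = beta_gataa)
  if (plant_gyggggg) {
    sim <- plant_motifs(sim, "GYGGGG", seed = derive_seed(seed, 12L))
    beta <- c(beta, GYGGGG = 0)
  }
  ge <- gen_expression(sim, beta = beta, sigma = sigma,
                       replicates = replicates,
                       seed = derive_seed(seed, 13L))
  list(sim = sim, expr = ge$expr, effect = ge$effect,
       params = list(seed = seed, n_genes = n_genes, beta = beta,
                     sigma = sigma, replicates = replicates))
}

#' Write a synthetic fixture to disk
#'
#' Writes genome FASTA, gene models GFF3, expression + sample-metadata TSVs,
#' and the ground truth as JSON.
#'
#' @param fixture output of [simulate_regulon()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             genes = file.path(dir, "genes.gff3"),
             expr = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(fixture$sim$genome, paths[["genome"]])
  g <- fixture$sim$genes
  gff <- data.frame(seqid = g$contig, source = "gzftools", type = "gene",
                    start = g$start + 1L, end = g$end, score = ".",
                    strand = g$strand, phase = ".",
                    attributes = paste0("ID=", g$gene_id))
  writeLines(c("##gff-version 3",
               do.call(paste, c(gff, sep = "\t"))), paths[["genes"]])
  expr <- fixture$expr
  write_tsv(data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
                       check.names = FALSE), paths[["expr"]])
  write_tsv(expr$samples, paths[["meta"]])
  truth <- fixture$sim$truth
  truth$effect <- as.list(fixture$effect)
  truth$params <- fixture$params
  truth$params$beta <- as.list(fixture$params$beta)  # keep names in JSON
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
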