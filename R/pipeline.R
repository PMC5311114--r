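# End-to-end orchestration: domain scan -> family tree -> promoter scan ->
# fold change -> motif binning / shift tests / enrichment, with a validated
# configuration and a machine-readable run manifest.

PIPELINE_CONFIG_KEYS <- c(
  "proteins", "species_map", "genome", "genes", "expression", "samples",
  "gene_sets", "anchors", "out_dir", "motifs", "max_distance", "step",
  "pseudocount", "count_mode", "exact_max", "aggregate", "spacings",
  "strict", "numerator", "denominator", "top_n", "seed")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a JSON file of one). Unknown keys are
#' rejected; input paths must exist; defaults are filled for the analysis
#' parameters (motifs GATAA + GYGGGG, 2 kb window grid at 200 bp, pseudocount
#' 0.1, combined-strand counting, top-N 500).
#'
#' @param config named list or path to a JSON config file.
#' @return the resolved configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(motifs = c("GATAA", "GYGGGG"), max_distance = 2000L,
                   step = 200L, pseudocount = 0.1, count_mode = "combined",
                   exact_max = 20L, aggregate = "mean_fpkm",
                   spacings = c(17L, 18L, 19L, 20L), strict = FALSE,
                   top_n = 500L, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  for (k in c("proteins", "genome", "genes", "expression", "samples",
              "gene_sets", "species_map", "anchors")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("config path for '", k, "' does not exist: ", config[[k]])
    }
  }
  if (!is.null(config$expression) &&
      (is.null(config$numerator) || is.null(config$denominator))) {
    stop("expression analysis requires numerator and denominator groups")
  }
  config
}

# Run one stage. On error the manifest (with the failure recorded) is
# written next to the partial outputs together with a FAILED marker file,
# and the pipeline aborts with a stage-labelled message.
run_stage <- function(manifest, out_dir, name, fun) {
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages[[name]] <- list(status = "FAILED",
                                    message = conditionMessage(res))
    manifest$failed <- name
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    file.create(file.path(out_dir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
  }
  manifest$stages[[name]] <- list(
    status = "completed",
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes, for whichever inputs the configuration provides: domain scan,
#' family-tree construction, promoter motif scan, fold-change computation,
#' motif-count binning, gene-set shift tests and top-N enrichment, writing
#' each stage's TSV/FASTA/Newick/BED artifacts plus a run manifest
#' (`manifest.json`) and the resolved configuration (`config.json`) to the
#' output directory. Outputs are deterministic for identical config+inputs.
#'
#' @param config configuration list or JSON path, see [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "gzftools",
                   version = as.character(utils::packageVersion("gzftools")),
                   seed = cfg$seed, stages = list(), failed = FALSE)
  env <- new.env()

  if (!is.null(cfg$proteins)) {
    manifest <- run_stage(manifest, cfg$out_dir, "scan-domains", function() {
      prot <- read_proteins(cfg$proteins, species_map = cfg$species_map)
      sp <- NULL
      if (!is.null(cfg$species_map)) {
        sp <- vapply(prot, function(p) p$species, character(1))
        names(sp) <- vapply(prot, function(p) p$id, character(1))
      }
      env$hits <- scan_proteome(prot, spacings = cfg$spacings,
                                strict = cfg$strict, species_of = sp,
                                out_prefix = file.path(cfg$out_dir, "domains"))
      message("scan-domains: ", length(prot), " proteins, ",
              nrow(env$hits), " hits")
      invisible(NULL)
    })
    if (!is.null(env$hits) && nrow(env$hits) >= 3) {
      manifest <- run_stage(manifest, cfg$out_dir, "build-tree", function() {
        seqs <- stats::setNames(env$hits$domain_seq, env$hits$protein_id)
        anchors <- NULL
        if (!is.null(cfg$anchors)) {
          a <- read.table(cfg$anchors, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
          anchors <- stats::setNames(a[[2]], a[[1]])
        }
        env$tree <- build_domain_tree(seqs, anchors = anchors,
                                      out_prefix = file.path(cfg$out_dir, "tree"))
        invisible(NULL)
      })
    }
  }

  if (!is.null(cfg$genome) && !is.null(cfg$genes)) {
    manifest <- run_stage(manifest, cfg$out_dir, "scan-promoters", function() {
      genome <- read_genome(cfg$genome)
      genes <- read_gene_models(cfg$genes)
      env$counts <- lapply(cfg$motifs, function(m) {
        count_matrix(genome, genes, m, max_distance = cfg$max_distance,
                     step = cfg$step)
      })
      names(env$counts) <- cfg$motifs
      for (m in cfg$motifs) {
        write_count_matrix(env$counts[[m]],
                           file.path(cfg$out_dir, paste0("counts_", m, ".tsv")))
        occ <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
          rbind(scan_window(genome, genes[g, ], c(-cfg$max_distance, 0L), m),
                scan_window(genome, genes[g, ], c(0L, cfg$max_distance), m))
        }))
        export_sites(occ, file.path(cfg$out_dir, paste0("sites_", m, ".bed")))
      }
      message("scan-promoters: ", nrow(genes), " genes x ",
              length(cfg$motifs), " motifs")
      invisible(NULL)
    })
  }

  if (!is.null(cfg$expression)) {
    manifest <- run_stage(manifest, cfg$out_dir, "fold-change", function() {
      env$expr <- read_expression(cfg$expression, cfg$samples)
      env$lfc <- log2_fold_change(env$expr,
                                  numerator = as.list(cfg$numerator),
                                  denominator = as.list(cfg$denominator),
                                  pseudocount = cfg$pseudocount,
                                  aggregate = cfg$aggregate)
      write_tsv(data.frame(gene_id = names(env$lfc), lfc = unname(env$lfc)),
                file.path(cfg$out_dir, "fold_change.tsv"),
                comment = "log2 fold change (numerator / denominator)")
      invisible(NULL)
    })
    if (!is.null(env$counts)) {
      manifest <- run_stage(manifest, cfg$out_dir, "bin-motifs", function() {
        summary <- motif_promoter_summary(env$lfc, env$counts)
        write_tsv(summary, file.path(cfg$out_dir, "motif_bins.tsv"),
                  comment = "mean lfc by motif-count category per TSS window")
        invisible(NULL)
      })
    }
    if (!is.null(cfg$gene_sets)) {
      manifest <- run_stage(manifest, cfg$out_dir, "shift-test", function() {
        universe <- names(env$lfc)[rowMeans(env$expr$fpkm) > 0]
        sets <- read_gene_sets(cfg$gene_sets, universe)
        rows <- lapply(names(sets$sets), function(nm) {
          st <- gene_set_shift_test(env$lfc, sets$sets[[nm]],
                                    background = universe,
                                    exact_max = cfg$exact_max)
          data.frame(set = nm, U = st$U, p = st$p, direction = st$direction,
                     n_set = st$n_set, stringsAsFactors = FALSE)
        })
        write_tsv(do.call(rbind, rows),
                  file.path(cfg$out_dir, "shift_tests.tsv"),
                  comment = "rank-sum fold-change shift per gene set")
        env$sets <- sets
        invisible(NULL)
      })
      manifest <- run_stage(manifest, cfg$out_dir, "enrich", function() {
        up <- top_n_genes(env$lfc[names(env$lfc) %in% env$sets$universe],
                          n = cfg$top_n, direction = "up")
        res <- enrich(up, env$sets)
        write_tsv(res, file.path(cfg$out_dir, "enrichment.tsv"),
                  comment = paste0("hypergeometric enrichment of top-",
                                   cfg$top_n,
                                   " upregulated genes, Bonferroni-corrected"))
        invisible(NULL)
      })
    }
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
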