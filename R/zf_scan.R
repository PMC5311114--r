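# Spaced-cysteine (GATA-type zinc finger) domain detection.
#
# The DNA-interaction domain of GATA-family zinc fingers has four cysteines
# arranged Cys-X2-Cys-Xn-Cys-X2-Cys, with n = 17 in canonical GATA factors
# and n = 18-20 in the WC-2-like and Ash1-like variants. All coordinates in
# hit tables are 0-based, end-exclusive (BED convention).

VALID_SPACINGS <- c(17L, 18L, 19L, 20L)

#' Classify a spaced-cysteine domain by its inter-motif spacing
#'
#' Maps the residue count between the second and third cysteine to a family
#' class: 17 is the canonical GATA spacing, 18 the WC-2-like (light-responsive)
#' spacing, and 19 or 20 the Ash1-like spacing.
#'
#' @param spacing_n integer in 17:20.
#' @return one of `"canonical_17"`, `"wc2_like_18"`, `"ash1_like_19_20"`.
#' @export
classify_spacing <- function(spacing_n) {
  if (length(spacing_n) != 1L || !is.numeric(spacing_n) ||
      spacing_n != as.integer(spacing_n) || !(spacing_n %in% VALID_SPACINGS)) {
    stop("spacing_n must be one of 17, 18, 19, 20; got ",
         paste(spacing_n, collapse = ","))
  }
  switch(as.character(as.integer(spacing_n)),
         "17" = "canonical_17",
         "18" = "wc2_like_18",
         "19" = ,
         "20" = "ash1_like_19_20")
}

# Internal: build one hit row (0-based, end-exclusive coordinates).
zf_hit_row <- function(protein_id, start0, spacing_n, seq_chars, strict) {
  len <- spacing_n + 8L
  domain_seq <- paste(seq_chars[(start0 + 1L):(start0 + len)], collapse = "")
  data.frame(protein_id = protein_id,
             start = start0,
             end = start0 + len,
             spacing_n = spacing_n,
             family_class = classify_spacing(spacing_n),
             strict_pass = strict,
             tail_ok = (length(seq_chars) - (start0 + len)) >= 25L,
             domain_seq = domain_seq,
             stringsAsFactors = FALSE)
}

#' Scan a protein for spaced-cysteine zinc-finger domains
#'
#' Reports every position where the pattern C-X2-C-Xn-C-X2-C occurs, for each
#' requested spacing n. Overlapping hits (including multiple spacings sharing a
#' start) are all reported; selecting a single domain per protein is the
#' separate [best_domain()] step. The ambiguity code `X` in the input matches
#' "any residue" positions but never a required cysteine.
#'
#' @param protein a `protein_record` (see [protein_record()]).
#' @param spacings integer subset of 17:20 (default all four).
#' @return data.frame of hits with columns protein_id, start, end (0-based,
#'   end-exclusive), spacing_n, family_class, strict_pass, tail_ok,
#'   domain_seq; sorted by (start, spacing_n).
#' @export
scan_zinc_fingers <- function(protein, spacings = VALID_SPACINGS) {
  stopifnot(inherits(protein, "protein_record"))
  if (length(spacings) == 0) stop("spacings must be a non-empty set")
  spacings <- as.integer(spacings)
  if (!all(spacings %in% VALID_SPACINGS)) {
    stop("spacings must be a subset of {17, 18, 19, 20}")
  }
  chars <- strsplit(protein$sequence, "")[[1]]
  L <- length(chars)
  cys <- which(chars == "C")          # 1-based positions
  is_cys <- logical(L)
  is_cys[cys] <- TRUE
  rows <- list()
  for (p in cys) {                    # p: 1-based first-Cys position
    if (p + 3L > L || !is_cys[p + 3L]) next
    for (n in sort(spacings)) {
      last <- p + n + 7L              # 1-based fourth-Cys position
      if (last > L) next
      if (is_cys[p + n + 4L] && is_cys[last]) {
        start0 <- p - 1L
        rows[[length(rows) + 1L]] <-
          zf_hit_row(protein$id, start0, n,
                     chars, matches_strict_retention(protein, start0))
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  out[order(out$start, out$spacing_n), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             spacing_n = integer(), family_class = character(),
             strict_pass = logical(), tail_ok = logical(),
             domain_seq = character(), stringsAsFactors = FALSE)
}

#' Test the strict retention pattern at a position
#'
#' The strict filter used to retain genuine GATA domains requires, reading
#' from `start`:
#' C, 2 any, C, 4 any, T, (P|S), (L|V), W, R, (R|K), 7 any, C, N, 1 any, C,
#' followed by at least 25 further residues before the end of the protein.
#' The implied spacing between the second and third cysteine is 17, so every
#' strict match is also a canonical X17 hit. `X` never satisfies a required
#' (non-"any") position.
#'
#' @param protein a `protein_record`.
#' @param start 0-based offset of the candidate first cysteine.
#' @return logical scalar.
#' @export
matches_strict_retention <- function(protein, start) {
  stopifnot(inherits(protein, "protein_record"))
  L <- nchar(protein$sequence)
  if (length(start) != 1L || !is.numeric(start) || start < 0 || start >= L) {
    stop("start out of range: ", start)
  }
  # core pattern is 25 residues; tail of >= 25 more must fit
  if (start + 25L + 25L > L) return(FALSE)
  s <- substr(protein$sequence, start + 1L, start + 25L)
  grepl("^C..C....T[PS][LV]WR[RK].{7}CN.C$", s)
}

# Canonical consensus used as the default anchor for best_domain: the
# constructed exact-length X17 pattern with alanine at "any" positions.
canonical_consensus <- function() {
  paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C")
}

#' Select the best-aligning domain among multiple hits in one protein
#'
#' When a protein carries several DNA-interaction domains, only the domain
#' whose sequence attains the maximum global-alignment score against a
#' consensus is retained. Ties break to the smallest start.
#'
#' @param protein a `protein_record`.
#' @param hits data.frame of hits from [scan_zinc_fingers()], all belonging to
#'   this protein.
#' @param consensus amino-acid string to score against; defaults to the
#'   constructed canonical C-X2-C-X17-C-X2-C pattern.
#' @param params alignment scoring parameters, see [global_align()].
#' @return the single best hit row.
#' @export
best_domain <- function(protein, hits, consensus = canonical_consensus(),
                        params = align_params()) {
  stopifnot(inherits(protein, "protein_record"))
  if (is.null(hits) || nrow(hits) == 0) stop("hits must be non-empty")
  if (!all(hits$protein_id == protein$id)) {
    stop("all hits must belong to protein ", protein$id)
  }
  scores <- vapply(hits$domain_seq, function(s) {
    global_align(s, consensus, params = params)$score
  }, numeric(1))
  ord <- order(-scores, hits$start)
  hits[ord[1L], , drop = FALSE]
}

#' Remove duplicate domain sequences within species
#'
#' Within each species, hits whose domain sequences are byte-identical
#' collapse to a single representative (lexicographically smallest
#' protein_id, then smallest start). Identical domains in different species
#' are all retained. Output is ordered by (species, protein_id, start).
#'
#' @param hits data.frame of hits.
#' @param species_of named character vector mapping protein_id to species.
#' @return deduplicated data.frame of hits.
#' @export
dedup_within_species <- function(hits, species_of) {
  if (nrow(hits) == 0) return(hits)
  missing <- setdiff(unique(hits$protein_id), names(species_of))
  if (length(missing) > 0) {
    stop("no species mapping for protein(s): ", paste(missing, collapse = ", "))
  }
  sp <- unname(species_of[hits$protein_id])
  key <- paste(sp, hits$domain_seq, sep = "\r")
  ord <- order(key, hits$protein_id, hits$start)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- h[keep, , drop = FALSE]
  out_sp <- sp[ord][keep]
  out <- out[order(out_sp, out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole proteome and write hit tables
#'
#' Convenience wrapper: scans every protein, optionally applies the strict
#' retention filter, best-domain selection and within-species deduplication,
#' and (optionally) writes a hits TSV plus a FASTA of domain sequences.
#'
#' @param proteins list of `protein_record` from [read_proteins()].
#' @param spacings spacings to scan for.
#' @param strict if TRUE, keep only hits passing the strict retention pattern.
#' @param best_only if TRUE, keep only the best-aligning domain per protein.
#' @param species_of optional named vector for deduplication; when supplied,
#'   within-species duplicate domains are removed.
#' @param out_prefix optional path prefix; writes `<prefix>.hits.tsv` and
#'   `<prefix>.domains.fasta`.
#' @return data.frame of hits.
#' @export
scan_proteome <- function(proteins, spacings = VALID_SPACINGS, strict = FALSE,
                          best_only = TRUE, species_of = NULL,
                          out_prefix = NULL) {
  per_protein <- lapply(proteins, function(p) {
    h <- scan_zinc_fingers(p, spacings = spacings)
    if (strict) h <- h[h$strict_pass, , drop = FALSE]
    if (best_only && nrow(h) > 1) h <- best_domain(p, h)
    h
  })
  hits <- do.call(rbind, c(per_protein, list(empty_hits())))
  rownames(hits) <- NULL
  if (!is.null(species_of) && nrow(hits) > 0) {
    hits <- dedup_within_species(hits, species_of)
  }
  if (!is.null(out_prefix)) {
    write_tsv(hits, paste0(out_prefix, ".hits.tsv"),
              comment = "zinc-finger domain hits; 0-based end-exclusive coordinates")
    if (nrow(hits) > 0) {
      dom <- Biostrings::AAStringSet(hits$domain_seq)
      names(dom) <- paste0(hits$protein_id, "/", hits$start, "-", hits$end)
      Biostrings::writeXStringSet(dom, paste0(out_prefix, ".domains.fasta"))
    } else {
      file.create(paste0(out_prefix, ".domains.fasta"))
    }
  }
  hits
}
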