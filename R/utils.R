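#' @importFrom utils write.table read.table head
NULL

# Amino-acid alphabet accepted in protein records: the 20 standard residues
# plus the ambiguity code X.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Derive a child seed from a master seed
#'
#' Deterministically fans a single master seed out to per-component seeds so
#' that independent generators (genome, motif planting, expression, proteome)
#' do not share random streams. The derivation is
#' `(seed * 48271 + index) mod (2^31 - 1)`, a Lehmer-style step kept inside
#' the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer master seed.
#' @param index non-negative integer component index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + index) %% m)
}

# Shared writer for tab-separated outputs: single '#'-prefixed comment line
# naming the columns, then plain TSV without quoting.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Validate and construct a protein record
#'
#' @param id protein identifier.
#' @param sequence amino-acid sequence (20-letter alphabet plus `X`).
#' @param species optional species label (may be empty).
#' @return a list with class `protein_record`.
#' @export
protein_record <- function(id, sequence, species = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("protein sequence must be non-empty: ", id)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("protein ", id, " contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, species = species,
                 sequence = paste(chars, collapse = "")),
            class = "protein_record")
}

#' Read a protein FASTA into a list of protein records
#'
#' @param path multi-FASTA file of amino-acid sequences.
#' @param species_map optional named character vector or two-column TSV path
#'   (protein_id, species) assigning species labels.
#' @return list of `protein_record`.
#' @export
read_proteins <- function(path, species_map = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map)) {
    sm <- read.table(species_map, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    species_map <- stats::setNames(sm[[2]], sm[[1]])
  }
  lapply(seq_along(aa), function(i) {
    sp <- if (!is.null(species_map) && ids[i] %in% names(species_map)) {
      unname(species_map[[ids[i]]])
    } else ""
    protein_record(ids[i], as.character(aa[[i]]), species = sp)
  })
}
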