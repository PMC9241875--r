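#' FASTA input and output
#'
#' Thin wrappers around Biostrings for the sequence sets the pipeline
#' exchanges: genomes and 16S markers (DNA) and per-genome protein sets.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return readers return a named character vector; writers return `path`
#'   invisibly.
#' @export
write_dna_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname write_dna_fasta
#' @export
write_protein_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path)
  invisible(path)
}

#' @rdname write_dna_fasta
#' @export
read_dna_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Read protein records for clustering
#'
#' Accepts either one FASTA per genome (named by the `genome_ids` vector)
#' or a single combined FASTA whose record ids are `genome|gene`.
#'
#' @param paths FASTA file path(s).
#' @param genome_ids genome labels, one per path; defaults to file base
#'   names.  Ignored for a single combined `genome|gene` FASTA.
#' @return `data.frame` with `genome_id`, `gene_id`, `residues` — the
#'   [greedy_cluster()] input.
#' @export
read_protein_fasta <- function(paths, genome_ids = NULL) {
  recs <- list()
  for (i in seq_along(paths)) {
    s <- Biostrings::readAAStringSet(paths[i])
    ids <- sub("\\s.*$", "", names(s))
    if (all(grepl("|", ids, fixed = TRUE)) && length(paths) == 1) {
      parts <- strsplit(ids, "|", fixed = TRUE)
      recs[[i]] <- data.frame(
        genome_id = vapply(parts, `[`, "", 1),
        gene_id = vapply(parts, `[`, "", 2),
        residues = as.character(s))
    } else {
      gid <- (genome_ids %||% sub("\\.[^.]*$", "", basename(paths)))[i]
      recs[[i]] <- data.frame(genome_id = gid, gene_id = ids,
                              residues = as.character(s))
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' GFF3 input and output for gene features
#'
#' Reads and writes the 1-based inclusive gene coordinates used by the
#' neighborhood module.  Gene names are taken from the `gene` attribute,
#' falling back to `Name`, then to the feature `ID`.
#'
#' @param path GFF3 file.
#' @param features feature `data.frame` (`gene_id`, `name`, `contig`,
#'   `start`, `end`, `strand`).
#' @return `read_features_gff3` returns a feature `data.frame`;
#'   `write_features_gff3` returns `path` invisibly.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  name <- df$gene %||% rep(NA_character_, nrow(df))
  if ("Name" %in% names(df)) name <- ifelse(is.na(name), df$Name, name)
  if ("ID" %in% names(df)) name <- ifelse(is.na(name), df$ID, name)
  out <- data.frame(
    gene_id = df$ID %||% sprintf("gene%03d", seq_len(nrow(df))),
    name = name,
    contig = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand))
  as_features(out)
}

#' @rdname read_features_gff3
#' @export
write_features_gff3 <- function(features, path) {
  features <- as_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = "gene",
    ID = features$gene_id,
    gene = features$name)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a list-like result as JSON
#'
#' Used for truth records, mutation logs, partition and fit results.
#'
#' @param x a list or S3 object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
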