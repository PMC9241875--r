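VALID_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

check_protein <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0) {
    stop("empty ", arg)
  }
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, VALID_RESIDUES)
  if (length(bad) > 0) {
    stop("non-residue character in ", arg, ": '", bad[1], "'")
  }
  toupper(x)
}

#' Global protein identity
#'
#' Fraction of identical residue pairs over all alignment columns (gap
#' columns included) of a Needleman-Wunsch global alignment under the
#' configured scoring (default BLOSUM62, gap open 10, gap extend 1).
#' Symmetric in its arguments.  The denominator can be switched to the
#' shorter sequence's length for sensitivity checks.
#'
#' @param a,b amino-acid strings (20 standard residues plus X).
#' @param scoring substitution matrix name, e.g. `"BLOSUM62"`.
#' @param gap_open,gap_extend positive gap penalties.
#' @param denominator `"columns"` (alignment length, default) or
#'   `"shorter"` (length of the shorter sequence).
#' @return identity as a fraction in `[0, 1]`.
#' @examples
#' global_identity("MKVL", "MKVI")   # 0.75
#' @export
global_identity <- function(a, b, scoring = "BLOSUM62",
                            gap_open = 10, gap_extend = 1,
                            denominator = c("columns", "shorter")) {
  a <- check_protein(a, "first sequence")
  b <- check_protein(b, "second sequence")
  denominator <- match.arg(denominator)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = scoring,
    gapOpening = gap_open, gapExtension = gap_extend)
  n_match <- Biostrings::nmatch(aln)
  denom <- switch(denominator,
                  columns = nchar(as.character(Biostrings::alignedPattern(aln))),
                  shorter = min(nchar(a), nchar(b)))
  n_match / denom
}

# k-mer set of a protein, used only as a conservative prefilter
protein_kmers <- function(x, k = 5L) {
  n <- nchar(x) - k + 1L
  if (n < 1L) return(character(0))
  unique(substring(x, seq_len(n), seq_len(n) + k - 1L))
}

#' Greedy centroid clustering of proteins into gene families
#'
#' USEARCH-style greedy clustering at a fixed global-identity threshold:
#' sequences are processed in decreasing length order (ties broken by
#' `genome|gene` label, ascending — deliberately removing any input-order
#' dependence), each joining the earliest-founded centroid whose
#' [global_identity()] reaches the threshold, otherwise founding a new family
#' with itself as centroid.  A shared-5-mer prefilter skips hopeless centroid
#' comparisons; it only fires when both sequences are at least
#' `prefilter_min_len` residues long — the regime where any pair that could
#' actually reach the identity threshold shares conserved 5-mers with
#' overwhelming probability — and short sequences are always compared
#' directly, so filtered and unfiltered runs coincide.  It can also be
#' turned off entirely for reference runs, which must — and in the test
#' suite do — give identical results.
#'
#' Multiple members of one family from the same genome (paralogs) are
#' retained in the counts but collapse to a single presence for pangenome
#' accounting.
#'
#' @param proteins `data.frame` with columns `genome_id`, `gene_id`,
#'   `residues` (e.g. from [gen_protein_families()] or [read_protein_fasta()]).
#' @param threshold identity threshold in `(0, 1]`; 0.5 by default.
#' @param prefilter use the k-mer prefilter (`TRUE`) or compare against every
#'   centroid (`FALSE`).
#' @param prefilter_min_len shortest sequence length (residues) the
#'   prefilter may act on.
#' @param ... passed to [global_identity()] (scoring, penalties, denominator).
#' @return A [family_matrix()]; family ids `fam00001`... in founding order.
#' @export
greedy_cluster <- function(proteins, threshold = 0.5, prefilter = TRUE,
                           prefilter_min_len = 200, ...) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0) {
    stop("empty input: at least one protein record is required")
  }
  stopifnot(all(c("genome_id", "gene_id", "residues") %in% names(proteins)),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  seqs <- vapply(proteins$residues, check_protein, "", USE.NAMES = FALSE)
  label <- paste(proteins$genome_id, proteins$gene_id, sep = "|")
  ord <- order(-nchar(seqs), label, method = "radix")

  cen_seq <- character(0)
  cen_kmers <- list()
  assign_to <- integer(nrow(proteins))
  for (i in ord) {
    s <- seqs[i]
    hit <- 0L
    filterable <- prefilter && nchar(s) >= prefilter_min_len
    km <- if (filterable) protein_kmers(s) else NULL
    for (ci in seq_along(cen_seq)) {
      if (filterable && nchar(cen_seq[ci]) >= prefilter_min_len &&
          !any(km %in% cen_kmers[[ci]])) next
      if (global_identity(s, cen_seq[ci], ...) >= threshold) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      cen_seq <- c(cen_seq, s)
      cen_kmers[[length(cen_seq)]] <- protein_kmers(s)
      hit <- length(cen_seq)
    }
    assign_to[i] <- hit
  }

  genomes <- unique(proteins$genome_id)
  fam_ids <- sprintf("fam%05d", seq_along(cen_seq))
  counts <- matrix(0L, length(cen_seq), length(genomes),
                   dimnames = list(fam_ids, genomes))
  for (i in seq_len(nrow(proteins))) {
    counts[assign_to[i], proteins$genome_id[i]] <-
      counts[assign_to[i], proteins$genome_id[i]] + 1L
  }
  members <- lapply(seq_along(cen_seq), function(ci) {
    idx <- which(assign_to == ci)
    data.frame(genome_id = proteins$genome_id[idx],
               gene_id = proteins$gene_id[idx], row.names = NULL)
  })
  names(members) <- fam_ids
  family_matrix(counts, members)
}
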