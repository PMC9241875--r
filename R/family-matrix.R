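#' Gene-family occurrence matrix
#'
#' The central container of the pangenome machinery: an integer matrix of
#' per-genome gene counts, one row per gene family and one column per genome,
#' optionally carrying the family membership lists produced by clustering.
#' All pangenome mathematics consumes *presence* (`count > 0`); raw counts are
#' retained so paralogs remain visible.
#'
#' @param counts integer matrix, families x genomes; dimnames required.
#' @param members optional named list, one entry per family, each a
#'   `data.frame` with columns `genome_id` and `gene_id`.
#' @return An object of class `family_matrix`.
#' @export
family_matrix <- function(counts, members = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("fam", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("family counts must be non-negative")
  if (nrow(counts) > 0 && any(rowSums(counts > 0) == 0)) {
    stop("every family must be present in at least one genome")
  }
  if (!is.null(members)) {
    if (!identical(sort(names(members)), sort(rownames(counts)))) {
      stop("`members` names must match family ids")
    }
    members <- members[rownames(counts)]
  }
  structure(list(counts = counts, members = members),
            class = "family_matrix")
}

#' @export
print.family_matrix <- function(x, ...) {
  cat(sprintf("family_matrix: %d families x %d genomes (%d presence cells)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' @export
dim.family_matrix <- function(x) dim(x$counts)

# coerce plain matrices (counts or 0/1 presence) for the pangenome functions
as_family_matrix <- function(x) {
  if (inherits(x, "family_matrix")) return(x)
  if (is.matrix(x)) return(family_matrix(x))
  stop("expected a family_matrix or a families x genomes matrix")
}

presence <- function(fm) fm$counts > 0

#' Write / read a family matrix as TSV
#'
#' Plain rows-are-families, columns-are-genomes gene-count table with the
#' family id in the first column (`family`).
#'
#' @param fm a [family_matrix()].
#' @param path file path.
#' @return `write_family_matrix` returns `path` invisibly;
#'   `read_family_matrix` returns a [family_matrix()].
#' @export
write_family_matrix <- function(fm, path) {
  fm <- as_family_matrix(fm)
  df <- data.frame(family = rownames(fm$counts), fm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_matrix
#' @export
read_family_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  family_matrix(counts)
}
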