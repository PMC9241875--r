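#' Labeled symmetric similarity / distance matrix
#'
#' Shared container for pairwise genome metrics: ANI (%), dDDH (%), 16S
#' identity (%) and phylogenetic distances.  Similarity metrics carry 100 on
#' the diagonal, distances 0.  Symmetry is enforced to 1e-9.
#'
#' @param values square numeric matrix with identical row and column names
#'   (strain labels).  `NA` cells mark pairs where the metric was undefined.
#' @param metric one of `"ANI"`, `"dDDH"`, `"identity16S"`, `"distance"`.
#' @return The matrix with class `sim_matrix` and a `metric` attribute.
#' @export
sim_matrix <- function(values,
                       metric = c("ANI", "dDDH", "identity16S", "distance")) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <-
      colnames(values) %||% paste0("s", seq_len(nrow(values)))
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels must agree")
  }
  asym <- abs(values - t(values))
  if (any(asym[!is.na(asym)] > 1e-9)) stop("matrix not symmetric (tol 1e-9)")
  diag_expect <- if (metric == "distance") 0 else 100
  diag(values) <- diag_expect
  structure(values, metric = metric, class = c("sim_matrix", "matrix"))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix [%s], %d labels\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

sm_metric <- function(x) attr(x, "metric") %||% "distance"

# strict upper triangle as a pair table
upper_pairs <- function(x) {
  lab <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  data.frame(a = lab[idx[, 1]], b = lab[idx[, 2]],
             value = x[idx], row.names = NULL)
}

#' Write / read a sim_matrix as TSV
#' @param x a [sim_matrix()].
#' @param path file path.
#' @param metric metric label used when reading.
#' @return `write_sim_matrix` returns `path` invisibly; `read_sim_matrix`
#'   a [sim_matrix()].
#' @export
write_sim_matrix <- function(x, path) {
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_matrix
#' @export
read_sim_matrix <- function(path, metric = "distance") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sim_matrix(m, metric)
}
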