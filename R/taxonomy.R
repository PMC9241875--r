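#' Taxonomic threshold set
#'
#' The genomic and 16S thresholds conventionally used for bacterial species
#' and genus delineation: 70% dDDH and 95% ANI (configurable up to 96) for
#' species, 73.98% ANI and 94.5% 16S identity for genus membership, 97% 16S
#' identity for species.  All comparisons in this package are inclusive
#' (a value exactly at the threshold passes).
#'
#' @param ddh_species,ani_species,ani_genus,s16_genus,s16_species percents.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(ddh_species = 70, ani_species = 95,
                          ani_genus = 73.98, s16_genus = 94.5,
                          s16_species = 97) {
  if (ani_species <= ani_genus || s16_species <= s16_genus) {
    stop("species thresholds must exceed genus thresholds")
  }
  structure(list(ddh_species = ddh_species, ani_species = ani_species,
                 ani_genus = ani_genus, s16_genus = s16_genus,
                 s16_species = s16_species),
            class = "threshold_set")
}

#' Delineate genospecies from a similarity matrix
#'
#' Builds a graph with an edge for every pair at or above the species
#' threshold and takes connected components as genospecies clusters
#' (single-linkage — the pairwise reasoning practitioners apply by hand).
#' Because single linkage can chain, any within-cluster pair that falls
#' *below* the threshold is reported as a conflict rather than silently
#' resolved.
#'
#' @param mat a [sim_matrix()] with metric `"dDDH"` or `"ANI"`.
#' @param thresholds a [threshold_set()].
#' @param metric which metric the matrix holds (checked against the matrix
#'   attribute).
#' @return An object of class `species_partition`: `clusters` (named
#'   integer vector), `n_clusters`, `conflicts` (`data.frame` with columns
#'   `a`, `b`, `metric`, `value`), `threshold`.
#' @examples
#' m <- matrix(c(100, 78.8, 78.8, 100), 2, 2,
#'             dimnames = list(c("x", "y"), c("x", "y")))
#' delineate(sim_matrix(m, "dDDH"))
#' @export
delineate <- function(mat, thresholds = threshold_set(),
                      metric = c("dDDH", "ANI")) {
  metric <- match.arg(metric)
  stopifnot(inherits(mat, "sim_matrix"))
  if (sm_metric(mat) != metric) {
    stop("matrix metric is '", sm_metric(mat), "', requested '", metric, "'")
  }
  pairs <- upper_pairs(mat)
  if (any(is.na(pairs$value))) {
    bad <- pairs[is.na(pairs$value), ]
    stop("missing cells for pair(s): ",
         paste(bad$a, bad$b, sep = " ~ ", collapse = ", "))
  }
  thr <- switch(metric, dDDH = thresholds$ddh_species,
                ANI = thresholds$ani_species)
  labs <- rownames(mat)
  g <- igraph::graph_from_data_frame(
    pairs[pairs$value >= thr, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = labs))
  comp <- igraph::components(g)$membership[labs]
  # renumber clusters by first appearance in label order
  comp <- as.integer(factor(comp, levels = unique(comp)))
  names(comp) <- labs
  within <- comp[pairs$a] == comp[pairs$b]
  confl <- pairs[within & pairs$value < thr, , drop = FALSE]
  conflicts <- data.frame(a = confl$a, b = confl$b,
                          metric = rep(metric, nrow(confl)),
                          value = confl$value, row.names = NULL)
  structure(list(clusters = comp, n_clusters = max(comp),
                 conflicts = conflicts, metric = metric, threshold = thr),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("%d strains -> %d genospecies cluster(s) at %s >= %.4g%%\n",
              length(x$clusters), x$n_clusters, x$metric, x$threshold))
  if (nrow(x$conflicts) > 0) {
    cat(sprintf("  %d within-cluster pair(s) below threshold (non-transitivity):\n",
                nrow(x$conflicts)))
    print(x$conflicts)
  }
  invisible(x)
}

#' Genus-membership screen
#'
#' A strain is flagged in-genus when *all* its pairwise ANI values reach the
#' genus boundary (inclusive); the analogous 16S screen is run when a 16S
#' matrix is supplied.  The two reports are independent — the screen never
#' merges them.
#'
#' @param ani_matrix a [sim_matrix()] with metric `"ANI"`.
#' @param s16_matrix optional [sim_matrix()] with metric `"identity16S"`,
#'   same labels.
#' @param thresholds a [threshold_set()].
#' @return A list with `data.frame`s `ani` and (if provided) `s16`, one row
#'   per strain: `strain`, `in_genus`, `min_value`, `offending_pairs`.
#' @export
genus_screen <- function(ani_matrix, s16_matrix = NULL,
                         thresholds = threshold_set()) {
  stopifnot(inherits(ani_matrix, "sim_matrix"))
  screen_one <- function(mat, thr) {
    labs <- rownames(mat)
    rows <- lapply(labs, function(s) {
      vals <- mat[s, setdiff(labs, s)]
      low <- names(vals)[vals < thr]
      data.frame(strain = s, in_genus = length(low) == 0,
                 min_value = min(vals),
                 offending_pairs = paste(low, collapse = ","))
    })
    do.call(rbind, rows)
  }
  out <- list(ani = screen_one(ani_matrix, thresholds$ani_genus))
  if (!is.null(s16_matrix)) {
    if (!identical(sort(rownames(ani_matrix)), sort(rownames(s16_matrix)))) {
      stop("ANI and 16S matrices must share labels")
    }
    out$s16 <- screen_one(s16_matrix, thresholds$s16_genus)
  }
  out
}

#' Summary statistics of the off-diagonal values
#'
#' Mean, median, min and max over the strict upper triangle of a
#' [sim_matrix()].
#'
#' @param mat a [sim_matrix()] with at least 2 labels.
#' @return Named numeric vector `mean`, `median`, `min`, `max`.
#' @export
matrix_summary <- function(mat) {
  stopifnot(inherits(mat, "sim_matrix"), nrow(mat) >= 2)
  v <- mat[upper.tri(mat)]
  c(mean = mean(v, na.rm = TRUE), median = median(v, na.rm = TRUE),
    min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
}
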