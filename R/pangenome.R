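#' Partition gene families into core, accessory and unique
#'
#' Core families are present in every genome, unique families in exactly
#' one, accessory families in at least two but not all.  Per-genome
#' percentages are computed over the families present in that genome.
#'
#' @param fm a [family_matrix()] (or a plain families x genomes matrix).
#' @return An object of class `pangenome_partition` with components `core`,
#'   `accessory`, `unique` (counts), `classes` (per-family class vector) and
#'   `per_genome` (`data.frame` of percentages).
#' @examples
#' m <- rbind(A = c(1, 1, 1), B = c(1, 1, 0), C = c(0, 0, 1))
#' partition_families(m)
#' @export
partition_families <- function(fm) {
  fm <- as_family_matrix(fm)
  pres <- presence(fm)
  n <- ncol(pres)
  if (n < 2) stop("partition undefined for a single-genome matrix")
  rs <- rowSums(pres)
  classes <- ifelse(rs == n, "core", ifelse(rs == 1L, "unique", "accessory"))
  names(classes) <- rownames(pres)
  per_genome <- t(apply(pres, 2, function(p) {
    tot <- sum(p)
    100 * c(core = sum(p & classes == "core"),
            accessory = sum(p & classes == "accessory"),
            unique = sum(p & classes == "unique")) / max(tot, 1L)
  }))
  structure(list(core = sum(classes == "core"),
                 accessory = sum(classes == "accessory"),
                 unique = sum(classes == "unique"),
                 total = nrow(pres),
                 classes = classes,
                 per_genome = as.data.frame(per_genome)),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf(
    "pangenome partition of %d families: core %d (%.1f%%), accessory %d (%.1f%%), unique %d (%.1f%%)\n",
    x$total, x$core, 100 * x$core / x$total,
    x$accessory, 100 * x$accessory / x$total,
    x$unique, 100 * x$unique / x$total))
  invisible(x)
}

#' COG category profile per pangenome class
#'
#' For each pangenome class, the fraction of families falling in each COG
#' functional category.  A family's category is the majority vote over its
#' members' mapped categories; ties give `"ambiguous"` and families with no
#' mapped member give `"unassigned"`.  The map may be partial.
#'
#' @param fm a [family_matrix()]; if it carries membership lists the map is
#'   keyed by gene id, otherwise by family id.
#' @param partition result of [partition_families()] on `fm`.
#' @param cog_map named character vector (or two-column `data.frame`)
#'   mapping gene ids to single COG letters `A`-`Z`.
#' @return A class x category matrix of proportions (rows sum to 1).
#' @export
cog_profile <- function(fm, partition, cog_map) {
  fm <- as_family_matrix(fm)
  if (is.data.frame(cog_map)) {
    cog_map <- setNames(as.character(cog_map[[2]]), cog_map[[1]])
  }
  bad <- setdiff(unique(cog_map), LETTERS)
  if (length(bad) > 0) {
    stop("unknown COG category letter(s) ", paste(bad, collapse = ", "),
         "; valid letters are ", paste(LETTERS, collapse = ""))
  }
  fam_ids <- rownames(fm$counts)
  fam_cat <- vapply(fam_ids, function(f) {
    genes <- if (!is.null(fm$members)) fm$members[[f]]$gene_id else f
    cats <- cog_map[genes]
    cats <- cats[!is.na(cats)]
    if (length(cats) == 0) return("unassigned")
    tab <- sort(table(cats), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
  }, "")
  classes <- partition$classes[fam_ids]
  levels_cat <- sort(unique(fam_cat))
  rows <- lapply(c("core", "accessory", "unique"), function(cl) {
    sub <- fam_cat[classes == cl]
    if (length(sub) == 0) return(setNames(rep(NA_real_, length(levels_cat)),
                                          levels_cat))
    as.numeric(table(factor(sub, levels = levels_cat))) / length(sub)
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(c("core", "accessory", "unique"), levels_cat)
  out
}

#' Pangenome and core-genome rarefaction curves
#'
#' For each iteration, genomes are taken in a fresh uniform random order
#' (permutations are sampled independently across iterations) and the
#' pangenome size (union of families) and core size (intersection) are
#' recorded after adding each genome.  Medians per genome count across
#' iterations are the fitting substrate of [fit_heaps()] and
#' [fit_core_decay()].
#'
#' @param fm a [family_matrix()].
#' @param iterations number of random genome orders (>= 1).
#' @param seed integer seed.
#' @return An object of class `accumulation_curves`: matrices `pan` and
#'   `core` (iterations x genomes), vectors `pan_median`, `core_median`,
#'   and `x = 1:n_genomes`.
#' @export
accumulation_curves <- function(fm, iterations = 500, seed = 1) {
  fm <- as_family_matrix(fm)
  stopifnot(is_count(iterations), iterations >= 1)
  pres <- presence(fm)
  n <- ncol(pres)
  with_rng(seed, {
    pan <- matrix(0L, iterations, n)
    core <- matrix(0L, iterations, n)
    for (it in seq_len(iterations)) {
      p <- sample.int(n)
      A <- pres[, p, drop = FALSE]
      # first genome in which each family appears -> pan via cumulative tally
      first_hit <- max.col(A, ties.method = "first")
      pan[it, ] <- cumsum(tabulate(first_hit, nbins = n))
      # core(x): families present in every one of the first x genomes,
      # i.e. whose first absence comes after position x
      first_miss <- max.col(!A, ties.method = "first")
      first_miss[rowSums(A) == n] <- n + 1L
      core[it, ] <- nrow(A) - cumsum(tabulate(first_miss, nbins = n))
    }
    structure(list(pan = pan, core = core,
                   pan_median = apply(pan, 2, median),
                   core_median = apply(core, 2, median),
                   x = seq_len(n), iterations = iterations),
              class = "accumulation_curves")
  })
}

#' @export
print.accumulation_curves <- function(x, ...) {
  cat(sprintf(
    "accumulation curves: %d iterations over %d genomes; pan %g -> %g, core %g -> %g (medians)\n",
    x$iterations, length(x$x), x$pan_median[1], tail(x$pan_median, 1),
    x$core_median[1], tail(x$core_median, 1)))
  invisible(x)
}

#' Boxplot of pangenome / core-genome accumulation
#'
#' Base-graphics boxplots of pangenome (yellow) and core-genome (cyan) sizes
#' per number of genomes sampled.
#'
#' @param curves an [accumulation_curves()] result.
#' @param ... passed to [graphics::boxplot()].
#' @return `curves`, invisibly.
#' @export
plot_accumulation <- function(curves, ...) {
  stopifnot(inherits(curves, "accumulation_curves"))
  n <- length(curves$x)
  graphics::boxplot(split(as.vector(curves$pan), col(curves$pan)),
                    at = curves$x - 0.15, boxwex = 0.25, col = "gold",
                    xlim = c(0.5, n + 0.5), xlab = "genomes sampled",
                    ylab = "gene families", names = curves$x, ...)
  graphics::boxplot(split(as.vector(curves$core), col(curves$core)),
                    at = curves$x + 0.15, boxwex = 0.25, col = "cyan3",
                    add = TRUE, names = rep("", n))
  invisible(curves)
}

# shared NLS driver: Levenberg-Marquardt refinement of a log-domain linear
# initialization, iterated to parameter tolerance below 1e-10.  When the
# initialization already reproduces the data exactly (noiseless curves) it
# is returned as-is.
fit_nls <- function(x, y, model, start) {
  res_fun <- function(p) y - model(p, x)
  r0 <- res_fun(start)
  if (sqrt(sum(r0^2)) <= 1e-10 * max(1, sqrt(sum(y^2)))) {
    return(list(par = start, residual_norm = sqrt(sum(r0^2))))
  }
  out <- minpack.lm::nls.lm(
    par = start, fn = res_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500))
  list(par = out$par, residual_norm = sqrt(sum(out$fvec^2)))
}

#' Fit Heaps' power law to a pangenome curve
#'
#' Nonlinear least squares of `f(x) = a * x^b` against the per-x pangenome
#' medians, initialized by log-log linear regression.  The exponent decides
#' openness: the pangenome is *open* when `0 < b < 1` and *closed* when
#' `b < 0`; `b = 0` and `b >= 1` are labelled *boundary* rather than
#' silently extrapolated.
#'
#' @param curves an [accumulation_curves()] result, or a list/data.frame
#'   with numeric `x` and `pan_median`.
#' A fitted exponent within 1e-9 of 0 or 1 is classified as boundary, so
#' numerically exact flat or linear curves are not reported as open.
#'
#' @return An object of class `heaps_fit`: `a`, `b`, `residual_norm`,
#'   `classification`.
#' @export
fit_heaps <- function(curves) {
  x <- curves$x
  y <- curves$pan_median
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3) stop("need >= 3 distinct x values")
  if (any(y <= 0)) {
    stop("non-positive pangenome medians: log-domain initialization impossible")
  }
  init <- lm(log(y) ~ log(x))
  fit <- fit_nls(x, y, function(p, x) p[["a"]] * x^p[["b"]],
                 c(a = exp(coef(init)[[1]]), b = coef(init)[[2]]))
  b <- fit$par[["b"]]
  # a b within numerical noise of 0 or 1 is the boundary case, not a
  # spurious open/closed call
  b_eff <- if (abs(b) < 1e-9) 0 else if (abs(b - 1) < 1e-9) 1 else b
  classification <- if (b_eff > 0 && b_eff < 1) "open"
                    else if (b_eff < 0) "closed" else "boundary"
  structure(list(a = fit$par[["a"]], b = b,
                 residual_norm = fit$residual_norm,
                 classification = classification),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: f(x) = %.4g * x^%.6g  [%s pangenome]\n",
              x$a, x$b, x$classification))
  invisible(x)
}

#' Fit an exponential decay to the core-genome curve
#'
#' Nonlinear least squares of `f1(x) = c * exp(d * x)` against the per-x
#' core-genome medians, initialized by log-linear regression.  Non-positive
#' medians cannot enter the log-domain initialization: the fit is restricted
#' to the leading positive prefix with a warning, and fails if fewer than
#' three points remain.
#'
#' @param curves an [accumulation_curves()] result, or a list/data.frame
#'   with numeric `x` and `core_median`.
#' @return An object of class `decay_fit`: `c`, `d`, `residual_norm`.
#' @export
fit_core_decay <- function(curves) {
  x <- curves$x
  y <- curves$core_median
  if (any(y <= 0)) {
    n_pos <- match(TRUE, y <= 0) - 1L
    warning("non-positive core medians from x = ", x[n_pos + 1L],
            "; fitting the positive prefix only")
    x <- x[seq_len(n_pos)]; y <- y[seq_len(n_pos)]
  }
  if (length(unique(x)) < 3) stop("need >= 3 distinct x values with positive core medians")
  init <- lm(log(y) ~ x)
  fit <- fit_nls(x, y, function(p, x) p[["c"]] * exp(p[["d"]] * x),
                 c(c = exp(coef(init)[[1]]), d = coef(init)[[2]]))
  structure(list(c = fit$par[["c"]], d = fit$par[["d"]],
                 residual_norm = fit$residual_norm),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("core-genome decay fit: f1(x) = %.4g * exp(%.6g x)\n",
              x$c, x$d))
  invisible(x)
}

#' Expected accumulation curve of a content model
#'
#' Closed-form expected pangenome size when sampling `x` genomes from the
#' generative model of [gen_family_matrix()]: the core contributes its full
#' size, each accessory-pool family is seen with probability
#' `1 - (1 - p)^x`, and unique draws add `unique_per_genome * x` on average.
#' Used as the independent oracle for exponent-recovery tests: the
#' "engineered" Heaps exponent of a model is the `b` fitted to this exact
#' curve.
#'
#' @param n_genomes,core_size,accessory_pool_size,p_accessory,unique_per_genome
#'   model parameters as in [gen_family_matrix()].
#' @return `data.frame` with `x` and `pan_median` (expected sizes), ready
#'   for [fit_heaps()].
#' @export
expected_pan_curve <- function(n_genomes, core_size, accessory_pool_size,
                               p_accessory, unique_per_genome) {
  x <- seq_len(n_genomes)
  data.frame(
    x = x,
    pan_median = core_size +
      accessory_pool_size * (1 - (1 - p_accessory)^x) +
      unique_per_genome * x)
}
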