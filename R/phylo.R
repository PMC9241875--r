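GAP_CHARS <- c("-", "N")

# alignment = named character vector of equal-length gapped DNA strings
as_alignment <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x) || length(x) < 2) {
    stop("alignment needs at least 2 sequences")
  }
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("alignment rows must carry unique taxon labels")
  }
  x <- toupper(x)
  if (length(unique(nchar(x))) != 1) stop("alignment rows differ in length")
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 c(DNA_BASES, GAP_CHARS))
  if (length(bad) > 0) stop("invalid alignment character '", bad[1], "'")
  x
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln, ""))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# P/Q proportions over sites free of gaps and Ns in both rows
pq_proportions <- function(ca, cb) {
  keep <- !(ca %in% GAP_CHARS) & !(cb %in% GAP_CHARS)
  if (sum(keep) == 0) stop("zero included sites after gap/N exclusion")
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  P <- sum(diff & is_transition(ca, cb)) / length(ca)
  Q <- sum(diff & !is_transition(ca, cb)) / length(ca)
  c(P = P, Q = Q, n = length(ca))
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where P and Q are the
#' transition and transversion proportions over sites free of gaps and Ns in
#' both rows.  Sites are excluded pairwise.
#'
#' @param a,b aligned sequences of equal length (strings).
#' @return the K2P distance (substitutions per site).
#' @examples
#' # P = 0.1, Q = 0.05 gives 0.170182
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  pq <- pq_proportions(ca, cb)
  k2p_from_pq(pq[["P"]], pq[["Q"]])
}

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: K2P undefined for P = ", signif(P, 4),
         ", Q = ", signif(Q, 4))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix of an alignment
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (or a `DNAStringSet`).
#' @param deletion `"pairwise"` (default; sites dropped per pair) or
#'   `"complete"` (columns with any gap/N dropped globally first).
#' @param saturation `"error"` (default) or `"pdistance"`: on a saturated
#'   pair, fall back to the p-distance `P + Q` and record the pair in the
#'   `saturated_pairs` attribute.
#' @return A [sim_matrix()] with metric `"distance"`.
#' @export
k2p_matrix <- function(alignment, deletion = c("pairwise", "complete"),
                       saturation = c("error", "pdistance")) {
  alignment <- as_alignment(alignment)
  deletion <- match.arg(deletion)
  saturation <- match.arg(saturation)
  M <- aln_matrix(alignment)
  if (deletion == "complete") {
    keep <- colSums(matrix(M %in% GAP_CHARS, nrow(M))) == 0
    if (!any(keep)) stop("complete deletion removes all columns")
    M <- M[, keep, drop = FALSE]
  }
  n <- nrow(M)
  labs <- names(alignment)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pq <- pq_proportions(M[i, ], M[j, ])
      d <- tryCatch(k2p_from_pq(pq[["P"]], pq[["Q"]]),
                    error = function(e) NA_real_)
      if (is.na(d)) {
        if (saturation == "error") {
          stop("saturation: K2P undefined for pair ", labs[i], " ~ ", labs[j])
        }
        d <- pq[["P"]] + pq[["Q"]]
        saturated <- c(saturated, paste(labs[i], labs[j], sep = " ~ "))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  out <- sim_matrix(D, "distance")
  attr(out, "saturated_pairs") <- saturated
  out
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration under the Q-criterion.  Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' labels; negative branch lengths are clamped to zero with the total
#' clamped amount recorded in the `negative_deficit` attribute.  Additive
#' distance matrices are recovered exactly (topology and branch lengths).
#'
#' @param dist a [sim_matrix()] with metric `"distance"`, a `dist`, or a
#'   square symmetric numeric matrix with zero diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (inherits(dist, "sim_matrix") && sm_metric(dist) != "distance") {
    stop("nj_tree needs a distance matrix, got metric '", sm_metric(dist), "'")
  }
  D <- unclass(as.matrix(dist))
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (any(abs(D - t(D)) > 1e-9)) stop("asymmetric distance matrix")
  if (any(D < 0)) stop("negative distances")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")

  labs <- rownames(D)
  frag <- as.list(labs)       # growing newick fragments per active node
  names(frag) <- labs
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)

  if (n == 2) {
    d <- D[1, 2]
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(d / 2), labs[2], fmt(d / 2))
    tree <- ape::read.tree(text = nwk)
    attr(tree, "negative_deficit") <- 0
    return(tree)
  }

  act <- labs
  while (length(act) > 3) {
    m <- length(act)
    Dm <- D[act, act]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    pair_lab <- cbind(pmin(act[cand[, 1]], act[cand[, 2]]),
                      pmax(act[cand[, 1]], act[cand[, 2]]))
    pick <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]

    dij <- D[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new <- paste0("__u", length(frag) + 1L)
    frag[[new]] <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt(li),
                           frag[[j]], fmt(lj))
    others <- setdiff(act, c(i, j))
    dnew <- (D[i, others] + D[j, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new
    D[new, others] <- D[others, new] <- dnew
    act <- c(others, new)
  }

  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((D[a, b] + D[a, c3] - D[b, c3]) / 2)
  lb <- clamp((D[a, b] + D[b, c3] - D[a, c3]) / 2)
  lc <- clamp((D[a, c3] + D[b, c3] - D[a, b]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[[a]], fmt(la), frag[[b]], fmt(lb), frag[[c3]], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# non-trivial bipartitions of an unrooted tree, canonicalized so the side
# not containing the alphabetically first taxon is kept; returns keys
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  keys <- vapply(internal_children, function(nd) {
    s <- sort(desc(nd))
    if (anchor %in% s) s <- sort(setdiff(tree$tip.label, s))
    paste(s, collapse = ";")
  }, "")
  setNames(keys, internal_children)
}

#' Bootstrap support for an NJ/K2P tree
#'
#' Resamples alignment columns with replacement, rebuilds a K2P + NJ tree
#' per replicate, and reports for each internal edge of the full-alignment
#' tree the percentage of replicates containing the same bipartition.
#' Saturated replicate distances fall back to the p-distance (counted in
#' the `saturated_replicates` attribute).
#'
#' @param alignment named character vector of aligned sequences.
#' @param reps bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param deletion gap handling, as in [k2p_matrix()].
#' @return The NJ tree of the full alignment with supports (percent) as
#'   internal node labels (`node.label`).
#' @export
bootstrap_support <- function(alignment, reps = 1000, seed = 1,
                              deletion = "pairwise") {
  alignment <- as_alignment(alignment)
  stopifnot(is_count(reps), reps >= 1)
  L <- nchar(alignment[1])
  if (L < 2) stop("alignment must have at least 2 columns")
  M <- aln_matrix(alignment)
  labs <- names(alignment)

  dist_of <- function(cols) {
    sub <- setNames(apply(M[, cols, drop = FALSE], 1, paste, collapse = ""),
                    labs)
    k2p_matrix(sub, deletion = deletion, saturation = "pdistance")
  }

  ref <- nj_tree(dist_of(seq_len(L)))
  ref_splits <- tree_splits(ref)
  hit <- setNames(numeric(length(ref_splits)), ref_splits)
  n_sat <- 0L
  with_rng(seed, {
    for (rpl in seq_len(reps)) {
      d <- dist_of(sample.int(L, L, replace = TRUE))
      if (length(attr(d, "saturated_pairs")) > 0) n_sat <- n_sat + 1L
      sp <- tree_splits(nj_tree(d))
      got <- ref_splits %in% sp
      hit[got] <- hit[got] + 1
    }
  })
  if (n_sat > 0) {
    warning(n_sat, " replicate(s) used p-distance fallback for saturated pairs")
  }
  support <- 100 * hit / reps
  n <- length(labs)
  node.label <- rep("", ref$Nnode)
  for (k in seq_along(ref_splits)) {
    node <- as.integer(names(ref_splits)[k])
    node.label[node - n] <- sprintf("%g", support[k])
  }
  ref$node.label <- node.label
  attr(ref, "support") <- setNames(support, ref_splits)
  attr(ref, "saturated_replicates") <- n_sat
  ref
}

#' Concatenate per-family alignments into a supermatrix
#'
#' Column-wise concatenation over the union of taxa (first-appearance
#' order); a taxon absent from a family receives an all-gap block.  Block
#' boundaries are recorded in the `blocks` attribute.
#'
#' @param families list of alignments (named character vectors).
#' @return A named character vector (the supermatrix) with a `blocks`
#'   attribute (`data.frame`: `family`, `start`, `end`).
#' @export
concat_alignments <- function(families) {
  stopifnot(is.list(families), length(families) >= 1)
  for (f in seq_along(families)) {
    fam <- families[[f]]
    if (anyDuplicated(names(fam))) {
      stop("duplicate taxon labels within family ", f)
    }
    if (length(unique(nchar(fam))) != 1) {
      stop("family ", f, " rows differ in length")
    }
  }
  taxa <- unique(unlist(lapply(families, names)))
  out <- setNames(rep("", length(taxa)), taxa)
  blocks <- data.frame(family = character(0), start = integer(0),
                       end = integer(0))
  pos <- 0L
  fam_names <- names(families) %||% paste0("family", seq_along(families))
  for (f in seq_along(families)) {
    fam <- families[[f]]
    len <- nchar(fam[1])
    block <- setNames(rep(strrep("-", len), length(taxa)), taxa)
    block[names(fam)] <- fam
    out <- paste0(out, block)
    names(out) <- taxa
    blocks <- rbind(blocks, data.frame(family = fam_names[f],
                                       start = pos + 1L, end = pos + len))
    pos <- pos + len
  }
  attr(out, "blocks") <- blocks
  out
}

#' Write a tree as newick
#'
#' Support values (when present) are written as internal node labels and
#' branch lengths with six decimals.
#'
#' @param tree an `ape::phylo` tree.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
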