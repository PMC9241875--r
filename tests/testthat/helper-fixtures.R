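# shared fixture builders; everything is generated in code, nothing on disk

# random presence matrix where every family occurs somewhere
random_presence_matrix <- function(n_fam, n_gen, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_fam * n_gen, 1, runif(1, 0.2, 0.8)), n_fam, n_gen)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_gen, sum(empty), replace = TRUE))] <- 1
  dimnames(m) <- list(sprintf("f%04d", seq_len(n_fam)),
                      sprintf("g%02d", seq_len(n_gen)))
  m
}

# random unrooted additive tree and its exact path-length distance matrix;
# the distances come from ape::cophenetic.phylo, an oracle independent of
# the package's NJ implementation
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.1, 2))
  D <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(D))
  list(tree = tree, D = D[labs, labs])
}

# symmetric similarity matrix with values drawn uniformly in [lo, hi]
random_sim_values <- function(n, lo, hi, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  diag(m) <- 100
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("s%02d", seq_len(n)))
  m
}

# the 16-strain dDDH structure of a one-conspecific-pair genus:
# exactly one pair above the 70% species threshold, all others far below
synthetic_16strain_ddh <- function(seed = 42) {
  set.seed(seed)
  n <- 16
  labs <- c("iso01", "iso02", sprintf("iso%02d", 3:n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 18.2, 47.3)
  m <- m + t(m)
  m[1, 2] <- m[2, 1] <- 78.8
  diag(m) <- 100
  sim_matrix(m, "dDDH")
}

# small protein-clustering instance; full-length proteins so the k-mer
# prefilter is actually in play
random_cluster_instance <- function(seed) {
  sim <- gen_family_matrix(2, core_size = 2, accessory_pool_size = 2,
                           p_accessory = 0.5, unique_per_genome = 1,
                           seed = seed)
  gen_protein_families(sim$matrix, aa_divergence = 0.15, seed = seed + 1)
}

# presence patterns of a family matrix as an unnamed sorted key multiset
presence_key <- function(counts) {
  unname(sort(apply(counts > 0, 1, paste, collapse = "")))
}

expect_same_families <- function(fm, generating_counts) {
  expect_identical(presence_key(fm$counts),
                   presence_key(generating_counts[, colnames(fm$counts)]))
}
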