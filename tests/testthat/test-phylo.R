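test_that("K2P distance: exact values, gap exclusion, saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # 20 sites: 2 transitions (A->G), 1 transversion (A->C): P = 0.1, Q = 0.05
  a2 <- "AAAAAAAAAAAAAAAAAAAA"
  b2 <- "GGCAAAAAAAAAAAAAAAAA"    # 2 transitions + 1 transversion
  d <- k2p_distance(a2, b2)
  expect_equal(d, -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1))
  expect_equal(round(d, 6), 0.170181)

  # gapped / ambiguous sites drop out pairwise
  expect_equal(k2p_distance("ACGT-NAA", "ACGTTTGA"),
               k2p_distance("ACGTAA", "ACGTGA"))
  expect_error(k2p_distance("----", "ACGT"), "zero included sites")
  # P = 0.5, Q = 0: 1 - 2P - Q = 0
  expect_error(k2p_distance("AAAAAAAAAA", "GGGGGAAAAA"), "saturation")
})

test_that("K2P approaches the p-distance for small divergence", {
  L <- 20000
  a <- strrep("A", L)
  b <- paste0(strrep("G", 2), strrep("C", 1), strrep("A", L - 3))
  p <- 3 / L
  expect_lt(abs(k2p_distance(a, b) - p) / p, 0.01)
})

test_that("K2P matrix agrees with the ape K80 implementation", {
  sim <- gen_divergent_pair(2000, 0.05, seed = 5)
  aln <- c(t1 = sim$genome_a, t2 = sim$genome_b,
           t3 = gen_divergent_pair(2000, 0.10, seed = 5)$genome_b)
  D <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
  D_ape <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unclass(D), D_ape[rownames(D), colnames(D)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NJ closed forms: two and three taxa", {
  D2 <- matrix(c(0, 1.4, 1.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(sum(t2$edge.length), 1.4)

  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(D3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 4) / 2)
  expect_equal(bl[["b"]], (2 + 4 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 4 - 2) / 2)
})

test_that("NJ recovers the four-taxon additive tree exactly", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs], D,
               tolerance = 1e-12)
  # the AB|CD split is present
  splits <- panogri:::tree_splits(tr)
  expect_true("A;B" %in% splits || "C;D" %in% splits)
})

test_that("NJ recovers random additive trees (path-length oracle)", {
  for (seed in 1:12) {
    case <- random_additive_case(n_taxa = sample(4:12, 1), seed = seed)
    tr <- nj_tree(case$D)
    got <- as.matrix(ape::cophenetic.phylo(tr))
    labs <- rownames(case$D)
    expect_equal(got[labs, labs], case$D, tolerance = 1e-8)
    expect_equal(attr(tr, "negative_deficit"), 0, tolerance = 1e-9)
    # topology cross-check against the independent ape implementation
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(as.dist(case$D)))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ validates its input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(m), "asymmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(nj_tree(m2), "negative")
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
  s <- sim_matrix(matrix(c(100, 90, 90, 100), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))), "ANI")
  expect_error(nj_tree(s), "distance")
})

test_that("bootstrap: clean signal gets full support, seeds reproduce", {
  # 90 constant columns + 10 columns splitting AB|CD (transversion, far
  # from saturation)
  col_const <- c(A = "A", B = "A", C = "A", D = "A")
  col_split <- c(A = "A", B = "A", C = "C", D = "C")
  aln <- vapply(names(col_const), function(t) {
    paste0(strrep(col_const[t], 90), strrep(col_split[t], 10))
  }, "")
  bt <- bootstrap_support(aln, reps = 100, seed = 5)
  expect_equal(unname(attr(bt, "support")), 100)

  bt2 <- bootstrap_support(aln, reps = 100, seed = 5)
  expect_identical(attr(bt, "support"), attr(bt2, "support"))

  bt3 <- bootstrap_support(aln, reps = 1, seed = 9)
  expect_true(all(attr(bt3, "support") %in% c(0, 100)))

  expect_error(bootstrap_support(c(A = "A", B = "A", C = "A"), reps = 10),
               "2 columns")
})

test_that("bootstrap supports are invariant to taxon input order", {
  sim1 <- gen_divergent_pair(600, 0.03, seed = 21)
  sim2 <- gen_divergent_pair(600, 0.12, seed = 21)
  sim3 <- gen_divergent_pair(600, 0.15, seed = 21)
  aln <- c(w = sim1$genome_a, x = sim1$genome_b,
           y = sim2$genome_b, z = sim3$genome_b)
  s1 <- attr(bootstrap_support(aln, reps = 50, seed = 3), "support")
  s2 <- attr(bootstrap_support(aln[c(3, 1, 4, 2)], reps = 50, seed = 3),
             "support")
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))])
})

test_that("concatenation builds the supermatrix with gap blocks", {
  f1 <- c(a = strrep("A", 100), b = strrep("C", 100))
  f2 <- c(a = strrep("G", 250), c = strrep("T", 250))
  sm <- concat_alignments(list(fam1 = f1, fam2 = f2))
  expect_equal(unname(nchar(sm)), rep(350, 3))
  expect_equal(substr(sm[["b"]], 101, 350), strrep("-", 250))
  expect_equal(substr(sm[["c"]], 1, 100), strrep("-", 100))
  expect_equal(attr(sm, "blocks")$end, c(100L, 350L))

  single <- concat_alignments(list(f1))
  expect_equal(as.character(single), unname(f1))
  expect_identical(names(single), names(f1))

  dup <- c(a = "AC", a = "GT")
  expect_error(concat_alignments(list(dup)), "duplicate")
})

test_that("newick output round-trips topology and lengths", {
  case <- random_additive_case(8, seed = 99)
  tr <- nj_tree(case$D)
  path <- tempfile(fileext = ".nwk")
  write_tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  labs <- rownames(case$D)
  expect_equal(as.matrix(ape::cophenetic.phylo(back))[labs, labs],
               case$D, tolerance = 1e-4)
})
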