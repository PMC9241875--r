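test_that("partition classifies core, accessory and unique correctly", {
  m <- rbind(A = c(1, 1, 1), B = c(1, 1, 0), C = c(0, 0, 1))
  p <- partition_families(m)
  expect_equal(c(p$core, p$accessory, p$unique), c(1L, 1L, 1L))
  expect_equal(unname(p$classes), c("core", "accessory", "unique"))

  all_core <- matrix(1, 4, 3)
  p2 <- partition_families(all_core)
  expect_equal(c(p2$accessory, p2$unique), c(0L, 0L))

  expect_error(partition_families(matrix(1, 5, 1)), "single-genome")
})

test_that("partition classes sum to the family total on random matrices", {
  for (seed in 1:25) {
    m <- random_presence_matrix(sample(20:200, 1), sample(2:12, 1), seed)
    p <- partition_families(m)
    expect_equal(p$core + p$accessory + p$unique, nrow(m))
    expect_true(all(rowSums(p$per_genome) - 100 < 1e-9))
  }
})

test_that("COG profile: trivial maps, constructed fractions, errors", {
  sim <- gen_family_matrix(3, core_size = 4, unique_per_genome = 2, seed = 2)
  prot <- gen_protein_families(sim$matrix, aa_divergence = 0.05, seed = 3)
  fm <- greedy_cluster(prot)
  part <- partition_families(fm)

  all_j <- setNames(rep("J", nrow(prot)), prot$gene_id)
  prof <- cog_profile(fm, part, all_j)
  expect_equal(unname(prof["core", "J"]), 1)

  # empty map: every populated class is 100% unassigned (this matrix has
  # no accessory families, so that row is NA by construction)
  empty <- cog_profile(fm, part, setNames(character(0), character(0)))
  expect_equal(unname(empty["core", "unassigned"]), 1)
  expect_equal(unname(empty["unique", "unassigned"]), 1)
  expect_true(is.na(empty["accessory", "unassigned"]))

  expect_error(cog_profile(fm, part, c(g1 = "j")), "valid letters")
})

test_that("COG majority vote and tie handling follow construction", {
  # family f1: members J,J,K -> J; family f2: members J,K -> ambiguous
  counts <- rbind(f1 = c(2, 1), f2 = c(1, 1))
  colnames(counts) <- c("g1", "g2")
  members <- list(
    f1 = data.frame(genome_id = c("g1", "g1", "g2"),
                    gene_id = c("a1", "a2", "a3")),
    f2 = data.frame(genome_id = c("g1", "g2"), gene_id = c("b1", "b2")))
  fm <- family_matrix(counts, members)
  part <- partition_families(fm)
  prof <- cog_profile(fm, part,
                      c(a1 = "J", a2 = "J", a3 = "K", b1 = "J", b2 = "K"))
  expect_equal(unname(prof["core", "J"]), 0.5)
  expect_equal(unname(prof["core", "ambiguous"]), 0.5)
})

test_that("accumulation curves: flat, disjoint and deterministic cases", {
  ident <- matrix(1, 7, 5)             # identical genomes, 7 families
  cur <- accumulation_curves(ident, iterations = 20, seed = 1)
  expect_true(all(cur$pan == 7))
  expect_true(all(cur$core == 7))

  disj <- gen_family_matrix(4, unique_per_genome = 6, seed = 3)$matrix
  u <- colSums(disj$counts)            # per-genome unique counts
  cur2 <- accumulation_curves(disj, iterations = 30, seed = 2)
  expect_true(all(cur2$core[, 2:4] == 0))
  expect_equal(unname(cur2$pan[, 4]), rep(sum(u), 30))

  c1 <- accumulation_curves(disj, iterations = 10, seed = 5)
  c2 <- accumulation_curves(disj, iterations = 10, seed = 5)
  expect_identical(c1, c2)
})

test_that("pan medians never decrease, core medians never increase", {
  for (seed in 1:10) {
    m <- random_presence_matrix(150, 10, seed)
    cur <- accumulation_curves(m, iterations = 40, seed = seed + 100)
    expect_true(all(diff(cur$pan_median) >= 0))
    expect_true(all(diff(cur$core_median) <= 0))
    expect_true(all(t(apply(cur$pan, 1, diff)) >= 0))
    expect_true(all(t(apply(cur$core, 1, diff)) <= 0))
  }
})

test_that("Heaps fit recovers exact power-law data and flags openness", {
  hf <- fit_heaps(list(x = 1:10, pan_median = 10 * (1:10)))
  expect_lt(abs(hf$a - 10), 1e-8)
  expect_lt(abs(hf$b - 1), 1e-8)
  expect_equal(hf$classification, "boundary")

  flat <- fit_heaps(list(x = 1:8, pan_median = rep(100, 8)))
  expect_lt(abs(flat$a - 100), 1e-8)
  expect_lt(abs(flat$b), 1e-8)
  expect_equal(flat$classification, "boundary")

  expect_error(fit_heaps(list(x = 1:2, pan_median = c(1, 2))), ">= 3")
  expect_error(fit_heaps(list(x = 1:5, pan_median = c(0, 1, 2, 3, 4))),
               "non-positive")
})

test_that("openness rule: open iff 0 < b < 1, closed iff b < 0", {
  want <- c("-0.5" = "closed", "0" = "boundary", "0.5" = "open",
            "1" = "boundary", "1.5" = "boundary")
  for (b in names(want)) {
    y <- 50 * (1:12)^as.numeric(b)
    hf <- fit_heaps(list(x = 1:12, pan_median = y))
    expect_equal(hf$classification, unname(want[b]), label = paste("b =", b))
  }
})

test_that("decay fit recovers exact exponential data to machine precision", {
  df <- fit_core_decay(list(x = 1:10, core_median = 2000 * exp(-0.05 * 1:10)))
  expect_lt(abs(df$c - 2000), 1e-7)
  expect_lt(abs(df$d + 0.05), 1e-10)

  const <- fit_core_decay(list(x = 1:6, core_median = rep(70, 6)))
  expect_lt(abs(const$c - 70), 1e-8)
  expect_lt(abs(const$d), 1e-10)

  # disjoint genomes: core hits 0 at x = 2, positive prefix too short
  expect_error(
    suppressWarnings(
      fit_core_decay(list(x = 1:5, core_median = c(30, 0, 0, 0, 0)))),
    ">= 3")
  expect_warning(
    fit_core_decay(list(x = 1:6, core_median = c(90, 60, 40, 26, 0, 0))),
    "positive prefix")
})

test_that("fitted exponent tracks the engineered accumulation exponent", {
  b_eng <- fit_heaps(expected_pan_curve(12, 300, 800, 0.15, 20))$b
  sim <- gen_family_matrix(12, 300, 800, 0.15, 20, seed = 31)
  cur <- accumulation_curves(sim$matrix, iterations = 200, seed = 32)
  expect_lt(abs(fit_heaps(cur)$b - b_eng), 0.05)
})
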