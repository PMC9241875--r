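test_that("core-only and unique-only content models behave by construction", {
  core_only <- gen_family_matrix(3, core_size = 5, seed = 1)
  expect_equal(dim(core_only$matrix$counts), c(5L, 3L))
  expect_true(all(core_only$matrix$counts == 1L))
  expect_true(all(core_only$truth$class == "core"))

  uniq_only <- gen_family_matrix(3, unique_per_genome = 2, seed = 4)
  pres <- uniq_only$matrix$counts > 0
  expect_true(all(rowSums(pres) == 1))
  expect_true(all(uniq_only$truth$class == "unique"))
  # family count equals the total of the per-genome draws
  expect_equal(nrow(pres), sum(colSums(pres)))
})

test_that("content model rejects degenerate inputs", {
  expect_error(gen_family_matrix(1, core_size = 5), "n_genomes")
  expect_error(gen_family_matrix(3, core_size = 0), "no families")
  expect_error(gen_family_matrix(3, accessory_pool_size = 10,
                                 p_accessory = 1.5), "is_prob")
})

test_that("truth classes agree with partition_families across seeds", {
  for (seed in 1:20) {
    sim <- gen_family_matrix(6, core_size = 30, accessory_pool_size = 40,
                             p_accessory = 0.4, unique_per_genome = 3,
                             seed = seed)
    p <- partition_families(sim$matrix)
    truth_counts <- table(factor(sim$truth$class,
                                 c("core", "accessory", "unique")))
    expect_identical(as.vector(truth_counts),
                     c(p$core, p$accessory, p$unique))
    expect_identical(unname(p$classes[sim$truth$family]),
                     sim$truth$class)
  }
})

test_that("generators are byte-identical under the same seed", {
  a <- gen_family_matrix(5, 10, 20, 0.5, 2, seed = 9)
  b <- gen_family_matrix(5, 10, 20, 0.5, 2, seed = 9)
  expect_identical(a, b)
  p1 <- gen_divergent_pair(5000, 0.05, 0.001, 4, seed = 3)
  p2 <- gen_divergent_pair(5000, 0.05, 0.001, 4, seed = 3)
  expect_identical(p1, p2)
  expect_identical(gen_protein_families(a$matrix, 0.1, seed = 2),
                   gen_protein_families(b$matrix, 0.1, seed = 2))
  expect_identical(gen_crt_annotation("III", seed = 7),
                   gen_crt_annotation("III", seed = 7))
  # and the generator leaves the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_family_matrix(3, 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("divergent pair: identity case, mutation-log accounting, errors", {
  p0 <- gen_divergent_pair(2000, sub_rate = 0, indel_rate = 0, seed = 1)
  expect_identical(p0$genome_a, p0$genome_b)
  expect_equal(p0$true_identity, 1.0)

  p <- gen_divergent_pair(20000, sub_rate = 0.03, indel_rate = 0, seed = 7)
  # at indel_rate = 0 the identity is exactly 1 - substituted_sites / L
  expect_equal(p$true_identity, 1 - length(p$log$sub_sites) / 20000)
  # and within binomial error of the nominal 0.97
  expect_lt(abs(p$true_identity - 0.97), 4 * sqrt(0.03 * 0.97 / 20000))

  expect_error(gen_divergent_pair(0, 0.01), "ancestor")
  expect_error(gen_divergent_pair(1000, sub_rate = 0.8), "saturation")
})

test_that("indels never overlap and the log reconstructs the derived length", {
  p <- gen_divergent_pair(30000, sub_rate = 0.02, indel_rate = 0.002,
                          indel_mean_len = 5, seed = 11)
  ind <- p$log$indels
  dels <- ind[ind$type == "del", ]
  if (nrow(dels) > 1) {
    d <- dels[order(dels$pos), ]
    expect_true(all(d$pos[-1] > (d$pos + d$len - 1)[-nrow(d)]))
  }
  expect_equal(nchar(p$genome_b),
               30000 - sum(dels$len) + sum(ind$len[ind$type == "ins"]))
  expect_equal(p$log$n_aligned, 30000 - sum(dels$len))
  # identity recomputable from the log
  subs_on_kept <- sum(!p$log$sub_sites %in%
                        unlist(mapply(seq, dels$pos, dels$pos + dels$len - 1,
                                      SIMPLIFY = FALSE)))
  expect_equal(p$true_identity,
               (p$log$n_aligned - subs_on_kept) / p$log$n_aligned)
})

test_that("protein families: zero divergence gives identical copies,
           independent families are dissimilar", {
  sim <- gen_family_matrix(4, core_size = 3, seed = 2)
  prot0 <- gen_protein_families(sim$matrix, aa_divergence = 0, seed = 5)
  for (f in unique(prot0$family)) {
    expect_length(unique(prot0$residues[prot0$family == f]), 1L)
  }
  # two independent ~100-residue families sit far below the 0.5 threshold
  reps <- vapply(split(prot0$residues, prot0$family), `[`, "", 1)
  for (i in seq_along(reps)) {
    for (j in seq_len(i - 1)) {
      expect_lt(global_identity(reps[i], reps[j]), 0.4)
    }
  }
  expect_warning(gen_protein_families(sim$matrix, aa_divergence = 0.6,
                                      seed = 1), "not guaranteed")
  expect_error(gen_protein_families(sim$matrix, 0.1, mean_len = 10), "mean_len")
})

test_that("crt annotation generator covers its rule table and rejects unknowns", {
  ann <- gen_crt_annotation("II", seed = 1)
  expect_true(all(c("crtB", "log", "crtI", "hyp", "crtY", "crtE", "crtG",
                    "DUF2141", "crtZ") %in% ann$name))
  expect_false("crtW" %in% ann$name)
  expect_true(all(ann$start <= ann$end))
  expect_error(gen_crt_annotation("V"), "known labels")
})
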