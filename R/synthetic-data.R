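#' Simulate a gene-family presence/absence matrix with known truth
#'
#' Generates the gene-content structure typical of a bacterial genus
#' pangenome: a conserved core present in every genome, a shared accessory
#' pool where each genome samples each family independently, and per-genome
#' unique genes drawn from an effectively infinite label space (Poisson
#' counts), so uniqueness holds by construction.
#'
#' The truth record reports each family's *realized* class (core when present
#' in all genomes, unique when present in exactly one, accessory otherwise),
#' which is the partition [partition_families()] recovers; the construction
#' origin (core pool, accessory pool, unique draw) is kept alongside since an
#' accessory-pool family can, by chance, land in all or exactly one genome.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param core_size families present in every genome.
#' @param accessory_pool_size size of the shared accessory pool.
#' @param p_accessory per-genome, per-pool-family inclusion probability.
#' @param unique_per_genome Poisson mean of unique families per genome.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A list with `matrix` (a [family_matrix()]) and `truth`
#'   (`data.frame` with columns `family`, `origin`, `class`).
#' @examples
#' sim <- gen_family_matrix(5, core_size = 10, accessory_pool_size = 20,
#'                          p_accessory = 0.4, unique_per_genome = 2, seed = 1)
#' table(sim$truth$class)
#' @export
gen_family_matrix <- function(n_genomes, core_size = 0,
                              accessory_pool_size = 0, p_accessory = 0,
                              unique_per_genome = 0, seed = 1) {
  if (!is_count(n_genomes) || n_genomes < 2) {
    stop("invalid model: `n_genomes` must be an integer >= 2")
  }
  stopifnot(is_count(core_size), is_count(accessory_pool_size),
            is_prob(p_accessory),
            is.numeric(unique_per_genome), unique_per_genome >= 0)
  with_rng(seed, {
    genomes <- sprintf("g%02d", seq_len(n_genomes))
    blocks <- list()
    origin <- character(0)
    if (core_size > 0) {
      m <- matrix(1L, core_size, n_genomes,
                  dimnames = list(sprintf("core%05d", seq_len(core_size)),
                                  genomes))
      blocks <- c(blocks, list(m))
      origin <- c(origin, rep("core_pool", core_size))
    }
    if (accessory_pool_size > 0) {
      m <- matrix(rbinom(accessory_pool_size * n_genomes, 1L, p_accessory),
                  accessory_pool_size, n_genomes,
                  dimnames = list(sprintf("acc%05d",
                                          seq_len(accessory_pool_size)),
                                  genomes))
      keep <- rowSums(m) > 0          # unobservable families do not exist
      m <- m[keep, , drop = FALSE]
      blocks <- c(blocks, list(m))
      origin <- c(origin, rep("accessory_pool", nrow(m)))
    }
    n_uni <- if (unique_per_genome > 0) rpois(n_genomes, unique_per_genome)
             else integer(n_genomes)
    if (sum(n_uni) > 0) {
      m <- matrix(0L, sum(n_uni), n_genomes,
                  dimnames = list(sprintf("uni%05d", seq_len(sum(n_uni))),
                                  genomes))
      m[cbind(seq_len(sum(n_uni)), rep(seq_len(n_genomes), n_uni))] <- 1L
      blocks <- c(blocks, list(m))
      origin <- c(origin, rep("unique_draw", nrow(m)))
    }
    if (length(blocks) == 0) stop("model generates no families")
    counts <- do.call(rbind, blocks)
    fm <- family_matrix(counts)
    rs <- rowSums(counts > 0)
    class <- ifelse(rs == n_genomes, "core",
                    ifelse(rs == 1L, "unique", "accessory"))
    truth <- data.frame(family = rownames(counts), origin = origin,
                        class = class, row.names = NULL)
    list(matrix = fm, truth = truth)
  })
}

#' Simulate a divergent genome pair with known identity
#'
#' Evolves a random ancestor by per-site substitutions (by default uniform
#' over the three alternative bases; a transition/transversion weight can be
#' set for K2P experiments) and optional non-overlapping indels with
#' geometric lengths.  The mutation log is returned so the true nucleotide
#' identity — matching sites over aligned (un-deleted) ancestor sites — is
#' known exactly, giving ANI and dDDH estimators a ground truth.
#'
#' @param ancestor_length ancestor length in bases.
#' @param sub_rate per-site substitution probability, in `[0, 0.75)`.
#' @param indel_rate per-site indel initiation probability.
#' @param indel_mean_len mean indel length (geometric).
#' @param kappa transition/transversion weight of the substitution draw;
#'   1 (default) is the uniform three-alternative model.
#' @param seed integer seed.
#' @return A list with `genome_a` (ancestor), `genome_b` (derived),
#'   `true_identity`, and `log` (substitution sites and applied indels, in
#'   ancestor coordinates).
#' @examples
#' p <- gen_divergent_pair(10000, sub_rate = 0.02, seed = 3)
#' p$true_identity
#' @export
gen_divergent_pair <- function(ancestor_length, sub_rate = 0,
                               indel_rate = 0, indel_mean_len = 3,
                               kappa = 1, seed = 1) {
  if (!is_count(ancestor_length) || ancestor_length < 1) {
    stop("empty or invalid ancestor: `ancestor_length` must be >= 1")
  }
  if (!is.numeric(sub_rate) || sub_rate < 0 || sub_rate >= 0.75) {
    stop("saturation: `sub_rate` must lie in [0, 0.75)")
  }
  stopifnot(is_prob(indel_rate), indel_mean_len >= 1, kappa > 0)
  with_rng(seed, {
    L <- as.integer(ancestor_length)
    anc <- sample(DNA_BASES, L, replace = TRUE)

    sub_sites <- which(runif(L) < sub_rate)
    der <- anc
    if (length(sub_sites) > 0) {
      der[sub_sites] <- vapply(anc[sub_sites], substitute_base, "",
                               kappa = kappa)
    }

    # indels: initiation sites without replacement, overlapping spans skipped
    indels <- data.frame(pos = integer(0), len = integer(0),
                         type = character(0))
    if (indel_rate > 0) {
      n_init <- rbinom(1L, L, indel_rate)
      cand <- sort(sample.int(L, min(n_init, L)))
      blocked_until <- 0L
      for (pos in cand) {
        if (pos <= blocked_until) next
        len <- 1L + rgeom(1L, 1 / indel_mean_len)
        type <- sample(c("del", "ins"), 1L)
        if (type == "del") {
          len <- min(len, L - pos + 1L)
          blocked_until <- pos + len - 1L
        } else {
          blocked_until <- pos
        }
        indels <- rbind(indels,
                        data.frame(pos = pos, len = len, type = type))
      }
    }

    deleted <- rep(FALSE, L)
    for (i in seq_len(nrow(indels))) {
      if (indels$type[i] == "del") {
        deleted[indels$pos[i]:(indels$pos[i] + indels$len[i] - 1L)] <- TRUE
      }
    }
    # assemble derived genome right-to-left so coordinates stay valid
    pieces <- der
    pieces[deleted] <- ""
    ins <- indels[indels$type == "ins", , drop = FALSE]
    ins_seq <- character(nrow(ins))
    for (i in seq_len(nrow(ins))) {
      ins_seq[i] <- random_dna(ins$len[i])
      pieces[ins$pos[i]] <- paste0(pieces[ins$pos[i]], ins_seq[i])
    }

    aligned <- !deleted
    matched <- aligned & !(seq_len(L) %in% sub_sites)
    true_identity <- if (sum(aligned) == 0) NA_real_ else
      sum(matched) / sum(aligned)

    list(genome_a = paste(anc, collapse = ""),
         genome_b = paste(pieces, collapse = ""),
         true_identity = true_identity,
         log = list(sub_sites = sub_sites, indels = indels,
                    inserted = ins_seq, n_aligned = sum(aligned)))
  })
}

# transition partner gets weight kappa, the two transversions weight 1 each
substitute_base <- function(base, kappa = 1) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")[[base]]
  alts <- setdiff(DNA_BASES, base)
  w <- ifelse(alts == transition, kappa, 1)
  sample(alts, 1L, prob = w / sum(w))
}

#' Simulate protein families consistent with a gene-content matrix
#'
#' Draws one random ancestral protein per family and hands each genome that
#' carries the family a copy mutated at a controlled per-residue divergence.
#' Families are mutually independent random sequences, so between-family
#' identity is far below any sensible clustering threshold while
#' within-family identity stays near `1 - aa_divergence` — the substrate for
#' clustering round-trip tests.
#'
#' @param fm a [family_matrix()] (presence defines who gets a copy; counts
#'   > 1 yield paralogous copies).
#' @param aa_divergence per-residue substitution probability, in `[0, 0.5]`
#'   (above 0.5 the round-trip with a 0.5 identity threshold is not
#'   guaranteed and a warning is raised).
#' @param mean_len mean protein length in residues (Poisson, floored at 30);
#'   the default matches the ~300-residue average of bacterial proteins.
#'   Note the identity between two family members is a per-site average, so
#'   short proteins widen its spread: at `mean_len = 300` the expected
#'   member-centroid identity at 0.2 divergence (~0.64) sits about five
#'   standard deviations above a 0.5 clustering threshold.
#' @param seed integer seed.
#' @return A `data.frame` of protein records (`genome_id`, `gene_id`,
#'   `residues`) with the generating family of each gene in column `family`.
#' @export
gen_protein_families <- function(fm, aa_divergence = 0.1, mean_len = 300,
                                 seed = 1) {
  fm <- as_family_matrix(fm)
  stopifnot(is.numeric(aa_divergence), aa_divergence >= 0,
            aa_divergence <= 1, mean_len >= 30)
  if (aa_divergence > 0.5) {
    warning("aa_divergence > 0.5: clustering round-trip at threshold 0.5 ",
            "is not guaranteed")
  }
  with_rng(seed, {
    fams <- rownames(fm$counts)
    genomes <- colnames(fm$counts)
    out <- vector("list", length(fams))
    for (f in seq_along(fams)) {
      len <- max(30L, rpois(1L, mean_len))
      anc <- sample(AA_RESIDUES, len, replace = TRUE)
      recs <- list()
      for (g in seq_along(genomes)) {
        n_copies <- fm$counts[f, g]
        for (cp in seq_len(n_copies)) {
          mut <- anc
          hit <- which(runif(len) < aa_divergence)
          if (length(hit) > 0) {
            mut[hit] <- vapply(anc[hit], function(r) {
              sample(setdiff(AA_RESIDUES, r), 1L)
            }, "")
          }
          recs[[length(recs) + 1L]] <- data.frame(
            genome_id = genomes[g],
            gene_id = sprintf("%s_%s_c%d", fams[f], genomes[g], cp),
            residues = paste(mut, collapse = ""),
            family = fams[f])
        }
      }
      out[[f]] <- do.call(rbind, recs)
    }
    do.call(rbind, out)
  })
}
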