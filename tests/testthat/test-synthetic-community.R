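test_that("generate_genome respects length, composition and determinism", {
  g <- generate_genome(10000, 0.5, seed = 1)
  expect_equal(nchar(g), 10000)
  expect_identical(g, generate_genome(10000, 0.5, seed = 1))

  pure_gc <- generate_genome(10000, 1.0, seed = 2)
  expect_true(grepl("^[GC]+$", pure_gc))
  pure_at <- generate_genome(1000, 0.0, seed = 2)
  expect_true(grepl("^[AT]+$", pure_at))

  # binomial bound: observed GC within 3 sd of the target at n = 50 kb
  g72 <- generate_genome(50000, 0.72, seed = 3)
  expect_lt(abs(gc_content(g72) / 100 - 0.72),
            3 * sqrt(0.72 * 0.28 / 50000))

  expect_error(generate_genome(0, 0.5), "positive")
  expect_error(generate_genome(100, 1.5), "0, 1")
})

test_that("evolve_variant plants the requested divergence", {
  g <- generate_genome(50000, 0.6, seed = 4)
  expect_identical(evolve_variant(g, 0, seed = 5), g)
  expect_identical(evolve_variant(g, 0.05, seed = 6),
                   evolve_variant(g, 0.05, seed = 6))

  v <- evolve_variant(g, 0.05, seed = 7)
  expect_equal(nchar(v), nchar(g))
  diff_frac <- mean(strsplit(g, "")[[1]] != strsplit(v, "")[[1]])
  expect_lt(abs(diff_frac - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))

  expect_error(evolve_variant(g, 1), "0, 1")

  # indel flag is off by default but changes length when enabled
  vi <- evolve_variant(substr(g, 1, 5000), 0, seed = 8, indel_rate = 0.02)
  expect_false(nchar(vi) == 5000 && vi == substr(g, 1, 5000))
})

test_that("plant_community produces consistent genomes, hits and truth", {
  comm <- small_community(seed = 11, n_clusters = 3, n_genomes = 3,
                          lengths = c(6000, 7000, 8000))
  expect_equal(nrow(comm$genomes), 10)                # 3 x 3 + 1 singleton
  expect_equal(length(unique(comm$truth$label)), 4)
  expect_setequal(comm$genomes$id, comm$truth$genome_id)
  expect_true(all(comm$domain_hits$genome_id %in% comm$genomes$id))
  expect_true(all(comm$domain_hits$evalue <= 0.001))
  expect_true(all(comm$truth$singleton == grepl("^S", comm$truth$label)))

  # disjoint pools when nothing is shared
  pools <- split(comm$domain_hits$domain_accession, comm$domain_hits$genome_id)
  lab <- setNames(comm$truth$label, comm$truth$genome_id)
  cluster_pools <- lapply(split(comm$domain_hits$domain_accession,
                                lab[comm$domain_hits$genome_id]), unique)
  for (i in seq_along(cluster_pools)) {
    for (j in seq_along(cluster_pools)) {
      if (i < j) {
        expect_length(intersect(cluster_pools[[i]], cluster_pools[[j]]), 0)
      }
    }
  }

  # byte-identical regeneration under the same spec + seed
  comm2 <- small_community(seed = 11, n_clusters = 3, n_genomes = 3,
                           lengths = c(6000, 7000, 8000))
  expect_identical(comm$genomes, comm2$genomes)
  expect_identical(comm$domain_hits, comm2$domain_hits)
})

test_that("community_spec validates its invariants", {
  expect_error(community_spec(clusters = tibble::tibble(
    n_genomes = 0, ancestor_length = 1000, gc_target = 0.5,
    within_cluster_substitution_rate = 0.1, domain_pool_size = 5,
    domains_per_genome = 3)), ">= 1 genome")
  expect_error(community_spec(clusters = tibble::tibble(
    n_genomes = 1, ancestor_length = 1000, gc_target = 0.5,
    within_cluster_substitution_rate = 0.1, domain_pool_size = 5,
    domains_per_genome = 8)), "domain_pool_size")
})

test_that("simulated read sets carry the termini-dependent signatures", {
  g <- generate_genome(40000, 0.6, seed = 21)
  L <- 40000

  # DTR: folded true-origin depth doubles over the repeat
  rs <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 1000),
                                target_depth = 30, seed = 22)
  d <- true_origin_depth(rs, L)
  ratio <- mean(d[1:1000]) / mean(d[1001:L])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  # conservation: total bases over virion length within 5% of target depth
  vl <- L + 1000
  expect_lt(abs(sum(nchar(rs$sequence)) / vl - 30) / 30, 0.05)

  # headful: the pac position is the unique global start-count maximum
  rs2 <- simulate_packaged_reads(
    g, termini_model("HEADFUL_PAC", pac_position = 5000),
    target_depth = 20, seed = 23)
  fwd_starts <- rs2$start[rs2$strand == "+"]
  tab <- table(fwd_starts)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 5000)
  expect_equal(sum(rs2$start == 5000 & rs2$strand == "+"),
               max(table(factor(rs2$start, levels = 0:(L - 1)))))

  # error-free reads are exact substrings of the (circularized) virion
  rs3 <- simulate_packaged_reads(g, termini_model("NONE"), target_depth = 2,
                                 read_length = 100, error_rate = 0,
                                 seed = 24)
  circ <- paste0(g, substr(g, 1, 99))
  fwd <- rs3$sequence
  fwd[rs3$strand == "-"] <- reverse_complement(fwd[rs3$strand == "-"])
  expect_true(all(vapply(fwd, function(s) grepl(s, circ, fixed = TRUE),
                         logical(1))))

  # read ids unique; identical seed reproduces the read set byte for byte
  expect_false(anyDuplicated(rs$read_id) > 0)
  rs_again <- simulate_packaged_reads(
    g, termini_model("DTR", repeat_length = 1000), target_depth = 30,
    seed = 22)
  expect_identical(tibble::as_tibble(rs), tibble::as_tibble(rs_again))

  expect_error(simulate_packaged_reads(
    g, termini_model("DTR", repeat_length = 25000), seed = 1),
    "half the genome")
})

test_that("FASTA/FASTQ round trips preserve simulated communities", {
  comm <- small_community(seed = 31, n_clusters = 2, lengths = c(4000, 5000))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(comm$genomes, fa)
  back <- read_fasta(fa)
  expect_identical(back$id, comm$genomes$id)
  expect_identical(back$sequence, comm$genomes$sequence)

  g <- comm$genomes$sequence[1]
  rs <- simulate_packaged_reads(g, termini_model("NONE"), target_depth = 3,
                                read_length = 80, seed = 32)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back_r <- read_fastq(fq)
  expect_identical(back_r$read_id, rs$read_id)
  expect_identical(back_r$sequence, rs$sequence)
})
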