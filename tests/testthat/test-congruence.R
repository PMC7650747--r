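test_that("adjusted_rand matches direct pair counting and mclust", {
  expect_equal(adjusted_rand(c(a = 1, b = 1, c = 2), c(a = "x", b = "x", c = "y")), 1)
  expect_equal(adjusted_rand(c(a = 1, b = 1, c = 1, d = 1),
                             c(a = 1, b = 2, c = 3, d = 4)), 0)

  # {AB|CD} vs {AC|BD}: brute-force over the 6 item pairs
  pa <- c(A = 1, B = 1, C = 2, D = 2)
  pb <- c(A = 1, B = 2, C = 1, D = 2)
  items <- names(pa)
  both <- 0; neither <- 0; only_a <- 0; only_b <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    sa <- pa[items[i]] == pa[items[j]]
    sb <- pb[items[i]] == pb[items[j]]
    both <- both + (sa && sb); neither <- neither + (!sa && !sb)
    only_a <- only_a + (sa && !sb); only_b <- only_b + (!sa && sb)
  }
  n_pairs <- 6
  expected <- (both + only_a) * (both + only_b) / n_pairs
  max_index <- ((both + only_a) + (both + only_b)) / 2
  brute <- (both - expected) / (max_index - expected)
  expect_equal(adjusted_rand(pa, pb), brute)

  # symmetry, relabeling invariance, and an external cross-check
  set.seed(111)
  for (rep in 1:5) {
    x <- setNames(sample(1:3, 12, replace = TRUE), letters[1:12])
    y <- setNames(sample(1:4, 12, replace = TRUE), letters[1:12])
    expect_equal(adjusted_rand(x, y), adjusted_rand(y, x))
    relab <- setNames(paste0("grp", x), names(x))
    expect_equal(adjusted_rand(x, y), adjusted_rand(relab, y))
    expect_equal(adjusted_rand(x, y),
                 mclust::adjustedRandIndex(x, y[names(x)]),
                 tolerance = 1e-12)
  }

  expect_error(adjusted_rand(c(a = 1, b = 2), c(a = 1, c = 2)), "different")
})

test_that("congruence summarises partition agreement", {
  cg <- congruence(c(a = 1, b = 1, c = 2), c(a = 2, b = 2, c = 9))
  expect_equal(cg$adjusted_rand, 1)
  expect_equal(cg$n_genomes, 3)
  expect_equal(cg$partition_a_k, 2)
  g <- glance(cg)
  expect_equal(g$adjusted_rand, 1)
})

test_that("cophenetic correlation is 1 for identical trees", {
  set.seed(112)
  m <- matrix(runif(40), nrow = 5, dimnames = list(paste0("g", 1:5), NULL))
  d <- as.matrix(dist(m))
  t1 <- agglomerate(d, "average")
  t2 <- agglomerate(d, "average")
  expect_equal(cophenetic_correlation(t1, t2), 1)
})

test_that("run_pipeline is deterministic and its report is complete", {
  spec <- community_spec(
    clusters = tibble::tibble(
      n_genomes = 2, ancestor_length = c(6000, 7000), gc_target = c(0.5, 0.65),
      within_cluster_substitution_rate = 0.02, domain_pool_size = 16,
      domains_per_genome = 10),
    n_singletons = 1, singleton_length = 6500, shared_domain_fraction = 0,
    seed = 113)
  cfg <- pipeline_config(community = spec, target_depth = 30, seed = 113)

  out1 <- file.path(tempdir(), "bundle_a")
  out2 <- file.path(tempdir(), "bundle_b")
  suppressMessages({
    rep1 <- run_pipeline(cfg, out_dir = out1)
    rep2 <- run_pipeline(cfg, out_dir = out2)
  })

  # byte-identical bundles under a fixed seed
  f1 <- sort(list.files(out1))
  f2 <- sort(list.files(out2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # completeness: one summary row per genome, both trees serialized
  expect_equal(nrow(rep1$summary), 5)
  expect_setequal(rep1$summary$id, spec_ids <- rep1$assignments$truth$genome_id)
  expect_true(file.exists(file.path(out1, "ani_tree.nwk")))
  expect_true(file.exists(file.path(out1, "domain_tree.nwk")))
  expect_match(readLines(file.path(out1, "ani_tree.nwk")), ";$")

  # planted structure fully recovered on this small community
  expect_true(all(rep1$congruence$adjusted_rand == 1))
  expect_gte(rep1$mapped_fraction, 0.8)

  # provenance echoes every threshold and the seed
  expect_true(all(c("seed", "ratio_threshold", "ani_fragment_size") %in%
                    rep1$provenance$key))
  expect_equal(rep1$provenance$value[rep1$provenance$key == "seed"], "113")

  g <- glance(rep1)
  expect_equal(g$termini_accuracy, 1)
  expect_equal(g$ari_ani_vs_domain, 1)

  unlink(c(out1, out2), recursive = TRUE)
})

test_that("tidiers expose matrices, profiles and calls as tibbles", {
  comm <- small_community(seed = 114, n_clusters = 2, lengths = c(4000, 4500))
  am <- ani_matrix(comm$genomes)
  td <- tidy(am)
  expect_true(all(c("id_a", "id_b", "ani") %in% names(td)))
  n <- nrow(am)
  expect_equal(nrow(td), n * (n + 1) / 2)
  expect_true(all(td$ani[td$id_a == td$id_b] == 100))

  g <- comm$genomes$sequence[1]
  rs <- simulate_packaged_reads(g, termini_model("NONE"), target_depth = 3,
                                seed = 115)
  prof <- build_coverage(map_reads(rs, g))
  tp <- tidy(prof)
  expect_equal(nrow(tp), nchar(g))
  expect_equal(sum(tp$starts_fwd) + sum(tp$starts_rev), prof$n_reads_mapped)
  gl <- glance(prof)
  expect_equal(gl$n_reads_total, nrow(rs))

  call <- classify_termini(prof)
  tc <- tidy(call)
  expect_equal(tc$termini_class, "UNDETERMINED")

  dd <- ward_dendrogram(build_pa_matrix(comm$domain_hits,
                                        genome_ids = comm$genomes$id))
  tdd <- tidy(dd)
  expect_equal(nrow(tdd), nrow(comm$genomes) - 1)

  expect_s3_class(ggplot2::autoplot(am), "ggplot")
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  expect_s3_class(ggplot2::autoplot(dd), "ggplot")
})
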