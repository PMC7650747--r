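test_that("parse_domain_hits applies the inclusive e-value cutoff", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\tprotein_id\tdomain_accession\tdomain_name\tevalue\tbitscore",
    "gA\tp1\tPF00001\td1\t1e-5\t120",
    "gA\tp2\tPF00002\td2\t0.01\t60",
    "gB\tp3\tPF00003\td3\t0.0005\t80"), tsv)
  hits <- parse_domain_hits(tsv, evalue_cutoff = 0.001)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$domain_accession, c("PF00001", "PF00003"))

  # boundary semantics: the cutoff itself is kept, and cutoff 0 keeps only
  # exact-zero e-values
  df <- hit_tbl(c("g1", "g1", "g1"), c("PF1", "PF2", "PF3"),
                evalue = c(0.001, 0.0011, 0))
  expect_setequal(parse_domain_hits(df, 0.001)$domain_accession,
                  c("PF1", "PF3"))
  expect_equal(parse_domain_hits(df, 0)$domain_accession, "PF3")

  # empty table -> empty hit list
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(parse_domain_hits(empty)), 0)

  # headerless file with positional columns
  nohead <- tempfile(fileext = ".tsv")
  writeLines("gC\tp9\tPF00009\td9\t1e-8\t55", nohead)
  h2 <- parse_domain_hits(nohead)
  expect_equal(h2$genome_id, "gC")
  expect_equal(h2$evalue, 1e-8)

  # unparseable e-value -> row rejected with a warning
  badev <- tempfile(fileext = ".tsv")
  writeLines(c("gC\tp1\tPF1\td\tnot_a_number\t10",
               "gC\tp2\tPF2\td\t1e-9\t10"), badev)
  expect_warning(h3 <- parse_domain_hits(badev), "unparseable")
  expect_equal(h3$domain_accession, "PF2")

  # custom column mapping for a different dialect
  dialect <- tempfile(fileext = ".tsv")
  writeLines(c("acc\teval\tgenome\tprot",
               "PF77\t1e-4\tgZ\tp1"), dialect)
  h4 <- parse_domain_hits(dialect, col_map = c(genome_id = "genome",
                                               protein_id = "prot",
                                               domain_accession = "acc",
                                               evalue = "eval"))
  expect_equal(h4$genome_id, "gZ")
  expect_equal(h4$domain_accession, "PF77")
})

test_that("build_pa_matrix encodes presence semantics", {
  hits <- hit_tbl(c("A", "A", "B", "B"), c("d1", "d2", "d2", "d3"))
  m <- build_pa_matrix(hits, pfam_only = FALSE)
  expect_equal(rownames(m), c("A", "B"))
  expect_equal(colnames(m), c("d1", "d2", "d3"))
  expect_equal(unname(unclass(m)), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))

  # duplicate hits (same genome, same domain, different proteins) collapse
  dup <- dplyr::bind_rows(hits, hit_tbl("A", "d1", protein_id = "other"))
  expect_identical(unclass(build_pa_matrix(dup, pfam_only = FALSE)),
                   unclass(m))
  # idempotent under full duplication of the input rows
  expect_identical(unclass(build_pa_matrix(dplyr::bind_rows(hits, hits),
                                           pfam_only = FALSE)),
                   unclass(m))

  # zero-hit genomes are kept as all-zero rows; no all-zero columns exist
  m2 <- build_pa_matrix(hits, genome_ids = c("A", "B", "C"),
                        pfam_only = FALSE)
  expect_equal(unname(unclass(m2)["C", ]), rep(0L, 3))
  expect_true(all(colSums(m2) > 0))

  # the Pfam filter drops other accession namespaces by default
  mixed <- hit_tbl(c("A", "A"), c("PF00001", "COG0001"))
  expect_equal(colnames(build_pa_matrix(mixed)), "PF00001")

  # planted community: columns equal the union of the planted pools
  comm <- small_community(seed = 101, n_clusters = 2, lengths = c(4000, 4500))
  pa <- build_pa_matrix(comm$domain_hits, genome_ids = comm$genomes$id)
  expect_setequal(colnames(pa), unique(comm$domain_hits$domain_accession))
})

test_that("cut_and_flag recovers planted clusters and flags singletons", {
  comm <- small_community(seed = 102, n_clusters = 3, n_genomes = 3,
                          lengths = c(4000, 4500, 5000))
  pa <- build_pa_matrix(comm$domain_hits, genome_ids = comm$genomes$id)
  dd <- ward_dendrogram(pa)
  cf <- cut_and_flag(dd, pa, k = 4)
  expect_equal(adjusted_rand(cf, comm$truth), 1)
  expect_equal(cf$genome_id[cf$singleton],
               comm$truth$genome_id[comm$truth$singleton])

  # k == n: every genome its own cluster
  all_single <- cut_and_flag(dd, pa, k = nrow(pa))
  expect_equal(length(unique(all_single$label)), nrow(pa))

  expect_error(cut_and_flag(dd, pa, k = nrow(pa) + 1), "exceed")
  expect_error(cut_and_flag(dd, pa), "exactly one")
  expect_error(cut_and_flag(dd, pa, k = 2, h = 1), "exactly one")

  # a genome sharing nothing with anyone is a singleton regardless of cut
  hits <- dplyr::bind_rows(
    hit_tbl(rep("g1", 4), paste0("PF0000", 1:4)),
    hit_tbl(rep("g2", 4), paste0("PF0000", 1:4)),
    hit_tbl(rep("g3", 4), paste0("PF0000", 5:8)),
    hit_tbl(rep("g4", 4), paste0("PF0000", 5:8)),
    hit_tbl(rep("lone", 4), paste0("PF0009", 1:4)))
  pa2 <- build_pa_matrix(hits)
  cf2 <- cut_and_flag(ward_dendrogram(pa2), pa2, k = 2)
  expect_true(cf2$singleton[cf2$genome_id == "lone"])
  expect_equal(cf2$label[cf2$genome_id == "lone"], "singleton_lone")
  expect_false(any(cf2$singleton[cf2$genome_id != "lone"]))
})

test_that("ward heights degrade gracefully as pools overlap", {
  # recovery is perfect with disjoint pools and no better with full sharing
  ari_for <- function(shared) {
    comm <- small_community(seed = 103, n_clusters = 3, n_genomes = 3,
                            lengths = c(4000, 4200, 4400), shared = shared)
    pa <- build_pa_matrix(comm$domain_hits, genome_ids = comm$genomes$id)
    cf <- cut_and_flag(ward_dendrogram(pa), pa,
                       k = length(unique(comm$truth$label)))
    adjusted_rand(cf, comm$truth)
  }
  a0 <- ari_for(0)
  a1 <- ari_for(1)
  expect_equal(a0, 1)
  expect_lte(a1, a0)
})

test_that("lifestyle_flags is a case-insensitive marker rule", {
  hits <- hit_tbl(c("tempA", "tempA", "lytB"),
                  c("pf00589", "PF00078", "PF00078"))
  flags <- lifestyle_flags(hits)
  expect_equal(flags$lifestyle_flag[flags$genome_id == "tempA"],
               "temperate-evidence")
  expect_equal(flags$lifestyle_flag[flags$genome_id == "lytB"],
               "no-temperate-evidence")

  # mixed-case input yields identical flags
  hits_uc <- hits
  hits_uc$domain_accession <- toupper(hits_uc$domain_accession)
  expect_identical(lifestyle_flags(hits_uc), flags)

  # empty hit list -> no evidence for the supplied genomes
  none <- lifestyle_flags(hit_tbl(character(), character()),
                          genome_ids = "gX")
  expect_equal(none$lifestyle_flag, "no-temperate-evidence")

  expect_error(lifestyle_flags(hits, marker_accessions = character()),
               "non-empty")

  markers <- temperate_markers()
  expect_true(all(grepl("^PF", markers$accession)))
  expect_true("PF00589" %in% markers$accession)
})
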