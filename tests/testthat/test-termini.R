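test_that("error-free reads map perfectly at their true folded origins", {
  g <- generate_genome(20000, 0.6, seed = 51)
  rs <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 800),
                                target_depth = 5, error_rate = 0, seed = 52)
  aln <- map_reads(rs, g)
  expect_true(all(aln$mapped))
  expect_true(all(aln$identity == 1))
  expect_equal(aln$start, rs$start)
  expect_equal(aln$strand, rs$strand)
})

test_that("unrelated reads stay unmapped and seeds are validated", {
  g <- generate_genome(20000, 0.6, seed = 53)
  junk <- generate_genome(150, 0.6, seed = 54)
  aln <- map_reads(junk, g)
  expect_false(aln$mapped[1])
  expect_error(map_reads(junk, g, seed_kmer = 9), ">= 11")
  expect_error(map_reads(strrep("A", 30000), g), "shorter than a read")
})

test_that("noisy reads still reach the expected mapping rate", {
  g <- generate_genome(30000, 0.6, seed = 55)
  rs <- simulate_packaged_reads(g, termini_model("NONE"), target_depth = 10,
                                error_rate = 0.01, seed = 56)
  aln <- map_reads(rs, g, seed_kmer = 15)
  expect_gte(mean(aln$mapped), 0.8)
})

test_that("build_coverage accounts for every aligned base and start", {
  aln <- tibble::tibble(read_id = "r1", start = 0L, end = 150L,
                        strand = "+", identity = 1, mapped = TRUE)
  prof <- build_coverage(aln, genome_length = 1000)
  expect_equal(prof$depth[1:150], rep(1L, 150))
  expect_equal(sum(prof$depth), 150)
  expect_equal(prof$starts_fwd[1], 1L)
  expect_equal(sum(prof$starts_fwd) + sum(prof$starts_rev), 1L)

  empty <- build_coverage(aln[0, ], genome_length = 1000)
  expect_true(all(empty$depth == 0))

  # recount oracle on a simulated set, including wrapping alignments
  g <- generate_genome(8000, 0.6, seed = 57)
  rs <- simulate_packaged_reads(g, termini_model("HEADFUL_PAC",
                                                 pac_position = 2000),
                                target_depth = 8, error_rate = 0, seed = 58)
  a2 <- map_reads(rs, g)
  p2 <- build_coverage(a2)
  expect_equal(sum(p2$depth), sum(a2$end[a2$mapped] - a2$start[a2$mapped]))
  expect_equal(sum(p2$starts_fwd) + sum(p2$starts_rev), p2$n_reads_mapped)
  expect_equal(p2$depth, as.integer(true_origin_depth(rs, 8000)))

  bad <- tibble::tibble(read_id = "r", start = 2000L, end = 2150L,
                        strand = "+", identity = 1, mapped = TRUE)
  expect_error(build_coverage(bad, genome_length = 1000), "outside")
})

test_that("detect_dtr handles forced and degenerate profiles", {
  flat <- structure(list(depth = rep(20L, 5000), starts_fwd = integer(5000),
                         starts_rev = integer(5000), n_reads_total = 1000L,
                         n_reads_mapped = 1000L, genome_length = 5000L),
                    class = "coverage_profile")
  expect_null(detect_dtr(flat))

  elevated <- flat
  elevated$depth[1001:2200] <- 40L
  d <- detect_dtr(elevated)
  expect_equal(d$start, 1000)
  expect_equal(d$end, 2200)
  expect_equal(d$ratio, 2)

  zero <- flat
  zero$depth <- integer(5000)
  expect_warning(expect_null(detect_dtr(zero)), "all-zero")

  expect_error(detect_dtr(flat, ratio_threshold = 1), "exceed 1")
})

test_that("detect_pac finds forced outliers and respects DTR exclusivity", {
  L <- 20000
  prof <- structure(list(depth = rep(10L, L),
                         starts_fwd = as.integer(rpois(L, 2)),
                         starts_rev = as.integer(rpois(L, 2)),
                         n_reads_total = 10000L, n_reads_mapped = 10000L,
                         genome_length = L), class = "coverage_profile")
  expect_null(detect_pac(prof))

  spiked <- prof
  spiked$starts_fwd[5001] <- 500L
  p <- detect_pac(spiked)
  expect_equal(p$position, 5000)
  expect_equal(p$strand, "+")
  expect_null(detect_pac(spiked, dtr = list(start = 0, end = 100)))
})

test_that("classify_termini maps architectures to the right labels", {
  g <- generate_genome(40000, 0.62, seed = 61)

  rs <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 1000),
                                target_depth = 25, seed = 62)
  call <- classify_termini(build_coverage(map_reads(rs, g)))
  expect_equal(call$klass, "DTR_SHORT")
  expect_null(call$pac_position)
  expect_true(call$evidence[["coverage_ratio"]] > 1.6)

  rs <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 12000),
                                target_depth = 25, seed = 63)
  call <- classify_termini(build_coverage(map_reads(rs, g)))
  expect_equal(call$klass, "DTR_LONG")

  rs <- simulate_packaged_reads(
    g, termini_model("HEADFUL_PAC", pac_position = 23456),
    target_depth = 25, seed = 64)
  call <- classify_termini(build_coverage(map_reads(rs, g)))
  expect_equal(call$klass, "HEADFUL_PAC")
  expect_equal(call$pac_position, 23456)
  expect_null(call$dtr_interval)

  # a DTR call and a pac call never coexist
  expect_true(is.null(call$dtr_interval) || is.null(call$pac_position))

  # too few mapped reads -> UNDETERMINED regardless of signal
  thin <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 1000),
                                  target_depth = 1, seed = 65)
  call <- classify_termini(build_coverage(map_reads(thin, g)),
                           min_mapped_reads = 1000)
  expect_equal(call$klass, "UNDETERMINED")
})

test_that("bedgraph and SAM exports are well-formed", {
  g <- generate_genome(5000, 0.6, seed = 66)
  rs <- simulate_packaged_reads(g, termini_model("NONE"), target_depth = 3,
                                seed = 67)
  aln <- map_reads(rs, g)
  prof <- build_coverage(aln)

  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(prof, bg, chrom = "phi")
  lines <- read.table(bg, sep = "\t")
  expect_equal(sum((lines$V3 - lines$V2) * lines$V4), sum(prof$depth))
  expect_equal(lines$V2[1], 0)
  expect_equal(lines$V3[nrow(lines)], 5000)

  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam, reads = rs, genome_id = "phi")
  sl <- readLines(sam)
  expect_match(sl[2], "SN:phi\tLN:5000")
  body <- strsplit(sl[-(1:2)], "\t")
  expect_equal(length(body), nrow(aln))
  expect_true(all(vapply(body, length, integer(1)) == 11))
})
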