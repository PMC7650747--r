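# normalise partition inputs: cluster_assignment tibble, tibble with
# genome_id + label/cluster, or a named vector
as_partition <- function(x) {
  if (is.data.frame(x)) {
    lab_col <- intersect(c("label", "cluster"), names(x))[1]
    if (is.na(lab_col) || !"genome_id" %in% names(x)) {
      stop("partition needs `genome_id` and `label`/`cluster` columns",
           call. = FALSE)
    }
    stats::setNames(as.character(x[[lab_col]]), x$genome_id)
  } else if (!is.null(names(x))) {
    stats::setNames(as.character(x), names(x))
  } else {
    stop("partition must be a labelled tibble or a named vector", call. = FALSE)
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the pair-count contingency table. 1 iff
#' the partitions are identical up to relabeling; 0 in expectation for
#' independent partitions. Symmetric and invariant under label renaming.
#'
#' @param labels_a,labels_b Partitions over the same genomes: a
#'   `cluster_assignment`, any tibble with `genome_id` and `label`/`cluster`
#'   columns, or a named vector of labels.
#' @return A single number in `[-1, 1]`.
#' @examples
#' adjusted_rand(c(a = 1, b = 1, c = 2), c(a = "x", b = "x", c = "y"))
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  a <- as_partition(labels_a)
  b <- as_partition(labels_b)
  if (!setequal(names(a), names(b))) {
    stop("partitions cover different genome id sets", call. = FALSE)
  }
  b <- b[names(a)]
  n <- length(a)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation of the cophenetic distances over the shared leaves; a
#' tree-level companion to the partition-level [adjusted_rand()].
#'
#' @param dend_a,dend_b `phage_dendrogram` objects over the same leaves.
#' @return A single correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(dend_a, dend_b) {
  ca <- as.matrix(stats::cophenetic(stats::as.hclust(dend_a)))
  cb <- as.matrix(stats::cophenetic(stats::as.hclust(dend_b)))
  shared <- intersect(rownames(ca), rownames(cb))
  if (length(shared) < 3L) stop("need at least 3 shared leaves", call. = FALSE)
  ua <- ca[shared, shared][upper.tri(diag(length(shared)))]
  ub <- cb[shared, shared][upper.tri(diag(length(shared)))]
  stats::cor(ua, ub)
}

#' Congruence between two classifications
#'
#' @param labels_a,labels_b Partitions (see [adjusted_rand()]).
#' @return A `congruence_result` list with `adjusted_rand`, `n_genomes`,
#'   `partition_a_k`, `partition_b_k`.
#' @export
congruence <- function(labels_a, labels_b) {
  a <- as_partition(labels_a)
  b <- as_partition(labels_b)
  structure(list(adjusted_rand = adjusted_rand(a, b),
                 n_genomes = length(a),
                 partition_a_k = length(unique(a)),
                 partition_b_k = length(unique(unname(b)))),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("<congruence_result> ARI %.3f over %d genomes (%d vs %d groups)\n",
              x$adjusted_rand, x$n_genomes, x$partition_a_k, x$partition_b_k))
  invisible(x)
}

#' Configure the end-to-end characterization pipeline
#'
#' @param community A [community_spec()]; defaults to the package's
#'   study-like community (three clusters plus a singleton).
#' @param target_depth,read_length,error_rate Read-simulation parameters
#'   (defaults 30x, 150 bp, 0.5%).
#' @param termini_models Optional list mapping truth labels (`"C1"`, `"S1"`,
#'   ...) to [termini_model()]s. By default clusters cycle through
#'   Headful(pac), Headful(pac), DTR 12 kb and singletons get a 1 kb DTR,
#'   mirroring the architectures reported for small actinophage panels.
#' @param ani An [ani_config()].
#' @param cut_k Number of clusters for both tree cuts; defaults to the
#'   number of truth groups (the synthetic benchmark setting).
#' @param singleton_min_shared Passed to [cut_and_flag()].
#' @param ratio_threshold,min_repeat_bp,long_dtr_threshold_bp,peak_factor
#'   Termini-caller thresholds (see [classify_termini()]).
#' @param seed Root seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(community = community_spec(),
                            target_depth = 30, read_length = 150,
                            error_rate = 0.005, termini_models = NULL,
                            ani = ani_config(), cut_k = NULL,
                            singleton_min_shared = 3, ratio_threshold = 1.6,
                            min_repeat_bp = 200, long_dtr_threshold_bp = 2000,
                            peak_factor = 5, seed = 1) {
  structure(list(community = community, target_depth = target_depth,
                 read_length = read_length, error_rate = error_rate,
                 termini_models = termini_models, ani = ani, cut_k = cut_k,
                 singleton_min_shared = singleton_min_shared,
                 ratio_threshold = ratio_threshold,
                 min_repeat_bp = min_repeat_bp,
                 long_dtr_threshold_bp = long_dtr_threshold_bp,
                 peak_factor = peak_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

# default per-truth-label termini models (cycled over clusters)
default_termini_models <- function(truth, genomes) {
  labels <- unique(truth$label)
  cluster_labels <- labels[!labels %in% truth$label[truth$singleton]]
  archetypes <- list(
    function(L) termini_model("HEADFUL_PAC", pac_position = round(L * 0.3)),
    function(L) termini_model("HEADFUL_PAC", pac_position = round(L * 0.3)),
    function(L) termini_model("DTR", repeat_length = min(12000L, floor(L / 3)))
  )
  out <- list()
  for (i in seq_along(cluster_labels)) {
    lab <- cluster_labels[i]
    L <- min(genomes$length_bp[genomes$truth_label == lab])
    out[[lab]] <- archetypes[[(i - 1L) %% length(archetypes) + 1L]](L)
  }
  for (lab in setdiff(labels, cluster_labels)) {
    L <- min(genomes$length_bp[genomes$truth_label == lab])
    out[[lab]] <- termini_model("DTR", repeat_length = min(1000L, floor(L / 3)))
  }
  out
}

pipeline_stage <- function(stage, code) {
  t0 <- Sys.time()
  message(sprintf("[%s] ...", stage))
  res <- tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full synthetic characterization pipeline
#'
#' Generates (or ingests) a phage community, simulates and maps reads per
#' genome, classifies termini, computes the ANIb matrix and tree, builds the
#' domain presence-absence matrix and Ward tree, cuts both trees, flags
#' singletons and lifestyle evidence, and scores all pairwise congruences.
#' Fully deterministic under a fixed seed; with `out_dir` set, all artifacts
#' are written as plain-text files and any partial output is removed if a
#' stage fails.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report bundle.
#' @param community Optional pre-built `phage_community` (e.g. real data
#'   assembled into the same shape); defaults to planting
#'   `config$community`.
#' @return A `phage_report` list: `summary` (report table), `termini`,
#'   `ani`, `ani_tree`, `pa_matrix`, `domain_tree`, `assignments` (list of
#'   partitions incl. truth), `congruence` (tibble of pairwise ARIs),
#'   `mapped_fraction`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         community = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  comm <- pipeline_stage("community", {
    if (is.null(community)) plant_community(config$community) else community
  })
  genomes <- comm$genomes
  models <- config$termini_models
  if (is.null(models)) models <- default_termini_models(comm$truth, genomes)

  termini <- pipeline_stage("termini", {
    purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
      g <- genomes[i, ]
      model <- models[[g$truth_label]]
      rs <- simulate_packaged_reads(
        g$sequence, model, target_depth = config$target_depth,
        read_length = config$read_length, error_rate = config$error_rate,
        seed = derive_seed(seed, 7000L + i))
      aln <- map_reads(rs, g$sequence)
      prof <- build_coverage(aln)
      call <- classify_termini(
        prof, ratio_threshold = config$ratio_threshold,
        min_repeat_bp = config$min_repeat_bp,
        long_dtr_threshold_bp = config$long_dtr_threshold_bp,
        peak_factor = config$peak_factor)
      tibble::tibble(
        id = g$id, true_model = model$kind, termini_class = call$klass,
        dtr_length = if (is.null(call$dtr_interval)) NA_integer_ else
          as.integer(call$dtr_interval[["end"]] - call$dtr_interval[["start"]]),
        pac_position = if (is.null(call$pac_position)) NA_integer_ else
          call$pac_position,
        n_reads = prof$n_reads_total, mapped_fraction =
          prof$n_reads_mapped / prof$n_reads_total)
    })
  })

  ani <- pipeline_stage("ani", ani_matrix(genomes, config$ani))
  ani_tree <- pipeline_stage("ani_tree", cluster_ani(ani))

  pa <- pipeline_stage("domains",
                       build_pa_matrix(comm$domain_hits,
                                       genome_ids = genomes$id))
  domain_tree <- pipeline_stage("domain_tree", ward_dendrogram(pa))

  k <- config$cut_k
  if (is.null(k)) k <- length(unique(comm$truth$label))
  assignments <- pipeline_stage("partitions", {
    domain_part <- cut_and_flag(domain_tree, pa, k = k,
                                singleton_min_shared = config$singleton_min_shared)
    ani_part <- cut_dendrogram(ani_tree, k = k)
    list(domain = domain_part, ani = ani_part, truth = comm$truth)
  })

  congr <- pipeline_stage("congruence", {
    tibble::tibble(
      comparison = c("ani_vs_truth", "domain_vs_truth", "ani_vs_domain"),
      adjusted_rand = c(
        adjusted_rand(assignments$ani, assignments$truth),
        adjusted_rand(assignments$domain, assignments$truth),
        adjusted_rand(assignments$ani, assignments$domain))
    )
  })

  flags <- lifestyle_flags(comm$domain_hits, genome_ids = genomes$id)
  summary <- pipeline_stage("summary", {
    recs <- dplyr::left_join(genomes, termini[, c("id", "termini_class")],
                             by = "id")
    recs$termini_class <- vapply(recs$termini_class, termini_label, character(1))
    recs <- dplyr::left_join(recs, flags, by = c(id = "genome_id"))
    summary_table(recs)
  })

  provenance <- tibble::tibble(
    key = c("seed", "target_depth", "read_length", "error_rate", "cut_k",
            "ratio_threshold", "min_repeat_bp", "long_dtr_threshold_bp",
            "peak_factor", "ani_fragment_size", "ani_min_identity",
            "ani_min_aligned_fraction", "singleton_min_shared"),
    value = as.character(c(seed, config$target_depth, config$read_length,
                           config$error_rate, k, config$ratio_threshold,
                           config$min_repeat_bp, config$long_dtr_threshold_bp,
                           config$peak_factor, config$ani$fragment_size,
                           config$ani$min_fragment_identity,
                           config$ani$min_fragment_aligned_fraction,
                           config$singleton_min_shared))
  )

  report <- structure(
    list(summary = summary, termini = termini, ani = ani,
         ani_tree = ani_tree, pa_matrix = pa, domain_tree = domain_tree,
         assignments = assignments, congruence = congr,
         mapped_fraction = mean(termini$mapped_fraction),
         provenance = provenance, config = config),
    class = "phage_report")

  if (!is.null(out_dir)) {
    pipeline_stage("write", write_report(report, out_dir, comm))
  }
  report
}

# write the report bundle as deterministic plain-text files
write_report <- function(report, out_dir, community) {
  fresh <- !dir.exists(out_dir)
  if (fresh) dir.create(out_dir, recursive = TRUE)
  written <- character()
  put <- function(fun, obj, file, ...) {
    path <- file.path(out_dir, file)
    fun(obj, path, ...)
    written <<- c(written, path)
    path
  }
  tryCatch({
    put(write_fasta, community$genomes, "genomes.fasta")
    put(readr::write_tsv, community$truth, "truth.tsv")
    put(readr::write_tsv, community$domain_hits, "domain_hits.tsv")
    put(readr::write_tsv, report$summary, "summary.tsv")
    put(readr::write_tsv, report$termini, "termini.tsv")
    put(write_ani_tsv, report$ani, "ani_matrix.tsv")
    put(function(x, p) writeLines(to_newick(x), p), report$ani_tree,
        "ani_tree.nwk")
    put(function(x, p) readr::write_tsv(
      tibble::as_tibble(unclass(x), rownames = "genome_id"), p),
      report$pa_matrix, "pa_matrix.tsv")
    put(function(x, p) writeLines(to_newick(x), p), report$domain_tree,
        "domain_tree.nwk")
    put(readr::write_tsv, report$assignments$domain, "domain_clusters.tsv")
    put(readr::write_tsv, report$assignments$ani, "ani_clusters.tsv")
    put(readr::write_tsv, report$congruence, "congruence.tsv")
    put(readr::write_tsv, report$provenance, "provenance.tsv")
  }, error = function(e) {
    unlink(written)
    if (fresh) unlink(out_dir, recursive = TRUE)
    stop("pipeline stage 'write' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(out_dir)
}

#' @export
print.phage_report <- function(x, ...) {
  cat("<phage_report>", nrow(x$summary), "genomes\n\n")
  print(x$summary)
  cat("\nCongruence (adjusted Rand):\n")
  print(x$congruence)
  invisible(x)
}
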