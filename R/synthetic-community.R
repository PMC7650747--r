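#' Generate a random phage-like genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_target / 2` and
#' `P(A) = P(T) = (1 - gc_target) / 2`, which gives genomes whose GC content
#' concentrates around `gc_target` with binomial fluctuations.
#'
#' @param length Genome length in bp (positive integer).
#' @param gc_target Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; identical inputs and seed give a
#'   byte-identical sequence.
#' @return A single character string of length `length`.
#' @examples
#' g <- generate_genome(1000, 0.65, seed = 1)
#' gc_content(g)
#' @export
generate_genome <- function(length, gc_target, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 1) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(gc_target) || gc_target < 0 || gc_target > 1) {
    stop("`gc_target` must lie in [0, 1]", call. = FALSE)
  }
  length <- as.integer(length)
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs[DNA_BASES]),
          collapse = "")
  })
}

#' Evolve a sequence by independent substitutions
#'
#' Each base is independently replaced, with probability `substitution_rate`,
#' by a uniformly chosen *different* base. Because no indels are introduced by
#' default, the planted divergence maps analytically onto expected nucleotide
#' identity (`ANI ~ 100 * (1 - p)` against the parent). A simple indel model is
#' available behind `indel_rate` but is off by default.
#'
#' @param parent Parent DNA sequence (single string).
#' @param substitution_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param indel_rate Per-base probability of a 1-bp indel (half insertions,
#'   half deletions). Default 0; when non-zero the output length may differ
#'   from the parent.
#' @return The evolved sequence as a single string.
#' @examples
#' v <- evolve_variant(generate_genome(500, 0.5, seed = 1), 0.05, seed = 2)
#' @export
evolve_variant <- function(parent, substitution_rate, seed = NULL, indel_rate = 0) {
  parent <- clean_dna(parent, "parent")
  if (length(parent) != 1L) stop("`parent` must be a single sequence", call. = FALSE)
  if (!is.numeric(substitution_rate) || substitution_rate < 0 || substitution_rate >= 1) {
    stop("`substitution_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (indel_rate < 0 || indel_rate >= 1) {
    stop("`indel_rate` must lie in [0, 1)", call. = FALSE)
  }
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  n <- length(chars)
  with_seed(seed, {
    if (substitution_rate > 0) {
      idx <- which(stats::runif(n) < substitution_rate)
      if (length(idx)) {
        cur <- match(chars[idx], DNA_BASES)
        shift <- sample.int(3L, length(idx), replace = TRUE)
        chars[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    if (indel_rate > 0) {
      u <- stats::runif(n)
      del <- u < indel_rate / 2
      ins <- u >= indel_rate / 2 & u < indel_rate
      ins_base <- character(n)
      ins_base[ins] <- sample(DNA_BASES, sum(ins), replace = TRUE)
      keep <- ifelse(del, "", chars)
      chars <- strsplit(paste0(paste0(keep, ifelse(ins, ins_base, "")),
                               collapse = ""), "", fixed = TRUE)[[1]]
    }
    paste(chars, collapse = "")
  })
}

#' Describe a virion termini / packaging architecture
#'
#' @param kind One of `"DTR"` (direct terminal repeat), `"HEADFUL_PAC"`
#'   (headful packaging from a fixed pac site) or `"NONE"` (no termini
#'   structure; uniform circular read starts, used as a negative control).
#' @param repeat_length Repeat length in bp (DTR only); must be shorter than
#'   half the genome.
#' @param pac_position 0-based pac position on the unit genome (headful only).
#' @param terminal_redundancy Headful terminal redundancy in bp. Recorded for
#'   provenance; the read-level simulation draws read starts directly, so this
#'   field does not change the simulated profiles.
#' @param pac_start_fraction Fraction of simulated reads whose 5' end sits
#'   exactly at `pac_position` on the packaging strand (fixed-first-end
#'   fraction, default 0.5); the remainder start uniformly on the circle.
#' @return A `termini_model` list.
#' @examples
#' termini_model("DTR", repeat_length = 1000)
#' termini_model("HEADFUL_PAC", pac_position = 5000)
#' @export
termini_model <- function(kind = c("DTR", "HEADFUL_PAC", "NONE"),
                          repeat_length = NULL, pac_position = NULL,
                          terminal_redundancy = 3000, pac_start_fraction = 0.5) {
  kind <- match.arg(kind)
  if (kind == "DTR") {
    if (is.null(repeat_length) || repeat_length < 1) {
      stop("a DTR model needs a positive `repeat_length`", call. = FALSE)
    }
  }
  if (kind == "HEADFUL_PAC") {
    if (is.null(pac_position) || pac_position < 0) {
      stop("a headful model needs a non-negative `pac_position`", call. = FALSE)
    }
    if (pac_start_fraction < 0 || pac_start_fraction > 1) {
      stop("`pac_start_fraction` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(kind = kind,
                 repeat_length = if (kind == "DTR") as.integer(repeat_length) else NULL,
                 pac_position = if (kind == "HEADFUL_PAC") as.integer(pac_position) else NULL,
                 terminal_redundancy = as.integer(terminal_redundancy),
                 pac_start_fraction = pac_start_fraction),
            class = "termini_model")
}

#' @export
print.termini_model <- function(x, ...) {
  cat("<termini_model>", x$kind)
  if (x$kind == "DTR") cat(" repeat_length=", x$repeat_length, sep = "")
  if (x$kind == "HEADFUL_PAC") cat(" pac_position=", x$pac_position, sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate single-end reads carrying a packaging signature
#'
#' Reads are drawn from the virion implied by `model` and their true origins
#' are folded back onto the unit genome (0-based, half-open; intervals whose
#' `end` exceeds the genome length wrap circularly).
#'
#' For a DTR virion (`repeat + core + repeat`) read starts are uniform over
#' the linear virion with starts clamped to the molecule ends, so terminal
#' fragments begin or end exactly at the termini; after folding, the repeat
#' receives about twice the core coverage with single-base-delimited
#' boundaries. For headful packaging a fixed fraction of reads start exactly
#' at the pac position on the packaging strand and the remainder start
#' uniformly on the circular genome. `"NONE"` gives uniform circular starts
#' on both strands. Substitution errors are applied i.i.d. at `error_rate`.
#'
#' @param genome Unit genome sequence (single string).
#' @param model A [termini_model()].
#' @param target_depth Mean fold coverage (DTR: relative to virion length).
#' @param read_length Read length in bp; must be shorter than the genome.
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed.
#' @return A `read_set`: a tibble with columns `read_id`, `sequence`, `start`,
#'   `end`, `strand` plus attributes `read_length`, `error_rate`,
#'   `genome_length`, `target_depth` and `model`.
#' @examples
#' g <- generate_genome(5000, 0.6, seed = 1)
#' rs <- simulate_packaged_reads(g, termini_model("DTR", repeat_length = 500),
#'                               target_depth = 5, read_length = 100, seed = 2)
#' nrow(rs)
#' @export
simulate_packaged_reads <- function(genome, model, target_depth = 30,
                                    read_length = 150, error_rate = 0.005,
                                    seed = NULL) {
  genome <- clean_dna(genome, "genome")
  if (length(genome) != 1L) stop("`genome` must be a single sequence", call. = FALSE)
  if (!inherits(model, "termini_model")) stop("`model` must be a termini_model", call. = FALSE)
  L <- nchar(genome)
  rl <- as.integer(read_length)
  if (rl >= L) stop("`read_length` must be shorter than the genome", call. = FALSE)
  if (target_depth <= 0) stop("`target_depth` must be positive", call. = FALSE)

  with_seed(seed, {
    if (model$kind == "DTR") {
      r <- model$repeat_length
      if (r >= L / 2) stop("`repeat_length` must be below half the genome length",
                           call. = FALSE)
      virion <- paste0(genome, substr(genome, 1L, r))
      vl <- L + r
      n <- as.integer(ceiling(target_depth * vl / rl))
      # terminal-fragment reads: every sequenced molecule contributes one
      # read flush with each physical end, which is what delimits the repeat
      # boundaries at single-base resolution in the folded coverage
      n_end <- min(as.integer(round(target_depth)), n %/% 4L)
      n_int <- n - 2L * n_end
      p <- c(sample.int(vl - rl + 1L, n_int, replace = TRUE) - 1L,
             rep(0L, n_end), rep(vl - rl, n_end))
      strand <- c(sample(c("+", "-"), n_int, replace = TRUE),
                  rep("+", n_end), rep("-", n_end))
      seqs <- substring(virion, p + 1L, p + rl)
      ustart <- ifelse(p >= L, p - L, p)
    } else {
      n <- as.integer(ceiling(target_depth * L / rl))
      circ <- paste0(genome, substr(genome, 1L, rl - 1L))
      if (model$kind == "HEADFUL_PAC") {
        pac <- model$pac_position
        if (pac >= L) stop("`pac_position` must lie within the genome", call. = FALSE)
        at_pac <- stats::runif(n) < model$pac_start_fraction
        p <- ifelse(at_pac, pac, sample.int(L, n, replace = TRUE) - 1L)
        strand <- ifelse(at_pac, "+", sample(c("+", "-"), n, replace = TRUE))
      } else {
        p <- sample.int(L, n, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), n, replace = TRUE)
      }
      seqs <- substring(circ, p + 1L, p + rl)
      ustart <- p
    }
    rev <- strand == "-"
    if (any(rev)) seqs[rev] <- reverse_complement(seqs[rev])
    seqs <- apply_substitutions(seqs, error_rate)
    out <- tibble::tibble(
      read_id = sprintf("read_%06d", seq_len(n)),
      sequence = seqs,
      start = as.integer(ustart),
      end = as.integer(ustart) + rl,
      strand = strand
    )
    structure(out, read_length = rl, error_rate = error_rate,
              genome_length = L, target_depth = target_depth, model = model,
              class = c("read_set", class(out)))
  })
}

#' Specify a synthetic phage community
#'
#' The default layout emulates a small actinophage study: three related
#' clusters (39 kb / GC 72%, 49 kb / GC 66%, 133 kb / GC 48%) of three genomes
#' each, diverged at a within-cluster substitution rate of 0.02
#' (pairwise ANI about 96%), plus one unrelated 47 kb / GC 69% singleton with
#' a disjoint domain repertoire.
#'
#' @param clusters A data frame with one row per cluster and columns
#'   `n_genomes`, `ancestor_length`, `gc_target`,
#'   `within_cluster_substitution_rate`, `domain_pool_size`,
#'   `domains_per_genome`.
#' @param n_singletons Number of unrelated singleton genomes.
#' @param shared_domain_fraction Fraction of each cluster's domain pool drawn
#'   from a pool common to all clusters (singletons always use disjoint pools).
#' @param singleton_length,singleton_gc Length (bp) and GC fraction of
#'   singleton genomes.
#' @param singleton_domains Number of domains per singleton genome.
#' @param seed Integer root seed; all per-genome streams are derived from it.
#' @return A `community_spec` list.
#' @examples
#' community_spec(n_singletons = 2)
#' @export
community_spec <- function(clusters = NULL, n_singletons = 1,
                           shared_domain_fraction = 0.1,
                           singleton_length = 47000, singleton_gc = 0.69,
                           singleton_domains = 25, seed = 1) {
  if (is.null(clusters)) {
    clusters <- tibble::tibble(
      n_genomes = c(3L, 3L, 3L),
      ancestor_length = c(39000L, 49000L, 133000L),
      gc_target = c(0.72, 0.66, 0.48),
      within_cluster_substitution_rate = c(0.02, 0.02, 0.02),
      domain_pool_size = c(40L, 40L, 40L),
      domains_per_genome = c(25L, 25L, 25L)
    )
  }
  clusters <- tibble::as_tibble(clusters)
  needed <- c("n_genomes", "ancestor_length", "gc_target",
              "within_cluster_substitution_rate", "domain_pool_size",
              "domains_per_genome")
  missing_cols <- setdiff(needed, names(clusters))
  if (length(missing_cols)) {
    stop("`clusters` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(clusters$n_genomes < 1)) stop("each cluster needs >= 1 genome", call. = FALSE)
  if (any(clusters$within_cluster_substitution_rate < 0 |
          clusters$within_cluster_substitution_rate > 1)) {
    stop("substitution rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(clusters$domains_per_genome > clusters$domain_pool_size)) {
    stop("`domains_per_genome` cannot exceed `domain_pool_size`", call. = FALSE)
  }
  if (shared_domain_fraction < 0 || shared_domain_fraction > 1) {
    stop("`shared_domain_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(clusters = clusters, n_singletons = as.integer(n_singletons),
                 shared_domain_fraction = shared_domain_fraction,
                 singleton_length = as.integer(singleton_length),
                 singleton_gc = singleton_gc,
                 singleton_domains = as.integer(singleton_domains),
                 seed = as.integer(seed)),
            class = "community_spec")
}

# synthetic Pfam-style accessions ("PF9...." namespace, outside real Pfam use)
synthetic_accessions <- function(from, n) {
  sprintf("PF9%04d", seq.int(from, length.out = n))
}

# draw a domain-hit table for one genome
draw_domain_hits <- function(genome_id, pool, n_domains) {
  acc <- sort(sample(pool, n_domains))
  tibble::tibble(
    genome_id = genome_id,
    protein_id = sprintf("%s_p%03d", genome_id, seq_along(acc)),
    domain_accession = acc,
    domain_name = paste0("dom_", acc),
    evalue = signif(10^stats::runif(length(acc), -30, -4), 3),
    bitscore = round(stats::runif(length(acc), 50, 500), 1)
  )
}

#' Plant a synthetic phage community with full ground truth
#'
#' Each cluster is one random ancestor plus independently evolved variants;
#' singletons are unrelated random genomes. Every genome receives a
#' domain-hit table drawn from its cluster's pool (partial overlap within a
#' cluster, configurable sharing across clusters, disjoint pools for
#' singletons), with e-values below the conventional 1e-3 parse cutoff.
#'
#' @param spec A [community_spec()].
#' @return A `phage_community` list with elements `genomes` (tibble: `id`,
#'   `sequence`, `length_bp`, `gc_percent`, `truth_label`), `domain_hits`
#'   (tibble of domain hits across all genomes) and `truth` (a
#'   `cluster_assignment` tibble: `genome_id`, `label`, `singleton`).
#' @examples
#' spec <- community_spec(
#'   clusters = data.frame(n_genomes = 2, ancestor_length = 3000,
#'                         gc_target = 0.6,
#'                         within_cluster_substitution_rate = 0.02,
#'                         domain_pool_size = 10, domains_per_genome = 6),
#'   n_singletons = 1, singleton_length = 3000, seed = 7)
#' comm <- plant_community(spec)
#' comm$truth
#' @export
plant_community <- function(spec) {
  if (!inherits(spec, "community_spec")) stop("`spec` must be a community_spec", call. = FALSE)
  cl <- spec$clusters
  k <- nrow(cl)

  # domain pools: a shared pool feeds `shared_domain_fraction` of every
  # cluster pool; remaining accessions are cluster- or singleton-unique
  n_shared <- if (k > 0) max(0L, round(spec$shared_domain_fraction * max(cl$domain_pool_size))) else 0L
  acc_counter <- 1L
  shared_pool <- synthetic_accessions(acc_counter, n_shared)
  acc_counter <- acc_counter + n_shared

  genomes <- list()
  hits <- list()
  truth <- list()

  for (i in seq_len(k)) {
    lab <- sprintf("C%d", i)
    n_from_shared <- min(n_shared, round(spec$shared_domain_fraction * cl$domain_pool_size[i]))
    n_unique <- cl$domain_pool_size[i] - n_from_shared
    pool_unique <- synthetic_accessions(acc_counter, n_unique)
    acc_counter <- acc_counter + n_unique
    pool <- with_seed(derive_seed(spec$seed, 1000L + i), {
      c(if (n_from_shared > 0) sample(shared_pool, n_from_shared) else character(),
        pool_unique)
    })
    ancestor <- generate_genome(cl$ancestor_length[i], cl$gc_target[i],
                                seed = derive_seed(spec$seed, 2000L + i))
    for (j in seq_len(cl$n_genomes[i])) {
      gid <- sprintf("%s_g%d", lab, j)
      gseed <- derive_seed(spec$seed, 3000L + 100L * i + j)
      seqs <- evolve_variant(ancestor, cl$within_cluster_substitution_rate[i],
                             seed = gseed)
      genomes[[gid]] <- tibble::tibble(
        id = gid, sequence = seqs, length_bp = nchar(seqs),
        gc_percent = gc_content(seqs), truth_label = lab
      )
      hits[[gid]] <- with_seed(derive_seed(spec$seed, 4000L + 100L * i + j),
                               draw_domain_hits(gid, pool, cl$domains_per_genome[i]))
      truth[[gid]] <- tibble::tibble(genome_id = gid, label = lab, singleton = FALSE)
    }
  }

  for (s in seq_len(spec$n_singletons)) {
    lab <- sprintf("S%d", s)
    gid <- sprintf("%s_g1", lab)
    pool <- synthetic_accessions(acc_counter, spec$singleton_domains)
    acc_counter <- acc_counter + spec$singleton_domains
    seqs <- generate_genome(spec$singleton_length, spec$singleton_gc,
                            seed = derive_seed(spec$seed, 5000L + s))
    genomes[[gid]] <- tibble::tibble(
      id = gid, sequence = seqs, length_bp = nchar(seqs),
      gc_percent = gc_content(seqs), truth_label = lab
    )
    hits[[gid]] <- with_seed(derive_seed(spec$seed, 6000L + s),
                             draw_domain_hits(gid, pool, spec$singleton_domains))
    truth[[gid]] <- tibble::tibble(genome_id = gid, label = lab, singleton = TRUE)
  }

  genomes <- dplyr::arrange(dplyr::bind_rows(genomes), .data$id)
  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$genome_id)
  truth <- structure(truth, class = c("cluster_assignment", class(truth)))
  all_hits <- dplyr::arrange(dplyr::bind_rows(hits), .data$genome_id,
                             .data$domain_accession)
  structure(list(genomes = genomes, domain_hits = all_hits,
                 truth = truth, spec = spec),
            class = "phage_community")
}

#' @export
print.phage_community <- function(x, ...) {
  cat("<phage_community>", nrow(x$genomes), "genomes,",
      length(unique(x$truth$label)), "truth groups,",
      nrow(x$domain_hits), "domain hits\n")
  invisible(x)
}
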