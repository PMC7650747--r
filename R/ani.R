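#' ANIb configuration
#'
#' Fragment-based average nucleotide identity following the ANIb convention:
#' the query is chopped into consecutive 1020 bp fragments, each fragment is
#' aligned locally against the reference, and fragments qualify when at least
#' `min_fragment_aligned_fraction` of the fragment aligns at
#' `min_fragment_identity` percent identity or better.
#'
#' @param fragment_size Fragment length in bp (default 1020).
#' @param min_fragment_identity Minimum percent identity for a fragment to
#'   qualify (default 30).
#' @param min_fragment_aligned_fraction Minimum aligned fraction of the
#'   fragment (default 0.7).
#' @param symmetrization How to combine the two directed values per pair:
#'   `"mean"` (default, matching an averaged identity matrix) or `"min"`.
#' @param seed_kmer Seed k-mer length for the fragment aligner (default 15).
#' @param band Alignment window half-width around the best seeded diagonal,
#'   in bp (default 75).
#' @return An `ani_config` list.
#' @export
ani_config <- function(fragment_size = 1020, min_fragment_identity = 30,
                       min_fragment_aligned_fraction = 0.7,
                       symmetrization = c("mean", "min"),
                       seed_kmer = 15, band = 75) {
  symmetrization <- match.arg(symmetrization)
  if (fragment_size < 1) stop("`fragment_size` must be positive", call. = FALSE)
  if (min_fragment_identity < 0 || min_fragment_identity > 100) {
    stop("`min_fragment_identity` must lie in [0, 100]", call. = FALSE)
  }
  if (min_fragment_aligned_fraction < 0 || min_fragment_aligned_fraction > 1) {
    stop("`min_fragment_aligned_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fragment_size = as.integer(fragment_size),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_aligned_fraction = min_fragment_aligned_fraction,
                 symmetrization = symmetrization,
                 seed_kmer = as.integer(seed_kmer), band = as.integer(band)),
            class = "ani_config")
}

#' Split a genome into consecutive ANIb fragments
#'
#' Non-overlapping windows of `fragment_size` bp; a trailing remainder
#' shorter than one fragment is discarded.
#'
#' @param sequence A single DNA sequence at least `fragment_size` long.
#' @param fragment_size Fragment length in bp (default 1020).
#' @return Character vector of fragments.
#' @examples
#' length(fragment_genome(strrep("ACGT", 1500), 1020))
#' @export
fragment_genome <- function(sequence, fragment_size = 1020) {
  sequence <- clean_dna(sequence)
  if (length(sequence) != 1L) stop("`sequence` must be a single string", call. = FALSE)
  n <- nchar(sequence)
  if (n < fragment_size) {
    stop("sequence shorter than one fragment", call. = FALSE)
  }
  k <- n %/% fragment_size
  starts <- (seq_len(k) - 1L) * fragment_size + 1L
  substring(sequence, starts, starts + fragment_size - 1L)
}

# per-fragment identities of query fragments against a reference
anib_fragments <- function(query, reference, config) {
  frags <- fragment_genome(query, config$fragment_size)
  res <- anib_map_fragments_cpp(clean_dna(reference), frags,
                                config$seed_kmer, config$band,
                                2, -3, 5)
  out <- tibble::as_tibble(res)
  out$fragment <- seq_len(nrow(out))
  out$qualifies <- !is.na(out$identity) &
    out$aligned_fraction >= config$min_fragment_aligned_fraction &
    out$identity >= config$min_fragment_identity
  out
}

#' Directed fragment-based ANI between two genomes
#'
#' Chops the query into fragments, aligns each locally against the reference
#' (k-mer seeded, both strands, gapped Smith-Waterman extension in a window
#' around the best diagonal), and averages the identities of qualifying
#' fragments. Returns `NA` when no fragment qualifies (no detectable
#' homology).
#'
#' @param query,reference Genome sequences (single strings, both at least
#'   one fragment long).
#' @param config An [ani_config()].
#' @return Percent identity in `[0, 100]`, or `NA_real_`.
#' @examples
#' g <- generate_genome(3000, 0.5, seed = 1)
#' anib_pair(g, g)
#' @export
anib_pair <- function(query, reference, config = ani_config()) {
  fr <- anib_fragments(query, reference, config)
  if (!any(fr$qualifies)) return(NA_real_)
  mean(fr$identity[fr$qualifies])
}

#' Pairwise ANIb matrix over a genome set
#'
#' All ordered pairs are computed and then symmetrized per
#' `config$symmetrization` (default: mean of the two directions; a missing
#' direction defers to the observed one; two missing directions stay
#' missing). The diagonal is 100 by definition.
#'
#' @param genomes Tibble with columns `id` and `sequence`, or a named
#'   character vector. Ids must be unique.
#' @param config An [ani_config()].
#' @return An `ani_matrix`: a symmetric numeric percent matrix with genome
#'   ids as dimnames and the configuration attached as attribute `config`.
#' @export
ani_matrix <- function(genomes, config = ani_config()) {
  genomes <- as_genome_tbl(genomes)
  if (nrow(genomes) < 2L) stop("need at least two genomes", call. = FALSE)
  if (anyDuplicated(genomes$id)) stop("duplicate genome ids", call. = FALSE)
  ids <- genomes$id
  n <- length(ids)
  directed <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(directed) <- 100
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      directed[i, j] <- anib_pair(genomes$sequence[i], genomes$sequence[j],
                                  config)
    }
  }
  values <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(values) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ab <- c(directed[i, j], directed[j, i])
      v <- if (all(is.na(ab))) {
        NA_real_
      } else if (config$symmetrization == "mean") {
        mean(ab, na.rm = TRUE)
      } else {
        min(ab, na.rm = TRUE)
      }
      values[i, j] <- values[j, i] <- v
    }
  }
  structure(values, config = config, directed = directed,
            class = c("ani_matrix", "matrix"))
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat("<ani_matrix>", nrow(x), "genomes;",
      sum(is.na(x[upper.tri(x)])), "pair(s) without detectable homology\n")
  m <- round(unclass(x), 2)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

#' Cluster an ANI matrix into a dendrogram
#'
#' Agglomerative clustering on the distance `100 - ANI`; pairs without
#' detectable homology are imputed at distance 100 (identity 0) so unrelated
#' genomes join last.
#'
#' @param x An [ani_matrix()].
#' @param linkage Linkage criterion (default `"average"`).
#' @return A `phage_dendrogram`.
#' @export
cluster_ani <- function(x, linkage = c("average", "ward.D2", "ward.D",
                                       "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(x, "ani_matrix"))
  d <- 100 - unclass(x)
  d[is.na(d)] <- 100
  diag(d) <- 0
  agglomerate(d, method = linkage)
}

#' Write an ANI matrix as TSV
#'
#' @param x An `ani_matrix`.
#' @param path Output path; ids form the header row and first column.
#' @return `path`, invisibly.
#' @export
write_ani_tsv <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}
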