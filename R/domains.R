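DOMAIN_HIT_COLS <- c("genome_id", "protein_id", "domain_accession",
                     "domain_name", "evalue", "bitscore")

#' Parse a domain-hit table and apply the e-value cutoff
#'
#' Reads a tab-separated table of protein-domain hits (RPS-BLAST-style
#' tabular dialect) and discards rows whose e-value exceeds the cutoff. The
#' cutoff is inclusive (`evalue <= cutoff` is kept). Rows with an
#' unparseable e-value are dropped with a warning; duplicate
#' (genome, domain) rows are retained at this stage (presence/absence
#' collapsing happens in [build_pa_matrix()]).
#'
#' @param table Path to a TSV file, or a data frame of hits.
#' @param evalue_cutoff Inclusive e-value cutoff (default 0.001, the
#'   conventional RPS-BLAST reporting threshold).
#' @param col_map Named character or integer vector mapping the canonical
#'   column names (`genome_id`, `protein_id`, `domain_accession`,
#'   `domain_name`, `evalue`, `bitscore`) to the file's columns. Defaults to
#'   same-named columns (or positional order for headerless files).
#' @param header `"auto"` (default), `TRUE` or `FALSE`. With `"auto"`, a
#'   first line whose e-value field is non-numeric is treated as a header.
#' @return Tibble of `DomainHit` rows with the canonical columns.
#' @export
parse_domain_hits <- function(table, evalue_cutoff = 0.001, col_map = NULL,
                              header = "auto") {
  if (is.character(table) && length(table) == 1L) {
    raw <- tryCatch(
      readr::read_tsv(table, col_names = FALSE, col_types = readr::cols(
        .default = readr::col_character()), progress = FALSE),
      error = function(e) stop("malformed domain-hit table: ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(raw) == 0L) {
      return(tibble::tibble(genome_id = character(), protein_id = character(),
                            domain_accession = character(),
                            domain_name = character(), evalue = numeric(),
                            bitscore = numeric()))
    }
    if (ncol(raw) < 4L) {
      stop("malformed domain-hit table: too few columns", call. = FALSE)
    }
    has_header <- if (identical(header, "auto")) {
      # a header row carries no numeric fields at all (data rows always
      # have a numeric e-value and usually a bitscore)
      all(is.na(suppressWarnings(as.numeric(unlist(raw[1, ])))))
    } else {
      isTRUE(header)
    }
    if (has_header) {
      names(raw) <- as.character(raw[1, ])
      raw <- raw[-1, , drop = FALSE]
    } else {
      names(raw)[seq_len(min(ncol(raw), 6L))] <-
        DOMAIN_HIT_COLS[seq_len(min(ncol(raw), 6L))]
    }
    table <- raw
  }
  table <- tibble::as_tibble(table)

  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      src <- col_map[[nm]]
      table[[nm]] <- if (is.numeric(src)) table[[as.integer(src)]] else table[[src]]
    }
  }
  missing_cols <- setdiff(c("genome_id", "protein_id", "domain_accession",
                            "evalue"), names(table))
  if (length(missing_cols)) {
    stop("domain-hit table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"domain_name" %in% names(table)) table$domain_name <- NA_character_
  if (!"bitscore" %in% names(table)) table$bitscore <- NA_real_

  ev <- suppressWarnings(as.numeric(table$evalue))
  bad <- is.na(ev) & !is.na(table$evalue)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable e-value rejected", call. = FALSE)
  }
  keep <- !is.na(ev) & ev <= evalue_cutoff
  out <- table[keep, , drop = FALSE]
  tibble::tibble(
    genome_id = as.character(out$genome_id),
    protein_id = as.character(out$protein_id),
    domain_accession = as.character(out$domain_accession),
    domain_name = as.character(out$domain_name),
    evalue = ev[keep],
    bitscore = suppressWarnings(as.numeric(out$bitscore))
  )
}

#' Build a genomes-by-domains presence-absence matrix
#'
#' Rows are genomes, columns the union of domain accessions across all hits
#' (sorted); a cell is 1 iff the genome has at least one qualifying hit for
#' that accession, so duplicated hits collapse to a single presence. Genomes
#' listed in `genome_ids` but absent from `hits` yield all-zero rows.
#'
#' @param hits Tibble of domain hits (see [parse_domain_hits()]); a named
#'   list of per-genome hit tables is also accepted.
#' @param genome_ids Optional character vector fixing the row universe.
#' @param pfam_only Keep only Pfam-prefixed accessions (`PF...`,
#'   case-insensitive; default `TRUE`, matching a Pfam-domain analysis).
#' @return A `pa_matrix`: binary integer matrix with genome ids as rownames
#'   and sorted accessions as colnames.
#' @examples
#' h <- tibble::tibble(genome_id = c("A", "A", "B"),
#'                     protein_id = c("p1", "p2", "p3"),
#'                     domain_accession = c("PF00001", "PF00002", "PF00002"),
#'                     domain_name = NA, evalue = 1e-5, bitscore = 100)
#' build_pa_matrix(h)
#' @export
build_pa_matrix <- function(hits, genome_ids = NULL, pfam_only = TRUE) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- dplyr::bind_rows(hits)
  hits <- tibble::as_tibble(hits)
  if (pfam_only && nrow(hits)) {
    hits <- hits[stringr::str_detect(toupper(hits$domain_accession), "^PF"), ,
                 drop = FALSE]
  }
  gids <- sort(unique(c(as.character(genome_ids), hits$genome_id)))
  if (!length(gids)) stop("no genomes supplied", call. = FALSE)
  accs <- sort(unique(hits$domain_accession))
  m <- matrix(0L, length(gids), length(accs), dimnames = list(gids, accs))
  if (nrow(hits)) {
    ij <- unique(cbind(match(hits$genome_id, gids),
                       match(hits$domain_accession, accs)))
    m[ij] <- 1L
  }
  structure(m, class = c("pa_matrix", "matrix"))
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("<pa_matrix>", nrow(x), "genomes x", ncol(x), "domains;",
      sum(x), "presences\n")
  invisible(x)
}

#' Ward clustering of a presence-absence matrix
#'
#' Euclidean distances between the binary genome rows, agglomerated with
#' Ward's criterion in its squared-Euclidean formulation (`ward.D2`: squared
#' distances inside the update, merge heights on the original scale).
#' `ward.D` and a Jaccard row distance are available for exploration.
#'
#' @param matrix A [build_pa_matrix()] result (any numeric genomes-by-features
#'   matrix works).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @param distance `"euclidean"` (default; required for Ward's geometric
#'   interpretation) or `"jaccard"`.
#' @return A `phage_dendrogram`.
#' @export
ward_dendrogram <- function(matrix, method = c("ward.D2", "ward.D"),
                            distance = c("euclidean", "jaccard")) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  m <- unclass(matrix)
  if (nrow(m) < 2L) {
    return(agglomerate(base::matrix(0, nrow(m), nrow(m),
                                    dimnames = list(rownames(m), rownames(m))),
                       method = method))
  }
  d <- if (distance == "euclidean") {
    stats::dist(m, method = "euclidean")
  } else {
    stats::dist(m, method = "binary")
  }
  agglomerate(as.matrix(d), method = method)
}

# pairwise counts of shared domains between genome rows
shared_domain_counts <- function(pa) {
  m <- unclass(pa)
  s <- m %*% t(m)
  diag(s) <- NA
  s
}

#' Cut a dendrogram into clusters and flag singletons
#'
#' The tree is cut into `k` clusters (or at height `h`); afterwards any
#' genome sharing fewer than `singleton_min_shared` domains with *every*
#' other genome is re-labelled as its own singleton regardless of the cut,
#' mirroring the treatment of highly divergent phages that do not share
#' sufficient similarity with any cluster.
#'
#' @param dendrogram A `phage_dendrogram` over the genomes of `matrix`.
#' @param matrix The [build_pa_matrix()] the tree was built from.
#' @param k,h Exactly one of cluster count `k` or cut height `h`.
#' @param singleton_min_shared Minimum shared-domain count with at least one
#'   other genome to escape singleton status (default 3).
#' @return A `cluster_assignment` tibble with columns `genome_id`, `label`
#'   and `singleton`.
#' @export
cut_and_flag <- function(dendrogram, matrix, k = NULL, h = NULL,
                         singleton_min_shared = 3) {
  part <- cut_dendrogram(dendrogram, k = k, h = h)
  pa <- unclass(matrix)[part$genome_id, , drop = FALSE]
  shared <- shared_domain_counts(pa)
  max_shared <- apply(shared, 1, max, na.rm = TRUE)
  max_shared[!is.finite(max_shared)] <- 0
  singleton <- max_shared < singleton_min_shared
  out <- tibble::tibble(
    genome_id = part$genome_id,
    label = paste0("cluster_", part$cluster),
    singleton = unname(singleton[part$genome_id])
  )
  out$label[out$singleton] <- paste0("singleton_", out$genome_id[out$singleton])
  structure(out, class = c("cluster_assignment", class(out)))
}

#' Default temperate-lifestyle marker domains
#'
#' Pfam accessions for phage integrases, serine recombinases and
#' immunity-repressor-type helix-turn-helix domains, shipped as a plain-text
#' configuration file that users can replace.
#'
#' @param path Optional path to a custom marker table (TSV with a column
#'   `accession`).
#' @return Tibble with columns `accession`, `name`, `role`.
#' @export
temperate_markers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "temperate_markers.tsv",
                        package = "phageprofiler")
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Rule-based temperate-lifestyle evidence flag
#'
#' A genome is flagged `temperate-evidence` iff at least one marker domain
#' (integrase/recombinase or immunity repressor by default) is present among
#' its hits; otherwise `no-temperate-evidence`. Matching is by accession
#' string, case-insensitive. This is an evidence flag, not a lifestyle
#' prediction: a phage can lose its integrase yet remain otherwise
#' temperate-looking, so the flag should be read alongside plaque morphology
#' and annotation.
#'
#' @param hits Tibble of domain hits with columns `genome_id` and
#'   `domain_accession`.
#' @param marker_accessions Character vector of marker accessions (default:
#'   the [temperate_markers()] table).
#' @param genome_ids Optional genome universe; genomes without hits are
#'   reported `no-temperate-evidence`.
#' @return Tibble with columns `genome_id` and `lifestyle_flag`.
#' @export
lifestyle_flags <- function(hits, marker_accessions = NULL, genome_ids = NULL) {
  if (is.null(marker_accessions)) {
    marker_accessions <- temperate_markers()$accession
  }
  if (!length(marker_accessions)) {
    stop("`marker_accessions` must be non-empty", call. = FALSE)
  }
  hits <- tibble::as_tibble(hits)
  gids <- sort(unique(c(as.character(genome_ids),
                        if (nrow(hits)) hits$genome_id)))
  markers <- toupper(marker_accessions)
  flagged <- if (nrow(hits)) {
    unique(hits$genome_id[toupper(hits$domain_accession) %in% markers])
  } else {
    character()
  }
  tibble::tibble(
    genome_id = gids,
    lifestyle_flag = ifelse(gids %in% flagged, "temperate-evidence",
                            "no-temperate-evidence")
  )
}
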