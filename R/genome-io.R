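#' Read a multi-record FASTA file into a tibble
#'
#' Sequences are upper-cased on read; characters outside `{A,C,G,T,N}` are
#' rejected. The record id is the first whitespace-delimited token of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- stringr::str_split_fixed(names(x), "\\s+", 2)[, 1]
  tibble::tibble(id = ids, sequence = unname(clean_dna(as.character(x))))
}

#' Write genome sequences to FASTA
#'
#' @param genomes Tibble with columns `id` and `sequence` (or a named
#'   character vector).
#' @param path Output path.
#' @param width Line wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70) {
  genomes <- as_genome_tbl(genomes)
  x <- Biostrings::DNAStringSet(stats::setNames(genomes$sequence, genomes$id))
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Write a read set to FASTQ
#'
#' Four-line records with a constant quality string (`"I"`, Phred 40); the
#' simulator models substitution errors only, so per-base qualities carry no
#' information.
#'
#' @param reads A `read_set` or tibble with columns `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- stringr::str_split_fixed(names(x), "\\s+", 2)[, 1]
  tibble::tibble(read_id = ids, sequence = unname(clean_dna(as.character(x))))
}

# normalise genome inputs: tibble(id, sequence) / named character vector
as_genome_tbl <- function(genomes) {
  if (is.character(genomes)) {
    ids <- names(genomes)
    if (is.null(ids)) ids <- sprintf("genome_%d", seq_along(genomes))
    genomes <- tibble::tibble(id = ids, sequence = unname(genomes))
  }
  genomes <- tibble::as_tibble(genomes)
  if (!all(c("id", "sequence") %in% names(genomes))) {
    stop("genomes need `id` and `sequence` columns", call. = FALSE)
  }
  genomes$sequence <- clean_dna(genomes$sequence)
  genomes
}

#' GC content of DNA sequences
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from
#' both numerator and denominator.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector of GC percentages in `[0, 100]` (unrounded; report
#'   tables round to one decimal).
#' @examples
#' gc_content(c("ATGC", "GGCC"))
#' @export
gc_content <- function(sequence) {
  sequence <- clean_dna(sequence)
  if (length(sequence) == 0L) return(numeric())
  gc <- stringr::str_count(sequence, "[GC]")
  acgt <- stringr::str_count(sequence, "[ACGT]")
  if (any(acgt == 0L)) {
    stop("GC content is undefined for an empty or all-N sequence", call. = FALSE)
  }
  100 * gc / acgt
}

ORF_STARTS <- c("ATG", "GTG", "TTG")
ORF_STOPS <- c("TAA", "TAG", "TGA")

# maximal ORFs on one strand of s; 0-based half-open coordinates on s
orfs_one_strand <- function(s, min_length_nt) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    m <- (n - f) %/% 3
    if (m < 2) next
    pos1 <- f + 3 * (seq_len(m) - 1) + 1
    codons <- substring(s, pos1, pos1 + 2)
    is_start <- codons %in% ORF_STARTS
    is_stop <- codons %in% ORF_STOPS
    stops <- which(is_stop)
    prev <- 0L
    for (st in stops) {
      if (st - prev >= 2L) {
        cand <- prev + which(is_start[(prev + 1L):(st - 1L)])
        if (length(cand)) {
          i0 <- cand[1L]
          len <- (st - i0 + 1L) * 3L
          if (len >= min_length_nt) {
            out[[length(out) + 1L]] <- c(start = f + (i0 - 1L) * 3L,
                                         end = f + st * 3L, frame = f)
          }
        }
      }
      prev <- st
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(), frame = integer()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Find open reading frames (bacterial genetic code)
#'
#' Scans both strands in all six frames for maximal reading frames running
#' from an `ATG`/`GTG`/`TTG` start codon to the next in-frame stop
#' (`TAA`/`TAG`/`TGA`; genetic code 11). For each stop, the leftmost start
#' after the previous in-frame stop is reported; overlapping ORFs in
#' different frames are all kept. This deliberately simple scan approximates
#' dedicated gene callers and will not reproduce curated ORF counts.
#'
#' @param sequence A single DNA sequence.
#' @param min_length_nt Minimum ORF length in nucleotides including the stop
#'   codon; must be a multiple of 3 and at least 6. Default 300.
#' @param genetic_code Genetic code identifier; only `"11"` is supported.
#' @return Tibble with columns `start`, `end` (0-based, half-open, on the
#'   forward strand), `strand` and `frame` (0-2 on the ORF's own strand),
#'   sorted by `start`.
#' @examples
#' find_orfs("ATGAAATAA", min_length_nt = 9)
#' @export
find_orfs <- function(sequence, min_length_nt = 300, genetic_code = "11") {
  sequence <- clean_dna(sequence)
  if (length(sequence) != 1L) stop("`sequence` must be a single string", call. = FALSE)
  if (!identical(as.character(genetic_code), "11")) {
    stop("unsupported `genetic_code`; only \"11\" is available", call. = FALSE)
  }
  if (min_length_nt < 6 || min_length_nt %% 3 != 0) {
    stop("`min_length_nt` must be >= 6 and a multiple of 3", call. = FALSE)
  }
  n <- nchar(sequence)
  fwd <- orfs_one_strand(sequence, min_length_nt)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- orfs_one_strand(reverse_complement(sequence), min_length_nt)
  if (nrow(rev)) {
    rev <- tibble::tibble(start = n - rev$end, end = n - rev$start,
                          frame = rev$frame, strand = "-")
  } else {
    rev$strand <- character()
  }
  out <- dplyr::bind_rows(fwd, rev)
  dplyr::arrange(out[, c("start", "end", "strand", "frame")],
                 .data$start, .data$end, .data$strand)
}

#' Summarize per-genome features as a report table
#'
#' One row per genome with the conventional characterization columns: size in
#' kb (rounded to the nearest integer), GC content to one decimal, ORF count,
#' termini class and lifestyle-evidence flag. Features that were not computed
#' are reported as `"unknown"`, never as an empty string. Rows are sorted by
#' genome id.
#'
#' @param records Tibble with columns `id` and `sequence`; optional columns
#'   `orf_count`, `termini_class`, `lifestyle_flag` are carried through.
#' @param compute_orfs If `TRUE` (default) and `orf_count` is absent, count
#'   ORFs with [find_orfs()] at `min_orf_length`.
#' @param min_orf_length Minimum ORF length passed to [find_orfs()].
#' @return Tibble with columns `id`, `genome_size_kb`, `gc_percent`,
#'   `orf_count`, `termini_class`, `lifestyle_flag`.
#' @export
summary_table <- function(records, compute_orfs = TRUE, min_orf_length = 300) {
  records <- as_genome_tbl(records)
  if (nrow(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  orf_count <- if ("orf_count" %in% names(records)) {
    records$orf_count
  } else if (compute_orfs) {
    purrr::map_int(records$sequence,
                   ~ nrow(find_orfs(.x, min_length_nt = min_orf_length)))
  } else {
    rep(NA_integer_, nrow(records))
  }
  as_chr_or_unknown <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", "unknown", x)
  }
  out <- tibble::tibble(
    id = records$id,
    genome_size_kb = round(nchar(records$sequence) / 1000),
    gc_percent = round(gc_content(records$sequence), 1),
    orf_count = orf_count,
    termini_class = as_chr_or_unknown(
      if ("termini_class" %in% names(records)) records$termini_class else NA),
    lifestyle_flag = as_chr_or_unknown(
      if ("lifestyle_flag" %in% names(records)) records$lifestyle_flag else NA)
  )
  dplyr::arrange(out, .data$id)
}

#' Read sequences from a local GenBank flat file
#'
#' Minimal sequence-only reader for GenBank records (LOCUS + ORIGIN blocks);
#' annotation features are ignored.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return Tibble with columns `id` (accession, falling back to the LOCUS
#'   name) and `sequence`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS", lines)
  if (!length(rec_start)) stop("no LOCUS record found in ", path, call. = FALSE)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  out <- purrr::map2(rec_start, rec_end, function(a, b) {
    block <- lines[a:b]
    acc <- stringr::str_match(block[grep("^ACCESSION", block)[1]],
                              "^ACCESSION\\s+(\\S+)")[, 2]
    if (is.na(acc) || !length(acc)) {
      acc <- stringr::str_match(block[1], "^LOCUS\\s+(\\S+)")[, 2]
    }
    o <- grep("^ORIGIN", block)
    if (!length(o)) stop("GenBank record without ORIGIN block", call. = FALSE)
    end <- grep("^//", block)
    end <- end[end > o[1]][1]
    seq_lines <- block[(o[1] + 1L):(end - 1L)]
    s <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    tibble::tibble(id = acc, sequence = s)
  })
  out <- dplyr::bind_rows(out)
  out$sequence <- clean_dna(out$sequence)
  out
}

#' Fetch genome sequences from GenBank by accession
#'
#' Downloads nucleotide records over the network via [ape::read.GenBank()].
#' Intended for accession-based feature checks against published report
#' tables; requires internet access.
#'
#' @param accessions Character vector of GenBank accessions.
#' @param timeout Download timeout in seconds (default 60).
#' @return Tibble with columns `id` and `sequence`.
#' @export
fetch_genbank <- function(accessions, timeout = 60) {
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  x <- ape::read.GenBank(accessions, as.character = TRUE)
  tibble::tibble(
    id = names(x),
    sequence = clean_dna(toupper(vapply(x, paste, character(1), collapse = "")))
  )
}
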