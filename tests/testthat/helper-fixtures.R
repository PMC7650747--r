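# small planted community used across test files
small_community <- function(seed = 11, n_clusters = 3, n_genomes = 2,
                            lengths = NULL, shared = 0, rate = 0.02) {
  if (is.null(lengths)) lengths <- 15000 + 1000 * seq_len(n_clusters)
  spec <- community_spec(
    clusters = tibble::tibble(
      n_genomes = n_genomes,
      ancestor_length = lengths,
      gc_target = seq(0.5, 0.7, length.out = n_clusters),
      within_cluster_substitution_rate = rate,
      domain_pool_size = 20,
      domains_per_genome = 12
    ),
    n_singletons = 1, singleton_length = round(mean(lengths)),
    shared_domain_fraction = shared, seed = seed
  )
  plant_community(spec)
}

# hit tibble builder with sensible defaults
hit_tbl <- function(genome_id, domain_accession, evalue = 1e-6,
                    protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sprintf("%s_p%d", genome_id, seq_along(genome_id))
  }
  tibble::tibble(genome_id = genome_id, protein_id = protein_id,
                 domain_accession = domain_accession,
                 domain_name = paste0("dom_", domain_accession),
                 evalue = evalue, bitscore = 100)
}

# independent regex-based ORF oracle: codons collapsed to a symbol string,
# maximal ORFs are leftmost "start ... next in-frame stop" matches
orf_oracle_one_strand <- function(s, min_len) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    m <- (n - f) %/% 3
    if (m < 2) next
    pos1 <- f + 3 * (seq_len(m) - 1) + 1
    codons <- substring(s, pos1, pos1 + 2)
    sym <- ifelse(codons %in% c("TAA", "TAG", "TGA"), "X",
                  ifelse(codons %in% c("ATG", "GTG", "TTG"), "S", "O"))
    symstr <- paste(sym, collapse = "")
    mt <- gregexpr("S[^X]*X", symstr)[[1]]
    if (mt[1] == -1) next
    for (z in seq_along(mt)) {
      i0 <- mt[z]                       # 1-based codon index of the start
      len <- attr(mt, "match.length")[z] * 3
      if (len >= min_len) {
        out[[length(out) + 1]] <- c(start = f + (i0 - 1) * 3,
                                    end = f + (i0 - 1 + attr(mt, "match.length")[z]) * 3,
                                    frame = f)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(), frame = integer()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

orf_oracle <- function(seq, min_len) {
  n <- nchar(seq)
  fwd <- orf_oracle_one_strand(seq, min_len)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- orf_oracle_one_strand(phageprofiler::reverse_complement(seq), min_len)
  if (nrow(rev)) {
    rev <- tibble::tibble(start = n - rev$end, end = n - rev$start,
                          frame = rev$frame, strand = "-")
  } else {
    rev$strand <- character()
  }
  out <- dplyr::bind_rows(fwd, rev)[, c("start", "end", "strand", "frame")]
  dplyr::arrange(out, start, end, strand)
}

# depth recomputed directly from true read origins (no mapper involved)
true_origin_depth <- function(reads, L) {
  delta <- numeric(L + 1)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]
    e <- reads$end[i]
    if (e <= L) {
      delta[s + 1] <- delta[s + 1] + 1
      delta[e + 1] <- delta[e + 1] - 1
    } else {
      delta[s + 1] <- delta[s + 1] + 1
      delta[L + 1] <- delta[L + 1] - 1
      delta[1] <- delta[1] + 1
      delta[e - L + 1] <- delta[e - L + 1] - 1
    }
  }
  cumsum(delta[seq_len(L)])
}

# local-alignment identity oracle via exhaustive dynamic programming,
# matching the package's scoring scheme (match 2, mismatch -3, linear gap 5)
dp_identity_oracle <- function(fragment, reference) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  best <- NULL
  for (s in c(fragment, phageprofiler::reverse_complement(fragment))) {
    aln <- Biostrings::pairwiseAlignment(s, reference, type = "local",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 5)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
      best <- aln
    }
  }
  Biostrings::pid(best, type = "PID1")
}
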