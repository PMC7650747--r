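DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from one root seed; stays below 2^31 - 1.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483629 + 1)
}

# Upper-case and validate a DNA sequence vector (alphabet A, C, G, T, N).
clean_dna <- function(x, what = "sequence") {
  if (!is.character(x)) stop("`", what, "` must be a character vector", call. = FALSE)
  x <- toupper(x)
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad, na.rm = TRUE)) {
    stop("`", what, "` contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length with each sequence reverse
#'   complemented.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(x) {
  x <- clean_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform substitution errors applied jointly over a vector of reads.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  big <- paste(seqs, collapse = "")
  chars <- strsplit(big, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  if (length(idx)) {
    cur <- match(chars[idx], DNA_BASES)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  big <- paste(chars, collapse = "")
  nc <- nchar(seqs)
  ends <- cumsum(nc)
  substring(big, ends - nc + 1L, ends)
}
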