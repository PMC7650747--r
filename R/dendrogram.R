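#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Lance-Williams agglomeration over a full distance matrix. Ward's
#' criterion is offered in its squared-Euclidean formulation (`"ward.D2"`,
#' heights on the original distance scale) and in the plain-distance variant
#' (`"ward.D"`); `"average"` (UPGMA), `"complete"` and `"single"` linkage are
#' also available. When several pairs tie at the minimum distance the pair
#' whose lexicographically smallest member labels come first is merged, so
#' the result is invariant to row permutations of the input.
#'
#' @param d A symmetric numeric distance matrix with labelled rows/columns,
#'   or a [stats::dist] object.
#' @param method Linkage criterion.
#' @return A `phage_dendrogram`: an hclust-compatible list with elements
#'   `merge`, `height`, `order`, `labels`, `method`.
#' @examples
#' m <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' agglomerate(m, "average")
#' @export
agglomerate <- function(d, method = c("average", "ward.D2", "ward.D",
                                      "complete", "single")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("`d` must be a square distance matrix", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("item_%d", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) {
    out <- list(merge = matrix(integer(), 0, 2), height = numeric(0),
                order = seq_len(n), labels = labels, method = method)
    class(out) <- "phage_dendrogram"
    return(out)
  }

  # ward.D2 updates operate on squared distances; heights are sqrt'ed back
  squared <- method == "ward.D2"
  D <- if (squared) d^2 else d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)              # hclust convention: leaves are negative
  rep_label <- labels              # lexicographically smallest member label
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    mn <- min(sub)
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    cand_i <- idx[hit[, 1]]
    cand_j <- idx[hit[, 2]]
    lo <- pmin(rep_label[cand_i], rep_label[cand_j])
    hi <- pmax(rep_label[cand_i], rep_label[cand_j])
    pick <- order(lo, hi)[1L]
    i <- cand_i[pick]; j <- cand_j[pick]

    height[step] <- if (squared) sqrt(mn) else mn
    # hclust row convention: singletons before clusters, then by index
    pair <- c(node[i], node[j])
    merge[step, ] <- pair[order(pair > 0, abs(pair))]

    others <- setdiff(idx, c(i, j))
    ni <- size[i]; nj <- size[j]
    for (k in others) {
      nk <- size[k]
      D[i, k] <- D[k, i] <- switch(
        method,
        average = (ni * D[i, k] + nj * D[j, k]) / (ni + nj),
        complete = max(D[i, k], D[j, k]),
        single = min(D[i, k], D[j, k]),
        ward.D = ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
          (ni + nj + nk),
        ward.D2 = ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
          (ni + nj + nk)
      )
    }
    size[i] <- ni + nj
    node[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
  }

  out <- list(merge = merge, height = height,
              order = dendrogram_order(merge, n), labels = labels,
              method = method)
  class(out) <- "phage_dendrogram"
  out
}

# leaf order for plotting, by recursive left-to-right traversal
dendrogram_order <- function(merge, n) {
  if (n == 1L) return(1L)
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.phage_dendrogram <- function(x, ...) {
  cat("<phage_dendrogram>", length(x$labels), "leaves,", x$method,
      "linkage; merge heights",
      paste(signif(range(x$height), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Convert a phage_dendrogram to an hclust object
#'
#' @param x A `phage_dendrogram`.
#' @param ... Unused.
#' @return A [stats::hclust] object.
#' @exportS3Method stats::as.hclust
as.hclust.phage_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into a partition
#'
#' @param dendrogram A `phage_dendrogram`.
#' @param k Number of clusters (exclusive with `h`).
#' @param h Cut height (exclusive with `k`).
#' @return Tibble with columns `genome_id` and `cluster` (integer labels).
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) {
    stop("supply exactly one of `k` or `h`", call. = FALSE)
  }
  n <- length(dendrogram$labels)
  if (!is.null(k)) {
    if (k > n) stop("`k` cannot exceed the number of leaves", call. = FALSE)
    if (n == 1L) {
      return(tibble::tibble(genome_id = dendrogram$labels, cluster = 1L))
    }
    cl <- stats::cutree(stats::as.hclust(dendrogram), k = k)
  } else {
    if (n == 1L) {
      return(tibble::tibble(genome_id = dendrogram$labels, cluster = 1L))
    }
    cl <- stats::cutree(stats::as.hclust(dendrogram), h = h)
  }
  tibble::tibble(genome_id = names(cl), cluster = unname(cl))
}

# quote a Newick label if it contains structural characters
newick_escape <- function(x) {
  needs <- stringr::str_detect(x, "[\\s,;:()\\[\\]']")
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a dendrogram as a rooted Newick string
#'
#' Branch lengths are differences of merge heights, so each leaf sits at
#' depth equal to the root merge height (an ultrametric tree). Two leaves
#' `A`, `B` merged at height `h` give `"(A:h,B:h);"`.
#'
#' @param dendrogram A `phage_dendrogram`.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by `";"`.
#' @export
to_newick <- function(dendrogram, digits = 10) {
  stopifnot(inherits(dendrogram, "phage_dendrogram"))
  labs <- newick_escape(dendrogram$labels)
  n <- length(labs)
  if (n == 1L) return(paste0(labs, ";"))
  fmt <- function(x) sprintf("%.*g", digits, x)
  node <- function(i, parent_h) {
    if (i < 0) return(paste0(labs[-i], ":", fmt(parent_h)))
    h <- dendrogram$height[i]
    paste0("(", node(dendrogram$merge[i, 1], h), ",",
           node(dendrogram$merge[i, 2], h), ")",
           if (!is.na(parent_h)) paste0(":", fmt(parent_h - h)) else "")
  }
  root <- nrow(dendrogram$merge)
  h <- dendrogram$height[root]
  paste0("(", node(dendrogram$merge[root, 1], h), ",",
         node(dendrogram$merge[root, 2], h), ");")
}
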