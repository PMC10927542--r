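# Monomer-UMI baseline methods used for benchmarking: trimer-to-monomer
# collapse by first or random base, the directional network deduplication of
# UMI-tools, and naive distinct counting.

#' Collapse a homotrimer UMI by its first base per block
#'
#' The monomer-baseline convention: each trimer block contributes its first
#' base, ignoring within-block evidence. Identical to [majority_collapse()]
#' on unanimous blocks.
#'
#' @param umi Character vector of homotrimer sequences.
#' @return Character vector of monomer UMIs.
#' @examples
#' collapse_first_base("TAAGGGCCC")  # "TGC"
#' @export
collapse_first_base <- function(umi) {
  umi <- .validate_trimer(umi)
  if (length(umi) == 0L) return(character(0))
  out <- character(length(umi))
  for (idx in split(seq_along(umi), nchar(umi))) {
    M <- .char_matrix(umi[idx])
    first_cols <- seq(1L, ncol(M), by = 3L)
    Mf <- M[, first_cols, drop = FALSE]
    out[idx] <- do.call(paste0, as.data.frame(Mf, stringsAsFactors = FALSE))
  }
  out
}

#' Collapse a homotrimer UMI by a random base per block
#'
#' Each block contributes the base at a uniformly chosen position (so a
#' two-of-three block yields its majority base with probability 2/3).
#' Deterministic given \code{seed}.
#'
#' @param umi Character vector of homotrimer sequences.
#' @param seed Optional integer seed.
#' @return Character vector of monomer UMIs.
#' @export
collapse_random_base <- function(umi, seed = NULL) {
  umi <- .validate_trimer(umi)
  if (length(umi) == 0L) return(character(0))
  if (!is.null(seed)) set.seed(seed)
  out <- character(length(umi))
  for (idx in split(seq_along(umi), nchar(umi))) {
    M <- .char_matrix(umi[idx])
    B <- ncol(M) %/% 3L
    n <- nrow(M)
    picks <- matrix(sample.int(3L, n * B, replace = TRUE), n, B)
    cols <- sweep(picks, 2L, 3L * (seq_len(B) - 1L), "+")
    sel <- matrix(M[cbind(rep(seq_len(n), B), as.vector(cols))], n, B)
    out[idx] <- do.call(paste0, as.data.frame(sel, stringsAsFactors = FALSE))
  }
  out
}

#' Directional network deduplication of monomer UMI counts
#'
#' The network-collapse rule: a directed edge runs from UMI \code{u} to UMI
#' \code{v} when their Hamming distance is 1 and
#' \code{count(u) >= 2 * count(v) - 1}. Each connected cluster grown from the
#' highest-count unvisited node (descending count, lexicographic tie-break)
#' counts as one molecule.
#'
#' @param counts Named integer vector or \code{table}: monomer UMI -> read
#'   count.
#' @param return_roots If \code{TRUE}, return the character vector of cluster
#'   root UMIs instead of their number.
#' @return Integer molecule count, or root UMIs when
#'   \code{return_roots = TRUE}.
#' @examples
#' directional_dedup(c(AAAA = 100, AAAT = 1))  # 1
#' directional_dedup(c(AAAA = 5, AAAT = 5))    # 2
#' @export
directional_dedup <- function(counts, return_roots = FALSE) {
  counts <- unclass(counts)
  umis <- names(counts)
  if (is.null(umis) || length(umis) == 0L)
    stop("counts must be a non-empty named vector of UMI read counts")
  cnt <- as.integer(counts)
  ord <- order(-cnt, umis)  # visit order: descending count, then lexicographic
  n <- length(umis)
  # adjacency under the directional rule
  adj <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (nchar(umis[i]) != nchar(umis[j])) next
        if (hamming(umis[i], umis[j]) == 1L) {
          if (cnt[i] >= 2L * cnt[j] - 1L) adj[[i]] <- c(adj[[i]], j)
          if (cnt[j] >= 2L * cnt[i] - 1L) adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  visited <- logical(n)
  roots <- character(0)
  for (i in ord) {
    if (visited[i]) next
    roots <- c(roots, umis[i])
    queue <- i
    visited[i] <- TRUE
    while (length(queue)) {
      node <- queue[[1L]]
      queue <- queue[-1L]
      for (nb in adj[[node]]) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (return_roots) roots else length(roots)
}

#' Count distinct monomer UMIs (naive lower-bound baseline)
#'
#' @param counts Named vector or \code{table} of monomer UMI read counts, or
#'   a plain character vector of monomer UMIs.
#' @return Integer number of distinct UMIs.
#' @export
naive_unique <- function(counts) {
  if (is.character(counts)) return(length(unique(counts)))
  length(unique(names(unclass(counts))))
}
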