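# Shared fixtures and independent oracles for the test suite.

BASES <- c("A", "C", "G", "T")

random_monomer <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# Substitute the base at position `pos` with a different one (or `to`).
substitute_base <- function(seq, pos, to = NULL) {
  cur <- substr(seq, pos, pos)
  if (is.null(to)) to <- sample(setdiff(BASES, cur), 1)
  substr(seq, pos, pos) <- to
  seq
}

# Inject n_block_errors single substitutions into distinct trimer blocks.
mutate_blocks <- function(trimer, n_block_errors) {
  B <- nchar(trimer) %/% 3L
  n_block_errors <- min(n_block_errors, B)
  blocks <- sample.int(B, n_block_errors)
  for (b in blocks) {
    pos <- 3L * (b - 1L) + sample.int(3L, 1L)
    trimer <- substitute_base(trimer, pos)
  }
  trimer
}

# Independent per-UMI error recount: split into blocks with substring and
# count 3 - max base multiplicity per block, without the package's vote code.
oracle_count_errors <- function(umi) {
  B <- nchar(umi) %/% 3L
  total <- 0L
  for (b in seq_len(B)) {
    blk <- substr(umi, 3L * b - 2L, 3L * b)
    ch <- strsplit(blk, "")[[1]]
    mult <- max(table(factor(ch, levels = BASES)))
    total <- total + (3L - mult)
  }
  total
}

# Brute-force candidate enumeration: per block, the distinct occurring bases;
# full Cartesian product assembled by string concatenation loops.
oracle_candidates <- function(umi) {
  B <- nchar(umi) %/% 3L
  out <- ""
  for (b in seq_len(B)) {
    blk <- strsplit(substr(umi, 3L * b - 2L, 3L * b), "")[[1]]
    occ <- sort(unique(blk[blk %in% BASES]))
    out <- as.vector(outer(out, occ, paste0))
  }
  sort(out)
}

# Brute-force minimum set cover: enumerate all subsets of the candidate pool
# by increasing size and return the first that covers every member.
oracle_min_cover_size <- function(members) {
  cands <- sort(unique(unlist(lapply(members, oracle_candidates))))
  covers <- lapply(cands, function(cn) {
    which(vapply(members, function(m) cn %in% oracle_candidates(m),
                 logical(1)))
  })
  n <- length(members)
  for (k in seq_along(cands)) {
    combs <- utils::combn(length(cands), k, simplify = FALSE)
    for (cb in combs) {
      if (length(unique(unlist(covers[cb]))) == n) return(k)
    }
  }
  stop("unreachable: members always self-coverable")
}

# Brute-force leftmost approximate anchor match (sliding-window Hamming).
oracle_find_anchor <- function(seq, anchor, max_mismatch) {
  L <- nchar(anchor)
  n <- nchar(seq)
  if (L > n) return(NA_integer_)
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(anchor, "")[[1]]
  for (i in seq_len(n - L + 1L)) {
    if (sum(sc[i:(i + L - 1L)] != ac) <= max_mismatch) return(i)
  }
  NA_integer_
}

# Random small set-cover group: n_umis homotrimer UMIs of B blocks with up to
# max_err block errors each (single substitutions in distinct blocks).
random_group <- function(n_umis, B, max_err = 3L) {
  vapply(seq_len(n_umis), function(i) {
    tri <- encode_homotrimer(random_monomer(B))
    mutate_blocks(tri, sample(0:min(max_err, B), 1L))
  }, character(1))
}
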