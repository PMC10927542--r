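# Homotrimer UMI codec: encoding, majority-vote collapse, per-block error
# counting and read filtering. A homotrimer UMI writes each monomer base three
# times ("GACT" -> "GGGAAACCCTTT"); within-block disagreement
# exposes substitution errors and a majority vote repairs them.

DNA_BASES <- c("A", "C", "G", "T")

#' Encode a monomer UMI as a homotrimer sequence
#'
#' Each base \code{b} of the monomer becomes the trimer block \code{"bbb"},
#' so a monomer of length \code{B} encodes to a sequence of length
#' \code{3 * B}. This is the inverse of [majority_collapse()] on error-free
#' reads, and is what the simulator and fixture builders use to construct
#' ground-truth homotrimer UMIs.
#'
#' @param monomer Character vector of monomer UMIs over A/C/G/T
#'   (lowercase accepted).
#' @return Character vector of homotrimer sequences, same length as input.
#' @examples
#' encode_homotrimer("GACT")  # "GGGAAACCCTTT"
#' @export
encode_homotrimer <- function(monomer) {
  monomer <- toupper(as.character(monomer))
  if (length(monomer) == 0L) return(character(0))
  if (any(is.na(monomer)) || any(nchar(monomer) == 0L))
    stop("monomer UMIs must be non-empty strings")
  if (any(grepl("[^ACGT]", monomer)))
    stop("monomer UMIs must contain only A, C, G, T")
  vapply(strsplit(monomer, "", fixed = TRUE),
         function(ch) paste(strrep(ch, 3L), collapse = ""),
         character(1))
}

# Split equal-length homotrimer sequences into an n x 3B character matrix.
# Validates length divisibility; mixed lengths are handled by callers.
.char_matrix <- function(x) {
  n <- length(x)
  L <- nchar(x[1L])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

# Per-block vote over an n x 3B char matrix. Returns list with:
#   vote   n x B matrix (NA where no base reaches multiplicity 2)
#   errors n x B integer matrix (3 - modal ACGT multiplicity)
# Non-ACGT characters (N, other IUPAC) never count toward a majority.
.block_vote_matrix <- function(M) {
  n <- nrow(M)
  B <- ncol(M) %/% 3L
  vote <- matrix(NA_character_, n, B)
  errors <- matrix(3L, n, B)
  for (j in seq_len(B)) {
    a <- M[, 3L * j - 2L]
    b <- M[, 3L * j - 1L]
    c <- M[, 3L * j]
    best_mult <- integer(n)
    best_base <- rep(NA_character_, n)
    for (base in DNA_BASES) {
      mult <- (a == base) + (b == base) + (c == base)
      upd <- mult > best_mult
      best_mult[upd] <- mult[upd]
      best_base[upd] <- base
    }
    errors[, j] <- 3L - best_mult
    conclusive <- best_mult >= 2L
    vote[conclusive, j] <- best_base[conclusive]
  }
  list(vote = vote, errors = errors)
}

.validate_trimer <- function(umi) {
  umi <- toupper(as.character(umi))
  bad <- is.na(umi) | nchar(umi) == 0L | nchar(umi) %% 3L != 0L
  if (any(bad))
    stop("homotrimer sequences must be non-empty with length divisible by 3")
  umi
}

#' Majority vote within a single trimer block
#'
#' A block votes for its modal base when that base occurs at least twice; a
#' block of three distinct bases is inconclusive. The per-block error count is
#' \code{3 - modal multiplicity}: 0 for a unanimous block, 1 when two of three
#' bases agree, 2 when all three differ -- the minimum number of substitutions
#' needed to make the block unanimous.
#'
#' @param block Character vector of 3-character blocks.
#' @return A data.frame with columns \code{base} (the winning base,
#'   \code{NA} for inconclusive blocks) and \code{errors}.
#' @examples
#' block_vote(c("AAA", "AAT", "ACT"))
#' @export
block_vote <- function(block) {
  block <- toupper(as.character(block))
  if (any(nchar(block) != 3L))
    stop("trimer blocks must have exactly 3 characters")
  if (length(block) == 0L)
    return(data.frame(base = character(0), errors = integer(0)))
  bv <- .block_vote_matrix(.char_matrix(block))
  data.frame(base = bv$vote[, 1L], errors = bv$errors[, 1L],
             stringsAsFactors = FALSE)
}

#' Collapse homotrimer UMIs to monomers by majority vote
#'
#' Each trimer block collapses to its modal base. Blocks with three distinct
#' bases are inconclusive; what happens then is caller-selectable because the
#' two downstream consumers differ: the simulator evaluation picks a random
#' occurring base, while the deduplication pipeline routes whole groups with
#' inconclusive members to the set-cover solver instead.
#'
#' @param umi Character vector of homotrimer sequences (length divisible
#'   by 3).
#' @param inconclusive One of \code{"na"} (default: return \code{NA} for that
#'   UMI so the caller can route it elsewhere) or \code{"random"} (pick one of
#'   the three occurring bases uniformly).
#' @param seed Optional integer seed used only when
#'   \code{inconclusive = "random"}.
#' @return Character vector of collapsed monomer UMIs (with \code{NA} where a
#'   block was inconclusive and \code{inconclusive = "na"}).
#' @examples
#' majority_collapse("GGGAAACCCTTTGGGCCCTTTAAACCCTTT")  # "GACTGCTACT"
#' majority_collapse("GGAAAACCC")                       # "GAC"
#' @export
majority_collapse <- function(umi, inconclusive = c("na", "random"),
                              seed = NULL) {
  inconclusive <- match.arg(inconclusive)
  umi <- .validate_trimer(umi)
  if (length(umi) == 0L) return(character(0))
  if (!is.null(seed)) set.seed(seed)
  out <- rep(NA_character_, length(umi))
  for (idx in split(seq_along(umi), nchar(umi))) {
    M <- .char_matrix(umi[idx])
    bv <- .block_vote_matrix(M)
    vote <- bv$vote
    if (inconclusive == "random" && anyNA(vote)) {
      holes <- which(is.na(vote), arr.ind = TRUE)
      for (h in seq_len(nrow(holes))) {
        i <- holes[h, 1L]; j <- holes[h, 2L]
        occ <- unique(M[i, (3L * j - 2L):(3L * j)])
        occ <- occ[occ %in% DNA_BASES]
        vote[i, j] <- if (length(occ)) sample(occ, 1L) else NA_character_
      }
    }
    collapsed <- apply(vote, 1L, function(r) {
      if (anyNA(r)) NA_character_ else paste(r, collapse = "")
    })
    out[idx] <- collapsed
  }
  out
}

#' Count substitution errors in homotrimer UMIs
#'
#' The per-block error count is \code{3 - modal multiplicity} (unanimous = 0,
#' two-of-three = 1, all distinct = 2), summed over blocks: the minimum number
#' of base substitutions that would make every block unanimous. This is the
#' metric behind the read filters (more than 3 errors for the set-cover path,
#' more than 5 for the bulk long-read path).
#'
#' @param umi Character vector of homotrimer sequences.
#' @return Integer vector of error counts.
#' @examples
#' count_umi_errors(encode_homotrimer("GACT"))  # 0
#' count_umi_errors("AATACTGGG")                # 1 + 2 + 0 = 3
#' @export
count_umi_errors <- function(umi) {
  umi <- .validate_trimer(umi)
  if (length(umi) == 0L) return(integer(0))
  out <- integer(length(umi))
  for (idx in split(seq_along(umi), nchar(umi))) {
    bv <- .block_vote_matrix(.char_matrix(umi[idx]))
    out[idx] <- as.integer(rowSums(bv$errors))
  }
  out
}

#' Filter homotrimer UMIs by error load
#'
#' Partitions UMIs into those with at most \code{max_errors} block errors
#' (kept) and the rest (dropped), preserving input order within each part.
#'
#' @param umi Character vector of homotrimer sequences.
#' @param max_errors Maximum tolerated error count (3 for set-cover
#'   deduplication, 5 for the bulk long-read pipeline).
#' @return List with elements \code{kept}, \code{dropped} (character vectors)
#'   and the corresponding index vectors \code{kept_idx}, \code{dropped_idx}.
#' @export
filter_umis <- function(umi, max_errors = 3L) {
  stopifnot(length(max_errors) == 1L, max_errors >= 0)
  umi <- .validate_trimer(umi)
  err <- count_umi_errors(umi)
  keep <- err <= max_errors
  list(kept = umi[keep], dropped = umi[!keep],
       kept_idx = which(keep), dropped_idx = which(!keep))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character vectors of equal-length strings (recycled pairwise).
#' @return Integer vector of per-pair substitution distances.
#' @examples
#' hamming("GACT", "CTGA")  # 4
#' @export
hamming <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming distance requires equal-length sequences")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Re-segment an indel-bearing read segment into trimer blocks
#'
#' Long-read platforms introduce indels, so the extracted UMI segment may not
#' have length exactly \code{3 * B}. This pre-step partitions the raw segment
#' into \code{B} consecutive chunks of length 2--4 (nominally 3), choosing the
#' partition that minimizes total disagreement: per chunk, the number of
#' characters differing from the chunk's modal base plus the deviation of the
#' chunk length from 3. Chunks are then padded/truncated to canonical trimer
#' blocks (a 2-chunk is padded with its modal base; a 4-chunk keeps the three
#' copies of its modal base plus remaining characters up to 3).
#'
#' @param segment Character vector of raw extracted segments.
#' @param n_blocks Number of trimer blocks B the segment should contain.
#' @param max_indels Maximum tolerated total length deviation from
#'   \code{3 * n_blocks} (default 2).
#' @return Character vector of re-segmented homotrimer sequences of length
#'   \code{3 * n_blocks}, or \code{NA} where the segment cannot be
#'   re-segmented within the indel budget.
#' @export
resegment_trimers <- function(segment, n_blocks, max_indels = 2L) {
  segment <- toupper(as.character(segment))
  vapply(segment, function(s) .resegment_one(s, n_blocks, max_indels),
         character(1), USE.NAMES = FALSE)
}

.chunk_cost <- function(ch) {
  tab <- table(factor(ch, levels = DNA_BASES))
  mism <- length(ch) - max(tab)
  mism + abs(length(ch) - 3L)
}

.chunk_modal <- function(ch) {
  tab <- table(factor(ch, levels = DNA_BASES))
  DNA_BASES[which.max(tab)]
}

.resegment_one <- function(s, B, max_indels) {
  if (is.na(s)) return(NA_character_)
  n <- nchar(s)
  if (abs(n - 3L * B) > max_indels) return(NA_character_)
  if (n == 3L * B && !grepl("[^ACGTN]", s)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sizes <- 2:4
  INF <- .Machine$integer.max %/% 4L
  # f[i+1, b+1] = min cost of splitting first i chars into b chunks
  f <- matrix(INF, n + 1L, B + 1L)
  back <- matrix(0L, n + 1L, B + 1L)
  f[1L, 1L] <- 0L
  for (b in seq_len(B)) {
    for (i in seq_len(n)) {
      for (k in sizes) {
        if (i - k < 0L) next
        prev <- f[i - k + 1L, b]
        if (prev >= INF) next
        cost <- prev + .chunk_cost(ch[(i - k + 1L):i])
        if (cost < f[i + 1L, b + 1L]) {
          f[i + 1L, b + 1L] <- cost
          back[i + 1L, b + 1L] <- k
        }
      }
    }
  }
  if (f[n + 1L, B + 1L] >= INF) return(NA_character_)
  # trace back chunk sizes, then canonicalize each chunk to a trimer
  ends <- integer(B)
  i <- n
  for (b in B:1) {
    k <- back[i + 1L, b + 1L]
    ends[b] <- i
    i <- i - k
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- character(B)
  for (b in seq_len(B)) {
    chunk <- ch[starts[b]:ends[b]]
    m <- .chunk_modal(chunk)
    if (length(chunk) == 3L) {
      blocks[b] <- paste(chunk, collapse = "")
    } else if (length(chunk) < 3L) {
      blocks[b] <- paste(c(chunk, rep(m, 3L - length(chunk))), collapse = "")
    } else {
      keep <- c(chunk[chunk == m][seq_len(min(3L, sum(chunk == m)))],
                chunk[chunk != m])
      blocks[b] <- paste(keep[1:3], collapse = "")
    }
  }
  paste(blocks, collapse = "")
}
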