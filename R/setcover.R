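# Set-cover deduplication of homotrimer UMIs. For a gene's multiset S of
# sequenced homotrimer UMIs, every s yields a candidate set C(s): the monomer
# sequences obtainable by picking, in each trimer block, one of the bases that
# occurs there. The smallest set of monomers whose candidate sets jointly
# cover S is the molecule-count estimate. A greedy solver (logarithmic
# approximation guarantee) serves production; an exact branch-and-bound
# solver acts as the small-instance oracle.

#' Enumerate candidate monomer collapses of a homotrimer UMI
#'
#' The Cartesian product, over trimer blocks, of the distinct A/C/G/T bases
#' occurring in each block. An error-free block contributes one base; a
#' two-of-three block contributes two; an all-distinct block contributes
#' three. Reads that pass the 3-error filter therefore yield at most
#' \code{3^3 = 27} candidates.
#'
#' @param umi A single homotrimer sequence.
#' @param cap Maximum number of candidates to enumerate; above this the read
#'   is considered unusable and \code{NULL} is returned with a warning.
#' @return Sorted character vector of candidate monomer UMIs, or \code{NULL}
#'   when the product exceeds \code{cap}.
#' @examples
#' candidate_collapses("AATCCC")  # "AC", "TC"
#' @export
candidate_collapses <- function(umi, cap = 4096L) {
  umi <- .validate_trimer(umi)
  stopifnot(length(umi) == 1L)
  M <- .char_matrix(umi)
  B <- ncol(M) %/% 3L
  per_block <- vector("list", B)
  n_cand <- 1
  for (j in seq_len(B)) {
    occ <- unique(M[1L, (3L * j - 2L):(3L * j)])
    occ <- sort(occ[occ %in% DNA_BASES])
    if (length(occ) == 0L) return(NULL)  # block with no usable base
    per_block[[j]] <- occ
    n_cand <- n_cand * length(occ)
  }
  if (n_cand > cap) {
    warning("candidate enumeration for read exceeds cap (", n_cand, " > ",
            cap, "); read dropped")
    return(NULL)
  }
  grid <- do.call(expand.grid,
                  c(rev(per_block),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  sort(do.call(paste0, rev(grid)))
}

#' Build the candidate map S_c for a group of homotrimer UMIs
#'
#' Coverage is evaluated over distinct raw UMI strings (read duplicates are
#' automatically covered by whichever monomer explains their shared string).
#'
#' @param umis Character vector of homotrimer UMIs for one group (gene, or
#'   cell-gene pair); duplicates allowed.
#' @param cap Per-read candidate enumeration cap passed to
#'   [candidate_collapses()].
#' @return Object of class \code{candidate_map}: list with \code{members}
#'   (distinct UMI strings), \code{multiplicity} (read counts per member),
#'   \code{map} (named list: candidate monomer -> integer indices of members
#'   it explains) and \code{dropped} (members dropped by the cap).
#' @export
build_candidate_map <- function(umis, cap = 4096L) {
  umis <- .validate_trimer(umis)
  tab <- table(umis)
  members <- names(tab)
  cand <- lapply(members, candidate_collapses, cap = cap)
  dropped <- members[vapply(cand, is.null, logical(1))]
  keep <- !vapply(cand, is.null, logical(1))
  members <- members[keep]
  cand <- cand[keep]
  map <- list()
  for (i in seq_along(members)) {
    for (c_seq in cand[[i]]) {
      map[[c_seq]] <- c(map[[c_seq]], i)
    }
  }
  structure(list(members = members,
                 multiplicity = as.integer(tab)[keep],
                 map = map,
                 dropped = dropped),
            class = "candidate_map")
}

#' @export
print.candidate_map <- function(x, ...) {
  cat("candidate_map:", length(x$members), "distinct UMIs,",
      length(x$map), "candidate monomers\n")
  invisible(x)
}

.cover_solution <- function(chosen, assignment, members, optimal) {
  structure(list(chosen = chosen,
                 assignment = assignment,
                 members = members,
                 molecule_count = length(chosen),
                 optimal = optimal),
            class = "cover_solution")
}

#' @export
print.cover_solution <- function(x, ...) {
  cat("cover_solution:", x$molecule_count, "molecules",
      if (x$optimal) "(exact)" else "(greedy)", "\n")
  invisible(x)
}

#' Greedy set cover over a candidate map
#'
#' Starts from the empty set and repeatedly adds the candidate monomer that
#' explains the largest number of still-unexplained UMIs; ties are broken by
#' the lexicographically smallest candidate sequence, making the result
#' deterministic. The solution size is guaranteed within a factor
#' \code{ln(|S|) + 1} of the optimum.
#'
#' @param cmap A \code{candidate_map} from [build_candidate_map()].
#' @return A \code{cover_solution} with the chosen monomers, a member ->
#'   monomer assignment, and \code{molecule_count}.
#' @export
greedy_cover <- function(cmap) {
  stopifnot(inherits(cmap, "candidate_map"))
  n <- length(cmap$members)
  if (n == 0L)
    return(.cover_solution(character(0), character(0), character(0), FALSE))
  cand_names <- sort(names(cmap$map))  # lexicographic tie-break
  covered <- logical(n)
  chosen <- character(0)
  assignment <- rep(NA_character_, n)
  while (!all(covered)) {
    gains <- vapply(cand_names,
                    function(cn) sum(!covered[cmap$map[[cn]]]),
                    integer(1))
    best <- cand_names[which.max(gains)]  # first max = lexicographically least
    if (gains[[best]] == 0L)
      stop("candidate map does not cover all members")  # violated invariant
    newly <- cmap$map[[best]][!covered[cmap$map[[best]]]]
    assignment[newly] <- best
    covered[cmap$map[[best]]] <- TRUE
    chosen <- c(chosen, best)
  }
  names(assignment) <- cmap$members
  .cover_solution(chosen, assignment, cmap$members, FALSE)
}

#' Exact minimum set cover (small-instance oracle)
#'
#' Branch-and-bound search that provably finds a minimum-cardinality cover.
#' Dominated candidates (coverage a subset of another's) are pruned first;
#' branching is on the uncovered member with the fewest remaining candidates.
#' Intended as a validation oracle for [greedy_cover()], not for production;
#' instances above \code{limit} distinct members are refused.
#'
#' @param cmap A \code{candidate_map}.
#' @param limit Maximum number of distinct members (default 20).
#' @return A \code{cover_solution} with \code{optimal = TRUE}.
#' @export
exact_cover <- function(cmap, limit = 20L) {
  stopifnot(inherits(cmap, "candidate_map"))
  n <- length(cmap$members)
  if (n == 0L)
    return(.cover_solution(character(0), character(0), character(0), TRUE))
  if (n > limit)
    stop("exact_cover is a small-instance oracle; ", n, " members > limit ",
         limit)
  cand_names <- sort(names(cmap$map))
  masks <- vapply(cand_names,
                  function(cn) sum(2^(cmap$map[[cn]] - 1L)),
                  numeric(1))
  # drop dominated candidates: a strict subset of another candidate's coverage
  # can never be needed in a minimum cover (keep the lexicographically first
  # among exact coverage duplicates)
  keep <- rep(TRUE, length(masks))
  for (i in seq_along(masks)) {
    if (!keep[i]) next
    for (j in seq_along(masks)) {
      if (i == j || !keep[j]) next
      superset <- bitwAnd2(masks[i], masks[j]) == masks[i]
      if (superset && (masks[j] != masks[i] || j < i)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cand_names <- cand_names[keep]
  masks <- masks[keep]
  full <- 2^n - 1
  ub <- greedy_cover(cmap)
  best <- ub$chosen
  member_cands <- lapply(seq_len(n), function(i) {
    which(vapply(cand_names, function(cn) i %in% cmap$map[[cn]], logical(1)))
  })
  search <- function(covered_mask, chosen_idx) {
    if (covered_mask == full) {
      if (length(chosen_idx) < length(best))
        best <<- cand_names[chosen_idx]
      return(invisible(NULL))
    }
    # adding one more candidate can at best tie the incumbent: prune
    if (length(chosen_idx) + 1L >= length(best)) return(invisible(NULL))
    uncovered <- which(covered_mask %/% 2^(seq_len(n) - 1L) %% 2 == 0)
    pick <- uncovered[which.min(lengths(member_cands[uncovered]))]
    for (ci in member_cands[[pick]]) {
      search(covered_mask + bitwAnd2(masks[ci], full - covered_mask),
             c(chosen_idx, ci))
    }
    invisible(NULL)
  }
  search(0, integer(0))
  chosen <- sort(best)
  assignment <- rep(NA_character_, n)
  for (cn in chosen) {
    idx <- cmap$map[[cn]]
    assignment[idx][is.na(assignment[idx])] <- cn
  }
  names(assignment) <- cmap$members
  .cover_solution(chosen, assignment, cmap$members, TRUE)
}

# Bitwise AND on coverage masks stored as doubles (n <= 30 members).
bitwAnd2 <- function(a, b) {
  r <- 0
  bit <- 1
  while (a > 0 && b > 0) {
    if (a %% 2 >= 1 && b %% 2 >= 1) r <- r + bit
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
  }
  r
}

#' Deduplicate one group of homotrimer UMIs
#'
#' The full per-gene pipeline: filter reads with more than \code{max_errors}
#' block errors; if every surviving UMI collapses conclusively (no block with
#' three distinct bases), count distinct majority-collapsed monomers; if at
#' least one trimer is inconclusive, stop treating UMIs independently and
#' solve the group's set-cover instance with the greedy algorithm.
#'
#' @param umis Character vector of homotrimer UMIs (reads) for one group.
#' @param max_errors Error filter threshold (default 3).
#' @param cap Candidate enumeration cap per read.
#' @param solver \code{"greedy"} (default) or \code{"exact"} for the oracle
#'   path on small groups.
#' @return List with \code{count} (molecule estimate), \code{method}
#'   (\code{"majority"} or \code{"setcover"}), \code{umis} (the collapsed
#'   monomers chosen), \code{solution} (the \code{cover_solution}, set-cover
#'   path only) and \code{n_filtered} (reads removed by the error filter).
#' @export
dedup_group <- function(umis, max_errors = 3L, cap = 4096L,
                        solver = c("greedy", "exact")) {
  solver <- match.arg(solver)
  flt <- filter_umis(umis, max_errors)
  if (length(flt$kept) == 0L) {
    warning("all reads in group removed by the error filter")
    return(list(count = 0L, method = "filtered", umis = character(0),
                solution = NULL, n_filtered = length(flt$dropped)))
  }
  collapsed <- majority_collapse(flt$kept, inconclusive = "na")
  if (!anyNA(collapsed)) {
    mono <- sort(unique(collapsed))
    return(list(count = length(mono), method = "majority", umis = mono,
                solution = NULL, n_filtered = length(flt$dropped)))
  }
  cmap <- build_candidate_map(flt$kept, cap = cap)
  sol <- if (solver == "exact") exact_cover(cmap) else greedy_cover(cmap)
  list(count = sol$molecule_count, method = "setcover", umis = sol$chosen,
       solution = sol, n_filtered = length(flt$dropped))
}

#' Deduplicate a table of gene-tagged reads into molecule counts
#'
#' Applies [dedup_group()] (or a baseline method) per group key. The group
#' key is the gene, or the cell barcode and gene jointly when a \code{cell}
#' column is present.
#'
#' @param reads A data.frame with columns \code{read_id}, \code{gene},
#'   \code{umi} and optionally \code{cell}. Rows with missing gene or UMI are
#'   skipped and counted.
#' @param method One of \code{"setcover"} (majority fast path + greedy set
#'   cover), \code{"majority"} (majority vote with random fallback),
#'   \code{"first-base-directional"}, \code{"random-base-directional"} or
#'   \code{"naive"} (distinct first-base monomers).
#' @param max_errors Error filter threshold for the homotrimer paths.
#' @param seed Seed for the random collapse and random fallback paths.
#' @return A data.frame with columns (\code{cell},) \code{gene},
#'   \code{count}; attribute \code{"skipped"} holds the number of skipped
#'   reads.
#' @importFrom data.table as.data.table
#' @export
dedup_table <- function(reads,
                        method = c("setcover", "majority",
                                   "first-base-directional",
                                   "random-base-directional", "naive"),
                        max_errors = 3L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(reads),
            all(c("read_id", "gene", "umi") %in% names(reads)))
  if (!is.null(seed)) set.seed(seed)
  has_cell <- "cell" %in% names(reads)
  dt <- data.table::as.data.table(reads)
  ok <- !is.na(dt$gene) & dt$gene != "" & !is.na(dt$umi) & dt$umi != ""
  skipped <- sum(!ok)
  dt <- dt[ok]
  if (nrow(dt) == 0L) {
    out <- if (has_cell) {
      data.frame(cell = character(0), gene = character(0),
                 count = integer(0))
    } else {
      data.frame(gene = character(0), count = integer(0))
    }
    attr(out, "skipped") <- skipped
    return(out)
  }
  keys <- if (has_cell) c("cell", "gene") else "gene"
  count_one <- function(u) .count_group(u, method, max_errors)
  res <- dt[, list(count = count_one(umi)), by = keys]
  out <- as.data.frame(res)
  attr(out, "skipped") <- skipped
  out
}

.count_group <- function(umis, method, max_errors) {
  switch(method,
    "setcover" = dedup_group(umis, max_errors = max_errors)$count,
    "majority" = {
      flt <- filter_umis(umis, max_errors)
      if (length(flt$kept) == 0L) return(0L)
      length(unique(majority_collapse(flt$kept, inconclusive = "random")))
    },
    "first-base-directional" =
      directional_dedup(table(collapse_first_base(umis))),
    "random-base-directional" =
      directional_dedup(table(collapse_random_base(umis))),
    "naive" = length(unique(collapse_first_base(umis)))
  )
}
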