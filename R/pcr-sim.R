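# Galton-Watson simulator of PCR amplification and sequencing of UMI-tagged
# molecules. Per cycle, the number of amplified reads n ~ Binom(m, alpha) and
# the pool grows as m' = m + n; base errors on the newly synthesized copies
# are drawn as v ~ NBinom(r, q) with q = 1 - P_e and r = q * t, where t is the
# number of bases synthesized that cycle, so E[v] = t * P_e. Sequencing is a
# subsample to depth with the same substitution-error machinery.

#' Simulation configuration
#'
#' Defaults follow the simulation settings used throughout: 50 true molecules
#' with 12-base monomer UMIs (36-base homotrimers), 12 PCR cycles at an
#' amplification rate of 0.85 (middle of the stated 0.8--1.0 range),
#' sequencing depth 400, PCR error rate 3.6e-6, sequencing error rate 1e-3,
#' and 50 replicate permutations.
#'
#' @param umi_num Number of true molecules (distinct tagged transcripts).
#' @param umi_len Monomer UMI length B (a homotrimer UMI has 3*B bases).
#' @param trimer Encode UMIs as homotrimers (\code{TRUE}) or plain monomers.
#' @param ampl_rate Per-read amplification probability alpha per PCR cycle.
#' @param pcr_err Per-base PCR substitution error probability P_e.
#' @param seq_err Per-base sequencing substitution error probability.
#' @param pcr_cycles Number of PCR cycles.
#' @param seq_depth Number of reads sampled at sequencing.
#' @param perm_num Number of independent replicates.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(umi_num = 50L, umi_len = 12L, trimer = TRUE,
                       ampl_rate = 0.85, pcr_err = 3.6e-6, seq_err = 1e-3,
                       pcr_cycles = 12L, seq_depth = 400L, perm_num = 50L,
                       seed = 1L) {
  stopifnot(umi_num >= 1L, umi_len >= 1L, pcr_cycles >= 0L, seq_depth >= 1L,
            perm_num >= 1L,
            ampl_rate >= 0, ampl_rate <= 1,
            pcr_err >= 0, pcr_err < 1, seq_err >= 0, seq_err < 1)
  structure(list(umi_num = as.integer(umi_num),
                 umi_len = as.integer(umi_len),
                 trimer = isTRUE(trimer),
                 ampl_rate = ampl_rate, pcr_err = pcr_err, seq_err = seq_err,
                 pcr_cycles = as.integer(pcr_cycles),
                 seq_depth = as.integer(seq_depth),
                 perm_num = as.integer(perm_num),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the true UMI pool
#'
#' Draws \code{umi_num} random monomer UMIs of length \code{umi_len}
#' (uniform bases) and, in trimer mode, encodes each base as a homotrimer
#' block. Uniqueness is not enforced -- tags are sampled at random as on a
#' real bead -- but collisions are reported via the \code{"collisions"}
#' attribute.
#'
#' @param config A \code{sim_config} (or arguments via \code{...} given to
#'   [sim_config()]).
#' @return Character vector of \code{umi_num} UMI sequences with attributes
#'   \code{"monomer"} (the underlying monomer UMIs) and \code{"collisions"}.
#' @export
generate_true_umis <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mono <- vapply(seq_len(config$umi_num), function(i) {
    paste(sample(DNA_BASES, config$umi_len, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- if (config$trimer) encode_homotrimer(mono) else mono
  attr(seqs, "monomer") <- mono
  attr(seqs, "collisions") <- sum(duplicated(mono))
  seqs
}

# One molecule pool: parallel vectors (sequence, true molecule id, cycle of
# synthesis; cycle 0 = original molecules).
.new_pool <- function(seqs) {
  list(seq = as.character(seqs),
       origin = seq_along(seqs),
       birth = rep(0L, length(seqs)))
}

#' One PCR amplification cycle
#'
#' Draws \code{n ~ Binomial(m, alpha)}, picks n distinct template reads
#' uniformly without replacement, and appends one copy of each; the pool
#' grows to exactly \code{m + n}. Only the appended copies are eligible for
#' error injection (templates are never retouched).
#'
#' @param pool A pool as produced by [run_simulation()] internals: list with
#'   \code{seq}, \code{origin}, \code{birth}.
#' @param ampl_rate Amplification probability alpha.
#' @param cycle Cycle index recorded as the copies' birth cycle.
#' @return List with the grown \code{pool}, \code{n_new} (number of copies
#'   appended at the tail) and \code{stats} (one-row data.frame with
#'   \code{m_before}, \code{n_amplified}, \code{m_after}).
#' @export
amplify_cycle <- function(pool, ampl_rate, cycle = 1L) {
  m <- length(pool$seq)
  stopifnot(m >= 1L)
  n <- stats::rbinom(1L, m, ampl_rate)
  if (n > 0L) {
    idx <- sample.int(m, n)
    pool$seq <- c(pool$seq, pool$seq[idx])
    pool$origin <- c(pool$origin, pool$origin[idx])
    pool$birth <- c(pool$birth, rep(as.integer(cycle), n))
  }
  list(pool = pool, n_new = n,
       stats = data.frame(m_before = m, n_amplified = n, m_after = m + n))
}

#' Inject substitution errors into newly synthesized copies
#'
#' With \code{t} bases synthesized, the error count is drawn as
#' \code{v ~ NBinom(r, q)} with \code{q = 1 - p} and \code{r = q * t}
#' (failures-before-r-successes; the continuous-size parameterization of
#' \code{\link[stats]{rnbinom}} handles non-integer r), so
#' \code{E[v] = r(1-q)/q = t * p}. The v error positions are drawn uniformly
#' without replacement from the t bases (v is capped at t) and each hit base
#' is replaced by one of the other three bases uniformly.
#'
#' @param seqs Character vector of the copies to mutate.
#' @param p Per-base substitution error probability.
#' @return List with \code{seqs} (mutated copies) and \code{v} (number of
#'   errors injected).
#' @export
inject_errors <- function(seqs, p) {
  lens <- nchar(seqs)
  t <- sum(lens)
  if (t == 0L || p == 0) return(list(seqs = seqs, v = 0L))
  q <- 1 - p
  r <- q * t
  v <- stats::rnbinom(1L, size = r, prob = q)
  v <- min(v, t)
  if (v == 0L) return(list(seqs = seqs, v = 0L))
  pos <- sample.int(t, v)
  cs <- cumsum(lens)
  seq_idx <- findInterval(pos - 1L, cs) + 1L
  offset <- pos - c(0L, cs)[seq_idx]
  cur <- substring(seqs[seq_idx], offset, offset)
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  repl <- others[cbind(match(cur, rownames(others)),
                       sample.int(3L, v, replace = TRUE))]
  # non-ACGT hit (shouldn't occur in simulated pools): substitute uniformly
  repl[is.na(repl)] <- sample(DNA_BASES, sum(is.na(repl)), replace = TRUE)
  if (length(unique(lens)) == 1L) {
    hit <- unique(seq_idx)
    M <- .char_matrix(seqs[hit])
    row_of <- match(seq_idx, hit)
    M[cbind(row_of, offset)] <- repl
    seqs[hit] <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
  } else {
    for (k in seq_len(v)) {
      s <- seqs[seq_idx[k]]
      substr(s, offset[k], offset[k]) <- repl[k]
      seqs[seq_idx[k]] <- s
    }
  }
  list(seqs = seqs, v = as.integer(v))
}

#' Sample the amplified pool to sequencing depth and add sequencing errors
#'
#' Sampling is uniform without replacement when the requested depth does not
#' exceed the pool size, with replacement otherwise. Sequencing errors reuse
#' the negative-binomial substitution machinery of [inject_errors()] with the
#' sequencing error rate. Ground-truth molecule ids are carried through.
#'
#' @param pool Pool list (\code{seq}, \code{origin}, \code{birth}).
#' @param seq_depth Number of reads to emit.
#' @param seq_err Per-base sequencing error probability.
#' @return data.frame with columns \code{read_id}, \code{umi} (the observed,
#'   possibly erroneous sequence) and \code{true_id} (index of the true
#'   molecule).
#' @export
sequence_pool <- function(pool, seq_depth, seq_err) {
  m <- length(pool$seq)
  if (m == 0L) stop("cannot sequence an empty pool")
  idx <- if (seq_depth <= m) sample.int(m, seq_depth)
         else sample.int(m, seq_depth, replace = TRUE)
  inj <- inject_errors(pool$seq[idx], seq_err)
  data.frame(read_id = sprintf("read%d", seq_len(seq_depth)),
             umi = inj$seqs,
             true_id = pool$origin[idx],
             stringsAsFactors = FALSE)
}

#' Run the full PCR + sequencing simulation
#'
#' For each replicate: generate true UMIs, run \code{pcr_cycles} cycles of
#' amplification with PCR error injection on the new copies, then subsample
#' to sequencing depth with sequencing errors. All randomness flows from
#' \code{config$seed}, so runs are byte-reproducible.
#'
#' @param config A \code{sim_config}.
#' @return Object of class \code{umi_sim}: list with \code{config},
#'   \code{replicates} (each a list with \code{reads} -- the data.frame from
#'   [sequence_pool()] -- plus \code{true_umis}, \code{true_monomers},
#'   \code{cycle_stats}, \code{final_pool_size}).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  replicates <- vector("list", config$perm_num)
  for (rep_i in seq_len(config$perm_num)) {
    true_umis <- generate_true_umis(config)
    pool <- .new_pool(true_umis)
    u_cum <- 0L
    stats_rows <- vector("list", config$pcr_cycles)
    for (cyc in seq_len(config$pcr_cycles)) {
      amp <- amplify_cycle(pool, config$ampl_rate, cycle = cyc)
      pool <- amp$pool
      n_new <- amp$n_new
      t_bases <- 0L
      v <- 0L
      if (n_new > 0L) {
        tail_idx <- (length(pool$seq) - n_new + 1L):length(pool$seq)
        inj <- inject_errors(pool$seq[tail_idx], config$pcr_err)
        pool$seq[tail_idx] <- inj$seqs
        t_bases <- sum(nchar(inj$seqs))
        v <- inj$v
      }
      u_cum <- u_cum + v
      stats_rows[[cyc]] <- data.frame(
        cycle = cyc,
        m_before = amp$stats$m_before,
        n_amplified = n_new,
        m_after = amp$stats$m_after,
        t_bases = t_bases,
        v_errors = v,
        u_cumulative = u_cum,
        q = 1 - config$pcr_err,
        r = (1 - config$pcr_err) * t_bases)
    }
    reads <- sequence_pool(pool, config$seq_depth, config$seq_err)
    reads$read_id <- sprintf("rep%d_%s", rep_i, reads$read_id)
    replicates[[rep_i]] <- list(
      reads = reads,
      true_umis = as.character(true_umis),
      true_monomers = attr(true_umis, "monomer"),
      cycle_stats = do.call(rbind, stats_rows),
      final_pool_size = length(pool$seq))
  }
  structure(list(config = config, replicates = replicates),
            class = "umi_sim")
}

#' @export
print.umi_sim <- function(x, ...) {
  cat("umi_sim:", length(x$replicates), "replicate(s) of", x$config$umi_num,
      "molecules,", x$config$pcr_cycles, "PCR cycles, depth",
      x$config$seq_depth, "\n")
  invisible(x)
}

#' Marginal trajectory of pool sizes under the branching process
#'
#' Draws the pool-size chain \code{m' = m + Binomial(m, alpha)} for a number
#' of cycles without materializing sequences -- the count marginal of
#' [amplify_cycle()], useful for Monte Carlo checks of the branching mean
#' \code{E[m_c] = m0 * (1 + alpha)^c}.
#'
#' @param m0 Initial pool size.
#' @param ampl_rate Amplification probability alpha.
#' @param cycles Number of cycles.
#' @param reps Number of independent trajectories.
#' @return Integer matrix of dimension \code{reps x (cycles + 1)}; column
#'   \code{i} holds pool sizes after \code{i - 1} cycles.
#' @export
branching_trajectories <- function(m0, ampl_rate, cycles, reps = 1L) {
  m <- matrix(0L, reps, cycles + 1L)
  m[, 1L] <- as.integer(m0)
  for (cyc in seq_len(cycles)) {
    m[, cyc + 1L] <- m[, cyc] + stats::rbinom(reps, m[, cyc], ampl_rate)
  }
  m
}

#' Benchmark deduplication methods on simulated reads
#'
#' Each replicate's sequenced reads form one group (one gene); every method
#' estimates the molecule count and the estimate is compared with the known
#' number of simulated molecules.
#'
#' @param sim A \code{umi_sim} from [run_simulation()].
#' @param methods Character vector from \code{"naive"},
#'   \code{"directional"}, \code{"majority"}, \code{"setcover"}.
#'   \code{"naive"} counts distinct first-base-collapsed monomers;
#'   \code{"directional"} applies the network collapse to first-base
#'   monomers; \code{"majority"} counts distinct majority-vote monomers
#'   (random fallback for inconclusive blocks); \code{"setcover"} runs the
#'   homotrimer filter + majority fast path + greedy set cover.
#' @param max_errors Error filter for the homotrimer paths.
#' @param seed Seed for the random-fallback collapse.
#' @return data.frame with one row per replicate per method: \code{replicate},
#'   \code{method}, \code{estimate}, \code{truth}, \code{deviation},
#'   \code{recovered} (fraction of true distinct monomer UMIs present in the
#'   method's estimated UMI set).
#' @export
evaluate_methods <- function(sim,
                             methods = c("naive", "directional", "majority",
                                         "setcover"),
                             max_errors = 3L, seed = NULL) {
  stopifnot(inherits(sim, "umi_sim"))
  known <- c("naive", "directional", "majority", "setcover")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  trimer <- sim$config$trimer
  rows <- list()
  for (rep_i in seq_along(sim$replicates)) {
    rep_data <- sim$replicates[[rep_i]]
    umis <- rep_data$reads$umi
    true_set <- unique(if (trimer) rep_data$true_monomers
                       else rep_data$true_umis)
    truth <- sim$config$umi_num
    for (mth in methods) {
      est_set <- .estimate_umi_set(umis, mth, trimer, max_errors)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, method = mth,
        estimate = length(est_set), truth = truth,
        deviation = abs(length(est_set) - truth),
        recovered = length(intersect(est_set, true_set)) / length(true_set),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.estimate_umi_set <- function(umis, method, trimer, max_errors) {
  mono <- if (trimer) collapse_first_base(umis) else umis
  switch(method,
    "naive" = unique(mono),
    "directional" = directional_dedup(table(mono), return_roots = TRUE),
    "majority" = {
      if (!trimer) return(unique(umis))
      flt <- filter_umis(umis, max_errors)
      if (length(flt$kept) == 0L) return(character(0))
      unique(majority_collapse(flt$kept, inconclusive = "random"))
    },
    "setcover" = {
      if (!trimer) return(unique(umis))
      dedup_group(umis, max_errors = max_errors)$umis
    })
}
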