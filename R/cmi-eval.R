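# Spike-in CMI accuracy evaluation. A CMI (common molecular identifier) is a
# single known homotrimer sequence synthesized in place of a UMI on every
# molecule; any deviation of an observed CMI from the expected sequence is by
# construction an error, so the CMI gives experimental ground truth for both
# per-base accuracy and deduplication (the true per-gene molecule count of a
# CMI library is 1).

#' The homotrimer CMI spike-in sequence
#'
#' 30 bases, ten trimer blocks; collapses to the monomer
#' \code{"GACTGCTACT"}.
#' @export
CMI_TRIMER <- "GGGAAACCCTTTGGGCCCTTTAAACCCTTT"

#' Score observed CMI sequences against the expected spike-in
#'
#' Pre-correction accuracy is the fraction of reads whose observed CMI
#' matches the expected sequence exactly (Hamming distance 0). Post-correction
#' accuracy is the fraction whose majority-vote collapse equals the collapse
#' of the expected sequence -- i.e. reads whose errors the homotrimer vote
#' repairs. A histogram of Hamming distances is reported for the inexact
#' reads. Reads whose extracted CMI length differs from the expected length
#' are indel suspects: they are re-segmented with [resegment_trimers()] when
#' \code{resegment = TRUE}, otherwise excluded and tallied.
#'
#' @param cmi Character vector of observed CMI sequences.
#' @param expected Expected homotrimer CMI (default [CMI_TRIMER]).
#' @param resegment Attempt DP re-segmentation of length-mismatched reads.
#' @param max_indels Indel budget for re-segmentation.
#' @return Object of class \code{cmi_report}: list with \code{n_reads},
#'   \code{n_scored}, \code{n_indel_suspect}, \code{n_exact_pre},
#'   \code{n_exact_post}, \code{percent_correct_pre},
#'   \code{percent_correct_post} and \code{hamming_hist} (named integer
#'   vector, distance -> read count).
#' @export
score_cmi <- function(cmi, expected = CMI_TRIMER, resegment = FALSE,
                      max_indels = 2L) {
  expected <- toupper(expected)
  cmi <- toupper(as.character(cmi))
  n_reads <- length(cmi)
  B <- nchar(expected) %/% 3L
  len_ok <- !is.na(cmi) & nchar(cmi) == nchar(expected)
  n_indel <- sum(!len_ok)
  if (resegment && n_indel > 0L) {
    fixed <- resegment_trimers(cmi[!len_ok], B, max_indels)
    recovered <- !is.na(fixed)
    cmi[!len_ok][recovered] <- fixed[recovered]
    len_ok[!len_ok][recovered] <- TRUE
    n_indel <- sum(!len_ok)
  }
  scored <- cmi[len_ok]
  if (length(scored) == 0L) {
    rep0 <- structure(list(n_reads = n_reads, n_scored = 0L,
                           n_indel_suspect = n_indel,
                           n_exact_pre = 0L, n_exact_post = 0L,
                           percent_correct_pre = NA_real_,
                           percent_correct_post = NA_real_,
                           hamming_hist = integer(0)),
                      class = "cmi_report")
    return(rep0)
  }
  d <- hamming(scored, rep(expected, length(scored)))
  expected_mono <- majority_collapse(expected)
  post <- majority_collapse(scored, inconclusive = "na")
  exact_post <- !is.na(post) & post == expected_mono
  hist <- table(d)
  structure(list(n_reads = n_reads,
                 n_scored = length(scored),
                 n_indel_suspect = n_indel,
                 n_exact_pre = sum(d == 0L),
                 n_exact_post = sum(exact_post),
                 percent_correct_pre = 100 * mean(d == 0L),
                 percent_correct_post = 100 * mean(exact_post),
                 hamming_hist = stats::setNames(as.integer(hist),
                                                names(hist))),
            class = "cmi_report")
}

#' @export
print.cmi_report <- function(x, ...) {
  cat("cmi_report:", x$n_scored, "of", x$n_reads, "reads scored",
      sprintf("(%d indel-suspect)\n", x$n_indel_suspect))
  cat(sprintf("  exact pre-correction:  %.2f%%\n", x$percent_correct_pre))
  cat(sprintf("  exact post-correction: %.2f%%\n", x$percent_correct_post))
  invisible(x)
}

#' Per-gene molecule counts for a CMI library
#'
#' In a CMI library every molecule carries the same identifier, so the true
#' deduplicated count of every gene is 1; any count above 1 is an
#' overcounting error of the chosen method. Reports the per-gene counts and
#' the fraction of genes counted exactly once.
#'
#' @param reads data.frame with columns \code{read_id}, \code{gene},
#'   \code{umi} (the observed CMI), optionally \code{cell}.
#' @param method Deduplication method, as in [dedup_table()].
#' @param ... Passed to [dedup_table()].
#' @return data.frame of per-gene counts with attribute \code{"accuracy"}:
#'   fraction of genes with count exactly 1.
#' @export
per_gene_overcount <- function(reads, method = "setcover", ...) {
  counts <- dedup_table(reads, method = method, ...)
  attr(counts, "accuracy") <-
    if (nrow(counts)) mean(counts$count == 1L) else NA_real_
  counts
}
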