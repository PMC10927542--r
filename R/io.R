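# File I/O: FASTQ emission for simulated reads, tagged-read TSV, count
# tables (TSV and MatrixMarket sparse matrix with barcode/feature sidecars),
# and simulation bundles.

#' Write reads as FASTQ
#'
#' Sequences are written with a constant quality string (\code{"I"}, Q40),
#' as simulated reads carry no per-base quality model.
#'
#' @param ids,seqs Character vectors of read ids and sequences.
#' @param path Output path (\code{.gz} implies gzip compression).
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (gzip-aware).
#' @return data.frame with columns \code{id} and \code{seq}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a molecule count table as TSV
#'
#' @param counts data.frame from [dedup_table()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write single-cell counts as a MatrixMarket triplet matrix
#'
#' Emits \code{matrix.mtx} (genes x cells), \code{features.tsv} and
#' \code{barcodes.tsv} into \code{dir}.
#'
#' @param counts data.frame with columns \code{cell}, \code{gene},
#'   \code{count}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(all(c("cell", "gene", "count") %in% names(counts)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- sort(unique(counts$cell))
  genes <- sort(unique(counts$gene))
  m <- Matrix::sparseMatrix(i = match(counts$gene, genes),
                            j = match(counts$cell, cells),
                            x = counts$count,
                            dims = c(length(genes), length(cells)))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "features.tsv"))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a simulation bundle to disk
#'
#' Per replicate: a FASTQ of sequenced reads and a truth TSV
#' (\code{read_id}, \code{true_id}, \code{true_umi}); plus a pooled
#' cycle-stats TSV and the configuration echoed as JSON.
#'
#' @param sim A \code{umi_sim} from [run_simulation()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "umi_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stats_all <- list()
  for (i in seq_along(sim$replicates)) {
    rep_data <- sim$replicates[[i]]
    write_fastq(rep_data$reads$read_id, rep_data$reads$umi,
                file.path(dir, sprintf("rep%d.fastq", i)))
    truth <- data.frame(read_id = rep_data$reads$read_id,
                        true_id = rep_data$reads$true_id,
                        true_umi = rep_data$true_umis[rep_data$reads$true_id])
    utils::write.table(truth, file.path(dir, sprintf("rep%d_truth.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cs <- rep_data$cycle_stats
    if (!is.null(cs) && nrow(cs)) {
      cs$replicate <- i
      stats_all[[i]] <- cs
    }
  }
  if (length(stats_all))
    utils::write.table(do.call(rbind, stats_all),
                       file.path(dir, "cycle_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a tagged-read TSV (read_id, gene, umi[, cell])
#'
#' @param path TSV path with a header line.
#' @return data.frame.
#' @export
read_tagged_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "gene", "umi") %in% names(df)))
  df
}
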