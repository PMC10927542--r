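# Read-structure utilities: orienting long reads by their poly-T marker,
# locating anchor/primer sequences with mismatches, extracting UMIs/CMIs and
# cell barcodes, whitelisting barcodes by frequency, and joining gene tags
# from alignments.

#' Extraction configuration
#'
#' Anchors default to the SMART-primer sequences flanking the 30-base
#' homotrimer UMI in the bulk long-read protocol; the poly-A/T orientation
#' marker is a run of 9 identical bases.
#'
#' @param anchor Primary anchor located to find the UMI (poly-A side SMART
#'   primer by default).
#' @param anchor_tso Optional second anchor (TSO-side SMART primer).
#' @param max_mismatch Mismatches tolerated in anchor search (default 2).
#' @param umi_length Number of bases to extract (30 = ten trimer blocks).
#' @param umi_side Side of the anchor holding the UMI: \code{"upstream"}
#'   (default, i.e. immediately 5' of the anchor) or \code{"downstream"}.
#' @param barcode_length Cell barcode length (0 = bulk, no barcode).
#' @param min_segment Minimum barcode+UMI segment length; shorter reads are
#'   rejected (48 for the droplet protocol, 0 disables).
#' @param polyt_run Length of the poly-T (or poly-A) run used as orientation
#'   marker.
#' @return An \code{extraction_config} list.
#' @export
extraction_config <- function(anchor = "GTACTCTGCGTTGATACCACTGCTT",
                              anchor_tso = "AAGCAGTGGTATCAACGCAGAGTAAT",
                              max_mismatch = 2L,
                              umi_length = 30L,
                              umi_side = c("upstream", "downstream"),
                              barcode_length = 0L,
                              min_segment = 0L,
                              polyt_run = 9L) {
  umi_side <- match.arg(umi_side)
  stopifnot(max_mismatch >= 0L, umi_length >= 1L, barcode_length >= 0L,
            polyt_run >= 1L, !grepl("[^ACGT]", anchor))
  structure(list(anchor = toupper(anchor),
                 anchor_tso = if (is.null(anchor_tso)) NULL
                              else toupper(anchor_tso),
                 max_mismatch = as.integer(max_mismatch),
                 umi_length = as.integer(umi_length),
                 umi_side = umi_side,
                 barcode_length = as.integer(barcode_length),
                 min_segment = as.integer(min_segment),
                 polyt_run = as.integer(polyt_run)),
            class = "extraction_config")
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Orient a read by its poly-A/poly-T marker
#'
#' cDNA reads may come off the sequencer in either orientation. If a poly-T
#' run is present the read is reverse complemented (so the poly-A tail ends
#' up in the expected orientation); if a poly-A run is present the read is
#' left unchanged; if neither marker is found the read is flagged unoriented
#' so the caller can skip it.
#'
#' @param seq A single read sequence.
#' @param config An \code{extraction_config} (controls the run length).
#' @return List with \code{seq} (possibly reverse complemented),
#'   \code{flipped} and \code{oriented} (FALSE when neither marker found, in
#'   which case \code{seq} is returned unchanged).
#' @export
orient_read <- function(seq, config = extraction_config()) {
  seq <- toupper(seq)
  polyA <- strrep("A", config$polyt_run)
  polyT <- strrep("T", config$polyt_run)
  if (grepl(polyT, seq, fixed = TRUE)) {
    list(seq = revcomp(seq), flipped = TRUE, oriented = TRUE)
  } else if (grepl(polyA, seq, fixed = TRUE)) {
    list(seq = seq, flipped = FALSE, oriented = TRUE)
  } else {
    list(seq = seq, flipped = FALSE, oriented = FALSE)
  }
}

#' Find an anchor sequence allowing mismatches
#'
#' Returns the 1-based start of the leftmost window whose Hamming distance to
#' the anchor is at most \code{max_mismatch}, or \code{NA} if none exists.
#' Backed by \code{\link[Biostrings]{matchPattern}}.
#'
#' @param seq A single read sequence.
#' @param anchor Anchor (primer) sequence to locate.
#' @param max_mismatch Number of substitutions tolerated.
#' @return Integer position (1-based) or \code{NA_integer_}.
#' @export
find_anchor <- function(seq, anchor, max_mismatch = 2L) {
  seq <- toupper(seq)
  anchor <- toupper(anchor)
  if (nchar(anchor) > nchar(seq)) return(NA_integer_)
  hits <- Biostrings::matchPattern(anchor, Biostrings::DNAString(seq),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  if (length(hits) == 0L) return(NA_integer_)
  as.integer(min(Biostrings::start(hits)))
}

#' Extract UMIs (and barcodes) from reads
#'
#' For each read: orient by the poly-A/T marker, locate the anchor with
#' mismatches, take \code{umi_length} (plus \code{barcode_length}) bases on
#' the configured side of the anchor, apply the minimum-segment-length
#' filter, and append barcode/UMI to the read id with the underscore
#' convention (\code{id_BARCODE_UMI} or \code{id_UMI}).
#'
#' @param reads data.frame with columns \code{id} and \code{seq}.
#' @param config An \code{extraction_config}.
#' @return data.frame with columns \code{id}, \code{new_id}, \code{umi},
#'   \code{barcode}, \code{status} (\code{"ok"}, \code{"unoriented"},
#'   \code{"no_anchor"}, \code{"too_short"}) and \code{flipped}. The
#'   \code{"rejections"} attribute tabulates non-ok statuses.
#' @export
extract_umi <- function(reads, config = extraction_config()) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  out <- data.frame(id = reads$id,
                    new_id = NA_character_,
                    umi = NA_character_,
                    barcode = NA_character_,
                    status = "ok",
                    flipped = FALSE,
                    stringsAsFactors = FALSE)
  seg_len <- config$umi_length + config$barcode_length
  for (i in seq_len(n)) {
    ori <- orient_read(reads$seq[i], config)
    out$flipped[i] <- ori$flipped
    if (!ori$oriented) {
      out$status[i] <- "unoriented"
      next
    }
    s <- ori$seq
    pos <- find_anchor(s, config$anchor, config$max_mismatch)
    if (is.na(pos)) {
      out$status[i] <- "no_anchor"
      next
    }
    if (config$umi_side == "upstream") {
      seg_end <- pos - 1L
      seg_start <- seg_end - seg_len + 1L
    } else {
      seg_start <- pos + nchar(config$anchor)
      seg_end <- seg_start + seg_len - 1L
    }
    avail_start <- max(seg_start, 1L)
    avail_end <- min(seg_end, nchar(s))
    available <- max(0L, avail_end - avail_start + 1L)
    if (available < seg_len ||
        (config$min_segment > 0L && available < config$min_segment)) {
      out$status[i] <- "too_short"
      next
    }
    segment <- substr(s, seg_start, seg_end)
    if (config$barcode_length > 0L) {
      out$barcode[i] <- substr(segment, 1L, config$barcode_length)
      out$umi[i] <- substr(segment, config$barcode_length + 1L, seg_len)
      out$new_id[i] <- paste(reads$id[i], out$barcode[i], out$umi[i],
                             sep = "_")
    } else {
      out$umi[i] <- segment
      out$new_id[i] <- paste(reads$id[i], out$umi[i], sep = "_")
    }
  }
  attr(out, "rejections") <- table(out$status[out$status != "ok"])
  out
}

#' Build a cell-barcode whitelist by frequency and assign reads
#'
#' The whitelist is the \code{expected_cells} most frequent barcodes (ties at
#' the cutoff are all included). Each observed barcode is then assigned to
#' the whitelist entry within \code{max_mismatch} substitutions; barcodes
#' equidistant from two or more entries are left unassigned.
#'
#' @param barcodes Character vector of per-read barcodes.
#' @param expected_cells Number of cells expected in the library.
#' @param max_mismatch Mismatches tolerated in assignment (default 2).
#' @return List with \code{whitelist} (character vector) and
#'   \code{assignment} (character vector parallel to \code{barcodes};
#'   \code{NA} where unassigned).
#' @export
whitelist_barcodes <- function(barcodes, expected_cells, max_mismatch = 2L) {
  stopifnot(expected_cells >= 1L)
  tab <- sort(table(barcodes), decreasing = TRUE)
  if (length(tab) <= expected_cells) {
    wl <- names(tab)
  } else {
    cutoff <- as.integer(tab[expected_cells])
    wl <- names(tab)[as.integer(tab) >= cutoff]  # ties at cutoff included
  }
  uniq <- unique(barcodes)
  assign_one <- function(bc) {
    if (bc %in% wl) return(bc)
    same_len <- wl[nchar(wl) == nchar(bc)]
    if (length(same_len) == 0L) return(NA_character_)
    d <- hamming(rep(bc, length(same_len)), same_len)
    ok <- d <= max_mismatch
    if (!any(ok)) return(NA_character_)
    dmin <- min(d[ok])
    nearest <- same_len[ok & d == dmin]
    if (length(nearest) == 1L) nearest else NA_character_
  }
  lut <- vapply(uniq, assign_one, character(1))
  list(whitelist = wl, assignment = unname(lut[match(barcodes, uniq)]))
}

#' Join gene tags from alignments with UMIs from read names
#'
#' Accepts a SAM/BAM file whose records carry the assigned gene/transcript in
#' the \code{XT} tag and the UMI as the final underscore-delimited token of
#' the read name (optionally a cell barcode as the second-to-last token), or
#' a TSV fallback with columns \code{read_id}, \code{gene}, \code{umi}
#' (optionally \code{cell}). Records without an XT tag or with a malformed
#' name are skipped and counted.
#'
#' @param path Path to a \code{.sam}, \code{.bam} or \code{.tsv} file.
#' @param with_cell Parse a cell barcode token from the read name (SAM path).
#' @return data.frame with columns \code{read_id}, (\code{cell},)
#'   \code{gene}, \code{umi}; attribute \code{"skipped"} counts dropped
#'   records.
#' @export
tag_reads_with_genes <- function(path, with_cell = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    } else path
    rec <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(what = "qname", tag = "XT"))[[1]]
    qname <- rec$qname
    gene <- rec$tag$XT
    if (is.null(gene)) gene <- rep(NA_character_, length(qname))
    parts <- strsplit(qname, "_", fixed = TRUE)
    ntok <- lengths(parts)
    need <- if (with_cell) 3L else 2L
    umi <- ifelse(ntok >= need,
                  vapply(parts, function(p) p[length(p)], character(1)),
                  NA_character_)
    cell <- if (with_cell) {
      ifelse(ntok >= 3L,
             vapply(parts, function(p) p[length(p) - 1L], character(1)),
             NA_character_)
    } else NULL
    read_id <- vapply(parts, function(p) {
      paste(p[seq_len(max(1L, length(p) - (need - 1L)))], collapse = "_")
    }, character(1))
    df <- data.frame(read_id = read_id, gene = gene, umi = umi,
                     stringsAsFactors = FALSE)
    if (with_cell) df$cell <- cell
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("read_id", "gene", "umi") %in% names(df)))
  }
  ok <- !is.na(df$gene) & df$gene != "" & !is.na(df$umi) & df$umi != ""
  if ("cell" %in% names(df)) ok <- ok & !is.na(df$cell) & df$cell != ""
  skipped <- sum(!ok)
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
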