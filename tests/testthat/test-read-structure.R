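test_that("orientation flips poly-T reads and is idempotent", {
  cfg <- extraction_config()
  body <- "GCGTACGTTAGC"
  polyA_read <- paste0(body, strrep("A", 12))
  polyT_read <- revcomp(polyA_read)
  expect_identical(revcomp("AAGC"), "GCTT")

  o1 <- orient_read(polyT_read, cfg)
  expect_true(o1$flipped)
  expect_identical(o1$seq, polyA_read)
  o2 <- orient_read(o1$seq, cfg)
  expect_false(o2$flipped)
  expect_identical(o2$seq, o1$seq)

  expect_false(orient_read(polyA_read, cfg)$flipped)
  expect_false(orient_read("GCGC", cfg)$oriented)
})

test_that("anchor search finds the leftmost window within the mismatch budget", {
  anchor <- "GTACTCTGCGTT"
  seq <- paste0("TTCACGA", anchor, "GGGCCC")
  expect_identical(find_anchor(seq, anchor, 0), 8L)
  # two substitutions tolerated at max_mismatch 2, not 1
  mut <- anchor
  substr(mut, 2, 2) <- "C"; substr(mut, 7, 7) <- "A"
  seq2 <- paste0("AACC", mut, "GG")
  expect_identical(find_anchor(seq2, anchor, 2), 5L)
  expect_true(is.na(find_anchor(seq2, anchor, 1)))
  # agreement with the brute-force sliding-window oracle on random fixtures
  set.seed(21)
  for (i in 1:100) {
    s <- random_monomer(60)
    a <- random_monomer(8)
    mm <- sample(0:2, 1)
    expect_identical(find_anchor(s, a, mm), oracle_find_anchor(s, a, mm))
  }
})

test_that("UMI extraction recovers constructed read structures", {
  cfg <- extraction_config(umi_length = 30, max_mismatch = 2)
  umi <- encode_homotrimer("GACTGCTACT")
  read <- paste0("CATG", umi, cfg$anchor, "GATTACA", strrep("A", 12))
  res <- extract_umi(data.frame(id = "r1", seq = read), cfg)
  expect_identical(res$status, "ok")
  expect_identical(res$umi, umi)
  expect_identical(res$new_id, paste0("r1_", umi))
  # reverse-complemented input is recovered via orientation
  res_rc <- extract_umi(data.frame(id = "r2", seq = revcomp(read)), cfg)
  expect_identical(res_rc$umi, umi)
  expect_true(res_rc$flipped)
  # too few bases upstream of the anchor -> rejected
  short <- paste0("CA", substr(umi, 1, 10), cfg$anchor, strrep("A", 12))
  expect_identical(extract_umi(data.frame(id = "r3", seq = short),
                               cfg)$status, "too_short")
  # no anchor at all
  noanc <- paste0(random_monomer(50), strrep("A", 12))
  expect_identical(extract_umi(data.frame(id = "r4", seq = noanc),
                               cfg)$status, "no_anchor")
  # rejection reasons conserve reads
  all4 <- extract_umi(data.frame(id = paste0("r", 1:4),
                                 seq = c(read, revcomp(read), short, noanc)),
                      cfg)
  expect_identical(sum(all4$status == "ok") +
                     sum(attr(all4, "rejections")), 4L)
})

test_that("extraction on error-free simulated reads recovers every true UMI", {
  cfg_sim <- sim_config(umi_num = 12, umi_len = 10, pcr_cycles = 4,
                        seq_depth = 50, perm_num = 1, pcr_err = 0,
                        seq_err = 0, seed = 77)
  sim <- run_simulation(cfg_sim)
  reads <- sim$replicates[[1]]$reads
  cfg <- extraction_config(umi_length = 30)
  full <- paste0(reads$umi, cfg$anchor, "CCGGTTAACC", strrep("A", 12))
  res <- extract_umi(data.frame(id = reads$read_id, seq = full), cfg)
  expect_true(all(res$status == "ok"))
  expect_identical(res$umi, reads$umi)
})

test_that("barcode whitelisting keeps top cells and resolves near matches", {
  bcs <- c(rep("AAAAGGGG", 100), rep("CCCCGGGG", 90), "TTTTGGGG")
  wl <- whitelist_barcodes(bcs, expected_cells = 2)
  expect_setequal(wl$whitelist, c("AAAAGGGG", "CCCCGGGG"))
  # one mismatch from a whitelist entry -> assigned
  res <- whitelist_barcodes(c(bcs, "AAAAGGGT"), expected_cells = 2)
  expect_identical(res$assignment[length(res$assignment)], "AAAAGGGG")
  # equidistant from two entries -> unassigned
  amb <- whitelist_barcodes(c(rep("AAAA", 10), rep("TTTT", 10), "AATT"),
                            expected_cells = 2)
  expect_true(is.na(amb$assignment[21]))
  # ties at the frequency cutoff are all included
  tie <- whitelist_barcodes(c(rep("AAAA", 5), rep("CCCC", 5),
                              rep("GGGG", 5)), expected_cells = 2)
  expect_length(tie$whitelist, 3L)
})

test_that("gene tagging joins XT tags with read-name UMIs, SAM and TSV alike", {
  umi1 <- "AAACCC"; umi2 <- "TTTGGG"
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    sprintf("r1_%s\t0\tchr1\t10\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII\tXT:Z:geneA",
            umi1),
    sprintf("r2_%s\t0\tchr1\t40\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII\tXT:Z:geneB",
            umi2),
    "r3\t0\tchr1\t60\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII\tXT:Z:geneB",
    sprintf("r4_%s\t0\tchr1\t80\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII", umi1))
  sam_path <- tempfile(fileext = ".sam")
  writeLines(sam, sam_path)
  tagged <- tag_reads_with_genes(sam_path)
  expect_identical(tagged$gene[tagged$read_id == "r1"], "geneA")
  expect_identical(tagged$umi[tagged$read_id == "r2"], umi2)
  # r3 has no UMI token, r4 no XT tag: at least the untagged read is skipped
  expect_false("r4" %in% tagged$read_id)
  expect_gte(attr(tagged, "skipped"), 1L)

  # TSV fallback round-trips the same records
  tsv_path <- tempfile(fileext = ".tsv")
  utils::write.table(tagged, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tagged2 <- tag_reads_with_genes(tsv_path)
  expect_identical(tagged2$read_id, tagged$read_id)
  expect_identical(tagged2$gene, tagged$gene)
  expect_identical(tagged2$umi, tagged$umi)
})
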