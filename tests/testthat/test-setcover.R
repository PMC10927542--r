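test_that("candidate enumeration is the per-block occurring-base product", {
  expect_identical(candidate_collapses("AAACCC"), "AC")
  expect_identical(candidate_collapses("AATCCC"), c("AC", "TC"))
  expect_identical(candidate_collapses("ACTCCC"), c("AC", "CC", "TC"))
  set.seed(3)
  for (i in 1:50) {
    umi <- mutate_blocks(encode_homotrimer(random_monomer(sample(2:6, 1))),
                         sample(0:3, 1))
    expect_identical(candidate_collapses(umi), oracle_candidates(umi))
  }
  # cap: a 6-block all-distinct UMI has 3^6 = 729 candidates
  wild <- paste(rep("ACT", 6), collapse = "")
  expect_warning(res <- candidate_collapses(wild, cap = 100), "cap")
  expect_null(res)
})

test_that("candidate map satisfies the coverage invariants", {
  members <- c("AAACCC", "AAACCC", "AATCCC", "TTTGGG", "ACTCGG")
  cm <- build_candidate_map(members)
  expect_identical(sort(cm$members), sort(unique(members)))
  expect_identical(sum(cm$multiplicity), length(members))
  # S_c = {s : c in C(s)} and every member self-covered
  for (cn in names(cm$map)) {
    for (i in cm$map[[cn]]) {
      expect_true(cn %in% oracle_candidates(cm$members[i]))
    }
  }
  expect_setequal(unlist(cm$map), seq_along(cm$members))
  # "AC" explains AAACCC, AATCCC and ACTCGG; "TG" explains TTTGGG and ACTCGG
  expect_identical(cm$map[["AC"]],
                   which(cm$members %in% c("AAACCC", "AATCCC", "ACTCGG")))
  expect_identical(cm$map[["TG"]],
                   which(cm$members %in% c("ACTCGG", "TTTGGG")))
})

test_that("greedy and exact covers solve the worked instances", {
  cm1 <- build_candidate_map(c("AAACCC", "AATCCC", "ACTCCC"))
  g1 <- greedy_cover(cm1)
  expect_identical(g1$chosen, "AC")
  expect_identical(g1$molecule_count, 1L)
  expect_identical(exact_cover(cm1)$molecule_count, 1L)

  cm2 <- build_candidate_map(c("AAACCC", "TTTGGG", "ACTCGG"))
  g2 <- greedy_cover(cm2)
  e2 <- exact_cover(cm2)
  expect_identical(g2$molecule_count, 2L)
  expect_identical(e2$molecule_count, 2L)
  expect_true(e2$optimal)

  single <- build_candidate_map("AATCCC")
  expect_identical(greedy_cover(single)$molecule_count, 1L)
  expect_identical(exact_cover(single)$molecule_count, 1L)

  # every member is assigned a chosen candidate that can explain it
  for (sol in list(g1, g2, e2)) {
    expect_false(anyNA(sol$assignment))
    for (i in seq_along(sol$members)) {
      expect_true(sol$assignment[i] %in%
                    oracle_candidates(sol$members[i]))
    }
  }
})

test_that("exact matches brute force and bounds greedy on random instances", {
  set.seed(101)
  n_equal <- 0L
  n_inst <- 60L
  for (i in seq_len(n_inst)) {
    members <- unique(random_group(sample(2:6, 1), B = sample(2:4, 1),
                                   max_err = 2))
    cm <- build_candidate_map(members)
    g <- greedy_cover(cm)$molecule_count
    e <- exact_cover(cm)$molecule_count
    expect_identical(e, oracle_min_cover_size(cm$members))
    expect_lte(e, g)
    expect_lte(g, ceiling((log(length(members)) + 1) * e))
    n_equal <- n_equal + (g == e)
  }
  # agreement rate reported, not hard-asserted at a paper value
  expect_gt(n_equal / n_inst, 0)
})

test_that("dedup_group routes between the majority fast path and set cover", {
  expect_identical(dedup_group(rep(encode_homotrimer("GACT"), 5))$count, 1L)
  two <- c(encode_homotrimer("GACT"), encode_homotrimer("GACA"))
  expect_identical(dedup_group(two)$count, 2L)
  expect_identical(dedup_group(two)$method, "majority")
  sc <- dedup_group(c("AAACCC", "ACTCCC"))
  expect_identical(sc$count, 1L)
  expect_identical(sc$method, "setcover")
  expect_identical(sc$umis, "AC")
  # all reads filtered out -> zero with warning
  expect_warning(z <- dedup_group("ACTACTACTACT", max_errors = 3), "filter")
  expect_identical(z$count, 0L)
  # adding an exact duplicate read never changes the estimate
  set.seed(5)
  grp <- random_group(6, B = 4, max_err = 2)
  expect_identical(dedup_group(c(grp, grp[1]))$count,
                   dedup_group(grp)$count)
})

test_that("dedup_table counts per group and skips keyless reads", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:7),
    gene = c(rep("geneA", 3), rep("geneB", 3), NA),
    umi = c("AAACCC", "TTTGGG", "ACTCGG",
            "AAACCC", "TTTGGG", "ACTCGG", "AAACCC"))
  tab <- dedup_table(reads, method = "setcover")
  expect_identical(tab$count[tab$gene == "geneA"], 2L)
  expect_identical(tab$count[tab$gene == "geneB"], 2L)
  expect_identical(attr(tab, "skipped"), 1L)
  # empty input
  empty <- dedup_table(reads[0, ], method = "naive")
  expect_identical(nrow(empty), 0L)
  # single-cell keys split counting by cell
  reads$cell <- c("c1", "c1", "c2", "c2", "c2", "c2", "c1")
  tab2 <- dedup_table(reads, method = "setcover")
  expect_identical(sort(names(tab2)), sort(c("cell", "gene", "count")))
  expect_identical(tab2$count[tab2$cell == "c2" & tab2$gene == "geneB"], 2L)
})

test_that("error-free simulated reads give identical counts for all methods", {
  cfg <- sim_config(umi_num = 20, umi_len = 8, pcr_cycles = 6,
                    seq_depth = 100, perm_num = 1, pcr_err = 0, seq_err = 0,
                    seed = 99)
  sim <- run_simulation(cfg)
  reads <- sim$replicates[[1]]$reads
  umis <- reads$umi
  # methods can only count molecules the sequencer sampled
  truth <- length(unique(sim$replicates[[1]]$true_monomers[reads$true_id]))
  expect_identical(dedup_group(umis)$count, truth)
  expect_identical(length(unique(collapse_first_base(umis))), truth)
})
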