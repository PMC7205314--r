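test_that("seed reverse complement matches a hand computation", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  # nucleotides 2-7 are GAGGUA; DNA reverse complement is TACCTC
  expect_identical(seed_rc(mir), "TACCTC")
  expect_identical(seed_rc(mir), rc_oracle("GAGGTA"))
})

test_that("seed-match density peaks at the planted offset; shuffled control is flat", {
  set.seed(14)
  n_mir <- 8
  mirnas <- tibble::tibble(mirna_id = sprintf("m%02d", 1:n_mir),
                           sequence = rand_dna(n_mir, 22))
  # one transcript per chimera; seed match planted exactly 20 nt downstream of
  # the ligation site (= target fragment start, miR-first)
  n <- 200
  pick <- sample(n_mir, n, replace = TRUE)
  lig <- 120L
  tx <- vapply(seq_len(n), function(i) {
    s <- rand_dna(1, 300)
    seed <- rc_oracle(substr(mirnas$sequence[pick[i]], 2, 7))
    substr(s, lig + 20 + 1, lig + 20 + 6) <- seed
    s
  }, character(1))
  transcripts <- tibble::tibble(transcript_id = sprintf("t%03d", 1:n),
                                sequence = tx)
  chim <- tibble::tibble(mirna_id = mirnas$mirna_id[pick],
                         transcript_id = transcripts$transcript_id,
                         t_start = lig, t_end = lig + 50L,
                         orientation = "mir_first")
  dens <- seed_match_density(chim, mirnas, transcripts, window_nt = 100,
                             shuffle_seed = 3)
  expect_equal(dens$offset[which.max(dens$real)], 20)
  peak <- dens$real[dens$offset == 20]
  expect_gt(peak, 0.9)  # nearly every chimera contributes its planted match
  # shuffled control has no planted structure at the offset
  expect_lt(dens$shuffled[dens$offset == 20], 0.1)
  # background density is near-flat: no off-peak offset comes close
  expect_lt(max(dens$real[dens$offset != 20]), 0.2)
})

test_that("ZOOPS enrichment finds an extreme planted 7-mer and skips small sets", {
  set.seed(15)
  motif <- "GAGGTAC"
  targets <- paste0(rand_dna(40, 15), motif, rand_dna(40, 15))
  background <- rand_dna(200, 37)
  enr <- enrich_kmers(targets, background, k = 7)
  expect_identical(enr$kmer[1], motif)
  expect_lt(enr$corrected_pvalue[1], 1e-6)
  expect_true(enr$passing[1])
  expect_equal(enr$n_targets_with_motif[1], 40L)
  # ZOOPS: no k-mer can exceed the number of targets
  expect_true(all(enr$n_targets_with_motif <= enr$n_targets))
  # below the minimum target count the miRNA is skipped
  expect_equal(nrow(enrich_kmers(targets[1:29], background, min_targets = 30)), 0)
})

test_that("no motif passes when targets equal the background distribution", {
  set.seed(16)
  fails <- 0
  for (r in 1:10) {
    targets <- rand_dna(40, 40)
    background <- rand_dna(200, 40)
    enr <- enrich_kmers(targets, background, k = 7)
    if (any(enr$passing)) fails <- fails + 1
  }
  expect_lte(fails, 1)  # Bonferroni keeps family-wise error low
})

test_that("motif registers map onto the correct miRNA positions", {
  set.seed(17)
  mir <- rand_dna(1, 22)
  # exact RC of nt 2-8 -> register start 2, 7/7 matches
  r <- map_motif_register(rc_oracle(substr(mir, 2, 8)), mir)
  expect_equal(r$register_start[1], 2L)
  expect_equal(r$register_end[1], 8L)
  expect_equal(r$matches[1], 7L)
  # RC of nt 13-19 -> register start 13
  r2 <- map_motif_register(rc_oracle(substr(mir, 13, 19)), mir)
  expect_equal(r2$register_start[1], 13L)
  # random k-mers rarely reach 6/7: compare against binomial expectation
  hits <- 0; n_try <- 300
  for (i in 1:n_try) {
    if (nrow(map_motif_register(rand_dna(1, 7), mir)) > 0) hits <- hits + 1
  }
  n_offsets <- 22 - 7 + 1
  p_one <- stats::pbinom(5, 7, 0.25, lower.tail = FALSE)
  p_any <- 1 - (1 - p_one)^n_offsets
  expect_lt(hits / n_try, p_any * 3 + 0.02)
})

test_that("usage matrix reflects planted registers and their shifts", {
  set.seed(18)
  mirnas <- tibble::tibble(mirna_id = c("miR-x", "miR-y"),
                           sequence = rand_dna(2, 22))
  mk_targets <- function(mir, from, to, n) {
    paste0(rand_dna(n, 10), rc_oracle(substr(mir, from, to)), rand_dna(n, 10))
  }
  # miR-x: register 2-8 at t1, shifted to 3-9 at t2; miR-y only at t1
  chim <- dplyr::bind_rows(
    tibble::tibble(mirna_id = "miR-x", timepoint = "t1",
                   target_segment = mk_targets(mirnas$sequence[1], 2, 8, 40)),
    tibble::tibble(mirna_id = "miR-x", timepoint = "t2",
                   target_segment = mk_targets(mirnas$sequence[1], 3, 9, 40)),
    tibble::tibble(mirna_id = "miR-y", timepoint = "t1",
                   target_segment = mk_targets(mirnas$sequence[2], 2, 8, 40)),
    tibble::tibble(mirna_id = "miR-y", timepoint = "t2",
                   target_segment = rand_dna(5, 34)))
  usage <- usage_by_timepoint(chim, mirnas, min_targets = 30, seed = 2)
  u <- usage$usage
  ux1 <- u[u$mirna_id == "miR-x" & u$timepoint == "t1", ]
  ux2 <- u[u$mirna_id == "miR-x" & u$timepoint == "t2", ]
  expect_true(all(ux1$proportion[ux1$position %in% 2:8] > 0.9))
  expect_true(all(ux1$proportion[!ux1$position %in% 2:8] == 0))
  expect_true(all(ux2$proportion[ux2$position %in% 3:9] > 0.9))
  expect_true(all(ux2$proportion[!ux2$position %in% 3:9] == 0))
  # miR-y absent at t2 -> NA column
  uy2 <- u[u$mirna_id == "miR-y" & u$timepoint == "t2", ]
  expect_true(all(is.na(uy2$proportion)))
  # retained motif table records the register
  mx <- usage$motifs
  expect_equal(mx$register_start[mx$mirna_id == "miR-x" & mx$timepoint == "t1"][1], 2L)
})
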