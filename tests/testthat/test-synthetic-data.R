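test_that("configuration rejects invalid proportion vectors", {
  expect_error(sim_config(utr_fractions = c(`5UTR` = 0.3, CDS = 0.3, `3UTR` = 0.3)),
               class = "clearclipr_config_error")
  expect_error(sim_config(read_class_mix = c(chimera = 0.5, clip = 0.6,
                                             mirna_only = 0, ncrna = 0, junk = 0)),
               class = "clearclipr_config_error")
  expect_s3_class(sim_config(), "ccl_config")
})

test_that("reference transcripts carry UTR/CDS blocks matching the fractions", {
  cfg <- sim_config(n_transcripts = 40, n_ncrna = 5, n_mirnas = 10,
                    utr_fractions = c(`5UTR` = 0.1, CDS = 0.5, `3UTR` = 0.4),
                    rng_seed = 3)
  ref <- sim_reference(cfg)
  mrna <- dplyr::filter(ref$transcripts, type == "mRNA")
  ann <- dplyr::filter(ref$annotation, feature %in% c("5UTR", "CDS", "3UTR"))
  for (i in seq_len(nrow(mrna))) {
    a <- ann[ann$transcript_id == mrna$transcript_id[i], ]
    len <- mrna$length[i]
    expect_equal(sort(a$feature), sort(c("5UTR", "CDS", "3UTR")))
    expect_equal(min(a$start), 0L)
    expect_equal(max(a$end), len)
    w <- a$end - a$start
    expect_lte(abs(w[a$feature == "5UTR"] - 0.1 * len), 1)
    expect_lte(abs(w[a$feature == "CDS"] - 0.5 * len), 1)
  }
  # miRNA lengths within the configured range, sequences unique
  expect_true(all(ref$mirnas$length %in% 21:23))
  expect_false(anyDuplicated(ref$mirnas$sequence) > 0)
})

test_that("identical config and seed give identical references and libraries", {
  cfg <- sim_config(n_transcripts = 30, n_ncrna = 4, n_mirnas = 8,
                    n_interactions = 30, n_reads = 500, rng_seed = 9)
  r1 <- sim_reference(cfg); r2 <- sim_reference(cfg)
  expect_identical(r1$transcripts, r2$transcripts)
  expect_identical(r1$mirnas, r2$mirnas)
  t1 <- sim_plant_interactions(r1, cfg); t2 <- sim_plant_interactions(r2, cfg)
  expect_identical(t1$interactions, t2$interactions)
  l1 <- sim_library(t1, "3hPE", cfg); l2 <- sim_library(t2, "3hPE", cfg)
  expect_identical(l1$reads, l2$reads)
})

test_that("planted sites obey their class containment rules (exhaustive scan)", {
  cfg <- sim_config(n_transcripts = 100, n_ncrna = 5, n_mirnas = 20,
                    n_interactions = 200, rng_seed = 7)
  truth <- sim_plant_interactions(sim_reference(cfg), cfg)
  ints <- truth$interactions
  tx <- stats::setNames(truth$reference$transcripts$sequence,
                        truth$reference$transcripts$transcript_id)
  mir <- stats::setNames(truth$reference$mirnas$sequence,
                         truth$reference$mirnas$mirna_id)
  for (i in seq_len(nrow(ints))) {
    site <- substr(tx[[ints$transcript_id[i]]], ints$site_start[i] + 1,
                   ints$site_end[i])
    m <- mir[[ints$mirna_id[i]]]
    cls <- ints$site_class[i]
    expect_lte(ints$site_end[i], nchar(tx[[ints$transcript_id[i]]]))
    if (cls == "canonical") {
      expect_true(grepl(rc_oracle(substr(m, 2, 7)), site, fixed = TRUE),
                  label = paste("canonical seed containment", i))
    } else if (cls == "supplementary") {
      expect_identical(site, rc_oracle(substr(m, 13, 19)))
    } else if (cls == "central") {
      expect_identical(site, rc_oracle(substr(m, 9, 15)))
    } else {
      banned <- rc_oracle(substring(m, 1:3, 6:8))
      for (b in banned) expect_false(grepl(b, site, fixed = TRUE))
    }
  }
})

test_that("library labels conserve read counts and emulate the class mix", {
  cfg <- sim_config(n_transcripts = 60, n_ncrna = 6, n_mirnas = 12,
                    n_interactions = 60, n_reads = 20000, rng_seed = 2)
  truth <- sim_plant_interactions(sim_reference(cfg), cfg)
  lib <- sim_library(truth, "30hPE", cfg)
  expect_equal(nrow(lib$labels), nrow(lib$reads))
  expect_identical(lib$labels$read_id, lib$reads$read_id)
  # chimera count within 4 binomial SDs of the configured rate
  p <- unname(cfg$read_class_mix["chimera"])
  n_ch <- sum(lib$labels$class == "chimera")
  expect_lt(abs(n_ch - 20000 * p), 4 * sqrt(20000 * p * (1 - p)))
  # every chimeric label references a planted interaction
  ch <- lib$labels[lib$labels$class == "chimera", ]
  expect_true(all(ch$interaction_id %in% truth$interactions$interaction_id))
})

test_that("pcr_dup_rate = 0 gives fully distinct (barcode, insert) pairs", {
  # miRNA-only reads are excluded: identical short inserts can share one of
  # only 64 degenerate barcodes by chance, which is not PCR duplication
  cfg <- sim_config(n_transcripts = 40, n_ncrna = 4, n_mirnas = 10,
                    n_interactions = 40, n_reads = 2000, pcr_dup_rate = 0,
                    read_class_mix = c(chimera = 0.2, clip = 0.6,
                                       mirna_only = 0, ncrna = 0.15,
                                       junk = 0.05),
                    rng_seed = 5)
  truth <- sim_plant_interactions(sim_reference(cfg), cfg)
  lib <- sim_library(truth, "3hPE", cfg)
  expect_false(any(lib$labels$is_duplicate))
  key <- paste(lib$labels$barcode, lib$labels$insert)
  # no PCR duplication: the only repeated pairs are rare birthday collisions
  # of identical fragments on the 64 degenerate barcodes (< 0.5%)
  expect_lt(mean(duplicated(key)), 0.005)
})

test_that("interaction activity gates the time points its reads appear in", {
  cfg <- sim_config(n_transcripts = 40, n_ncrna = 0, n_mirnas = 10,
                    n_interactions = 20, n_reads = 3000, rng_seed = 8,
                    read_class_mix = c(chimera = 0.5, clip = 0.5,
                                       mirna_only = 0, ncrna = 0, junk = 0),
                    clip_background_frac = 0)
  truth <- sim_plant_interactions(sim_reference(cfg), cfg)
  # force one interaction active only at 120hPE, the rest only at 3hPE
  act_cols <- paste0("activity_", cfg$timepoints)
  truth$interactions[act_cols] <- 0
  truth$interactions$activity_3hPE <- 1
  truth$interactions$activity_3hPE[1] <- 0
  truth$interactions$activity_120hPE[1] <- 1
  only120 <- truth$interactions$interaction_id[1]
  lib3 <- sim_library(truth, "3hPE", cfg)
  lib120 <- sim_library(truth, "120hPE", cfg)
  expect_false(only120 %in% lib3$labels$interaction_id)
  expect_true(only120 %in% lib120$labels$interaction_id)
  expect_true(all(stats::na.omit(lib120$labels$interaction_id) == only120))
})

test_that("sim_dataset writes a complete, reproducible file set", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(n_transcripts = 20, n_ncrna = 2, n_mirnas = 6,
                    n_interactions = 15, n_reads = 300, rng_seed = 4)
  sim_dataset(cfg, dir1, timepoints = "3hPE")
  sim_dataset(cfg, dir2, timepoints = "3hPE")
  for (f in c("transcripts.fa", "mirnas.fa", "annotation.tsv",
              "ground_truth.tsv", "expression.tsv", "library_3hPE.fastq",
              "labels_3hPE.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)), label = f)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
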