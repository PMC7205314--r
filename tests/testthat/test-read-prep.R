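ADAPTER <- "AGATCGGAAGAGCACACGTCT"

# Independent reference implementation of the trimming rule, used as oracle.
trim_oracle <- function(seq, adapter = ADAPTER, min_overlap = 5,
                        max_mm_rate = 0.1) {
  n <- nchar(seq)
  for (p in 0:(n - min_overlap)) {
    ov <- min(n - p, nchar(adapter))
    a <- strsplit(substr(seq, p + 1, p + ov), "")[[1]]
    b <- strsplit(substr(adapter, 1, ov), "")[[1]]
    if (sum(a != b) <= floor(max_mm_rate * ov)) return(substr(seq, 1, p))
  }
  seq
}

test_that("adapter trimming removes the adapter and everything 3' of it", {
  x <- "ACGTACGTACGTACGTACGT"
  reads <- read_tbl(c(paste0(x, ADAPTER),               # full adapter
                      x,                                 # no adapter
                      paste0(x, "AGAT"),                 # below min_overlap
                      paste0(x, "AGATCG"),               # 6-nt partial at end
                      paste0(x, ADAPTER, "TTTTTT")))     # trailing bases
  out <- trim_adapter(reads, ADAPTER, min_overlap = 5)
  expect_identical(out$sequence, c(x, x, paste0(x, "AGAT"), x, x))
  expect_identical(nchar(out$quality), nchar(out$sequence))
})

test_that("trimming agrees with an independent reference on random reads", {
  set.seed(21)
  inserts <- rand_dna(150, 30)
  tails <- vapply(1:150, function(i) {
    k <- sample(0:21, 1)
    substr(ADAPTER, 1, k)
  }, character(1))
  seqs <- paste0(inserts, tails)
  out <- trim_adapter(read_tbl(seqs), ADAPTER, min_overlap = 5)
  expected <- vapply(seqs, trim_oracle, character(1), USE.NAMES = FALSE)
  expect_identical(out$sequence, expected)
})

test_that("barcode stripping is a reversible split and drops too-short reads", {
  reads <- read_tbl(c("ACGTTTTGGG", "AC"))
  out <- strip_barcode(reads, 3)
  expect_equal(nrow(out), 1)
  expect_identical(out$barcode, "ACG")
  expect_identical(out$sequence, "TTTTGGG")
  expect_identical(paste0(out$barcode, out$sequence), reads$sequence[1])
  expect_equal(attr(out, "n_discarded_short"), 1)
})

test_that("collapse keeps one record per (barcode, sequence) with multiplicity", {
  reads <- read_tbl(c(rep("ACGTACGTACGTACGTA", 3), "TTTTTTTTTTTTTTTTT",
                      "ACGTACGTACGTACG"))  # last one is 15 nt
  reads$barcode <- c("AAA", "AAA", "AAA", "CCC", "AAA")
  prep <- collapse_and_filter(reads, min_len = 16)
  expect_equal(prep$stats$n_discarded_short, 1)
  expect_equal(nrow(prep$reads), 2)
  expect_equal(sort(prep$reads$dup_count), c(1L, 3L))
  # count conservation and dedup correctness
  expect_equal(sum(prep$reads$dup_count) + prep$stats$n_discarded_short,
               nrow(reads))
  # same barcode, same sequence, split when barcode differs
  reads2 <- reads; reads2$barcode[2] <- "GGG"
  expect_equal(nrow(collapse_and_filter(reads2, 16)$reads), 3)
})

test_that("collapse is idempotent", {
  set.seed(5)
  reads <- read_tbl(rand_dna(50, 20))
  reads$barcode <- sample(c("AAA", "CCC"), 50, replace = TRUE)
  p1 <- collapse_and_filter(reads, 16)
  p2 <- collapse_and_filter(p1$reads, 16)
  expect_identical(p1$reads, p2$reads)
})

test_that("prep chain conserves counts and recovers unique molecules", {
  run <- small_run()
  st <- run$prep$stats
  expect_equal(st$n_input,
               st$n_reads_collapsed + st$n_discarded_quality +
                 st$n_discarded_no_barcode + st$n_discarded_short)
  expect_equal(sum(run$prep$reads$dup_count) + st$n_discarded_short +
                 st$n_discarded_quality + st$n_discarded_no_barcode,
               nrow(run$lib$reads))
})

test_that("kept unique count matches the generator's distinct molecules", {
  cfg <- sim_config(n_transcripts = 40, n_ncrna = 4, n_mirnas = 10,
                    n_interactions = 40, n_reads = 4000, pcr_dup_rate = 0.3,
                    rng_seed = 5)
  truth <- sim_plant_interactions(sim_reference(cfg), cfg)
  lib <- sim_library(truth, "3hPE", cfg)
  prep <- prep_reads(lib$reads)
  lab <- lib$labels
  # ground truth: distinct (barcode, insert) pairs among length-passing inserts
  ok <- nchar(lab$insert) >= 16
  truth_unique <- length(unique(paste(lab$barcode[ok], lab$insert[ok])))
  expect_equal(nrow(prep$reads), truth_unique)
})

test_that("FASTQ round trip preserves reads and collapsed FASTA has dup headers", {
  run <- small_run()
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(paste0("@", run$lib$reads$read_id, "\n", run$lib$reads$sequence,
                    "\n+\n", run$lib$reads$quality), fq)
  back <- read_fastq_tbl(fq)
  expect_identical(back$sequence, run$lib$reads$sequence)
  expect_identical(back$read_id, run$lib$reads$read_id)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(run$prep, fa)
  lines <- readLines(fa)
  expect_match(lines[1], "^>.*\\|dup=\\d+\\|bc=[ACGT]+$")
})
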