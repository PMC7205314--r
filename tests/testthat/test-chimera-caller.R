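# Small hand-built reference used across these tests.
chim_ref <- function() {
  cached("chim_ref", {
    set.seed(31)
    tx <- tibble::tibble(
      transcript_id = c("TXA", "TXB", "TXC"),
      sequence = rand_dna(3, 600))
    # duplicate a 60-nt block of TXA into TXB to create a multimapping locus
    dup <- substr(tx$sequence[1], 101, 160)
    substr(tx$sequence[2], 301, 360) <- dup
    nc <- tibble::tibble(transcript_id = "RRNA1",
                         sequence = rand_dna(1, 400))
    transcripts <- dplyr::bind_rows(tx, nc)
    transcripts$length <- nchar(transcripts$sequence)
    annotation <- tibble::tibble(
      transcript_id = c(rep(c("TXA", "TXB", "TXC"), each = 3), "RRNA1"),
      feature = c(rep(c("5UTR", "CDS", "3UTR"), 3), "rRNA"),
      start = c(rep(c(0L, 60L, 400L), 3), 0L),
      end = c(rep(c(60L, 400L, 600L), 3), 400L))
    mirnas <- tibble::tibble(
      mirna_id = c("miR-a", "miR-b", "miR-c"),
      sequence = rand_dna(3, 22))
    list(transcripts = transcripts, annotation = annotation, mirnas = mirnas)
  })
}

test_that("an exact miRNA concatenated with a target is found with a tiny E-value", {
  ref <- chim_ref()
  target <- substr(ref$transcripts$sequence[3], 451, 490)  # TXC [450, 490)
  reads <- read_tbl(paste0(ref$mirnas$sequence[1], target))
  hits <- find_mirna_in_read(reads, ref$mirnas)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$mirna_id, "miR-a")
  expect_equal(hits$read_start, 0L)
  expect_equal(hits$read_end, 22L)
  expect_lt(hits$evalue, 1e-4)
})

test_that("reads sharing no 8-nt word with the mirnome give no hit", {
  ref <- chim_ref()
  # build a random read rejected against sharing any 8-mer with any miRNA
  words <- unique(unlist(lapply(ref$mirnas$sequence, function(m) {
    substring(m, 1:(nchar(m) - 7), 8:nchar(m))
  })))
  set.seed(12)
  repeat {
    r <- rand_dna(1, 60)
    shares <- any(vapply(words, function(w) grepl(w, r, fixed = TRUE),
                         logical(1)))
    if (!shares) break
  }
  hits <- find_mirna_in_read(read_tbl(r), ref$mirnas)
  expect_equal(nrow(hits), 0)
})

test_that("hits with E-value at or above the threshold are rejected", {
  ref <- chim_ref()
  reads <- read_tbl(paste0(ref$mirnas$sequence[2], rand_dna(1, 40)))
  hit <- find_mirna_in_read(reads, ref$mirnas)
  expect_equal(nrow(hit), 1)
  # the same alignment is rejected once the threshold drops below its E-value
  expect_equal(nrow(find_mirna_in_read(reads, ref$mirnas,
                                       evalue_max = hit$evalue / 2)), 0)
})

test_that("split_read resolves orientation, miRNA-only and ambiguous reads", {
  ref <- chim_ref()
  m <- ref$mirnas$sequence[1]
  target <- substr(ref$transcripts$sequence[3], 101, 140)
  reads <- read_tbl(c(paste0(m, target),            # miR-first
                      paste0(target, m),            # miR-last
                      paste0(m, "ACG"),             # 3-nt residual
                      paste0(target, m, target)))   # residues on both sides
  hits <- find_mirna_in_read(reads, ref$mirnas)
  sp <- split_read(reads, hits)
  sp <- sp[match(reads$read_id, sp$read_id), ]
  expect_identical(sp$status, c("target", "target", "mirna_only", "ambiguous"))
  expect_identical(sp$orientation[1:2], c("mir_first", "mir_last"))
  expect_identical(sp$target_segment[1], target)
  expect_identical(sp$target_segment[2], target)
})

test_that("segments map back to their exact origin; decoys and duplicates flagged", {
  ref <- chim_ref()
  segs <- tibble::tibble(
    id = c("verbatim", "decoy", "dupred", "nohit"),
    sequence = c(substr(ref$transcripts$sequence[3], 101, 142),  # TXC [100,142)
                 substr(ref$transcripts$sequence[4], 51, 90),    # rRNA decoy
                 substr(ref$transcripts$sequence[1], 105, 150),  # duplicated block
                 rand_dna(1, 40)))
  m <- map_target(segs, ref$transcripts, ref$annotation)
  expect_identical(m$transcript_id[1], "TXC")
  expect_equal(m$t_start[1], 100L)
  expect_equal(m$t_end[1], 142L)
  expect_true(m$is_ncrna[2])
  expect_true(m$multimapped[3])
  expect_true(is.na(m$transcript_id[4]))
})

test_that("region assignment follows the midpoint rule", {
  ref <- chim_ref()
  # fully inside 3UTR; straddling CDS/3UTR with midpoint in CDS
  r <- annotate_region(ref$annotation,
                       c("TXA", "TXA", "TXA", "RRNA1"),
                       c(450L, 380L, 0L, 10L),
                       c(470L, 410L, 60L, 30L))
  expect_identical(r, c("3UTR", "CDS", "5UTR", NA))
})

test_that("every cleaned read receives exactly one class and tallies match truth", {
  run <- small_run()
  calls <- run$calls
  expect_equal(nrow(calls$classes), nrow(run$prep$reads))
  expect_false(anyNA(calls$classes$class))
  expect_equal(sum(unlist(calls$stats)), nrow(run$prep$reads))
  # per-class tallies against generator truth (collapsed reads, by read id)
  lab <- run$lib$labels[match(run$prep$reads$read_id, run$lib$labels$read_id), ]
  tab <- table(truth = lab$class, called = calls$classes$class)
  # diagonal dominance for the main classes
  for (cl in c("chimera", "clip", "mirna_only", "ncrna")) {
    frac <- tab[cl, cl] / sum(tab[cl, ])
    expect_gt(frac, 0.9)
  }
  # chimera calls carry the correct miRNA and transcript for >= 95% of reads
  ch <- calls$chimeras
  lab_ch <- run$lib$labels[match(ch$read_id, run$lib$labels$read_id), ]
  ok <- ch$mirna_id == lab_ch$mirna_id & ch$transcript_id == lab_ch$transcript_id
  expect_gt(mean(ok, na.rm = TRUE), 0.95)
})

test_that("CLIP reads land on the transcript with their planted interval", {
  run <- small_run()
  clip <- run$calls$clip
  lab <- run$lib$labels[match(clip$read_id, run$lib$labels$read_id), ]
  same <- clip$transcript_id == lab$transcript_id
  expect_gt(mean(same[lab$class == "clip"], na.rm = TRUE), 0.95)
})
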