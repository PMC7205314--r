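#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Sanger quality).
#' @return Tibble `read_id`, `sequence`, `quality`, `dup_count` (1).
#' @export
read_fastq_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
    dup_count = 1L)
}

#' Filter reads on mean base quality
#'
#' @param reads Tibble with `sequence` and `quality`.
#' @param min_mean_phred Minimum mean Phred score to keep a read.
#' @return The kept reads, with attribute `n_discarded_quality`.
#' @export
quality_filter <- function(reads, min_mean_phred = 20) {
  keep <- mean_phred(reads$quality) >= min_mean_phred
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_discarded_quality") <- sum(!keep)
  out
}

#' Trim the 3' adapter from reads
#'
#' Removes the leftmost read suffix matching a prefix of `adapter` (overlap at
#' least `min_overlap`, mismatch rate at most `max_mismatch_rate`) and
#' everything 3' of it; qualities are trimmed in lockstep.  Reads without an
#' adapter match pass through unchanged.
#'
#' @param reads Tibble with `sequence` (and optionally `quality`).
#' @param adapter Adapter DNA sequence.
#' @param min_overlap Minimum adapter prefix length at the read 3' end.
#' @param max_mismatch_rate Maximum mismatch proportion within the overlap.
#' @return `reads` with trimmed `sequence`/`quality`.
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGCACACGTCT",
                         min_overlap = 5, max_mismatch_rate = 0.1) {
  if (!nzchar(adapter)) abort("`adapter` must be non-empty")
  pos <- cpp_adapter_pos(reads$sequence, adapter, as.integer(min_overlap),
                         max_mismatch_rate)
  reads$sequence <- substr(reads$sequence, 1L, pos)
  if ("quality" %in% names(reads)) {
    reads$quality <- substr(reads$quality, 1L, pos)
  }
  reads
}

#' Move the degenerate 5' barcode into its own column
#'
#' @param reads Tibble with `sequence` (and optionally `quality`).
#' @param barcode_len Barcode length (nt).
#' @return Kept reads with a `barcode` column; reads not longer than the
#'   barcode are discarded and counted in attribute `n_discarded_short`.
#' @export
strip_barcode <- function(reads, barcode_len = 3) {
  keep <- nchar(reads$sequence) > barcode_len
  out <- reads[keep, , drop = FALSE]
  out$barcode <- substr(out$sequence, 1L, barcode_len)
  out$sequence <- substr(out$sequence, barcode_len + 1L, nchar(out$sequence))
  if ("quality" %in% names(out)) {
    out$quality <- substr(out$quality, barcode_len + 1L, nchar(out$quality) +
                            barcode_len)
  }
  attr(out, "n_discarded_short") <- sum(!keep)
  dplyr::relocate(out, "read_id", "barcode")
}

#' Collapse identical reads and apply the minimum-length filter
#'
#' One record is kept per distinct duplicate key with `dup_count` equal to the
#' multiplicity; reads shorter than `min_len` are discarded first.  The
#' default key is the (barcode, sequence) pair, treating the degenerate
#' barcode as a UMI; `collapse_on = "sequence"` collapses on sequence alone.
#'
#' @param reads Barcode-stripped, adapter-trimmed reads.
#' @param min_len Minimum insert length to keep (nt).
#' @param collapse_on `"barcode_sequence"` or `"sequence"`.
#' @return A list of class `ccl_prep`: `reads` (collapsed; first read id by
#'   sort order is the representative) and `stats`.
#' @export
collapse_and_filter <- function(reads, min_len = 16,
                                collapse_on = c("barcode_sequence", "sequence")) {
  collapse_on <- match.arg(collapse_on)
  n_in <- nrow(reads)
  if (!"dup_count" %in% names(reads)) reads$dup_count <- 1L
  long <- reads[nchar(reads$sequence) >= min_len, , drop = FALSE]
  n_short <- n_in - nrow(long)
  keys <- if (collapse_on == "barcode_sequence" && "barcode" %in% names(long)) {
    c("barcode", "sequence")
  } else "sequence"
  collapsed <- long |>
    dplyr::arrange(.data$read_id) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(read_id = dplyr::first(.data$read_id),
                     quality = dplyr::first(.data$quality),
                     dup_count = sum(.data$dup_count), .groups = "drop") |>
    dplyr::arrange(.data$read_id) |>
    dplyr::relocate("read_id")
  stats <- list(n_input = n_in, n_kept = nrow(collapsed),
                n_discarded_short = n_short,
                n_reads_collapsed = sum(collapsed$dup_count))
  structure(list(reads = collapsed, stats = stats), class = "ccl_prep")
}

#' Run the full read-preprocessing chain
#'
#' Quality filter, 3' adapter trim, 5' barcode removal, identical-read
#' collapse and minimum-length filter, with count-conserving statistics.
#'
#' @param reads Tibble (`read_id`, `sequence`, `quality`) or a FASTQ path.
#' @inheritParams trim_adapter
#' @inheritParams collapse_and_filter
#' @inheritParams strip_barcode
#' @inheritParams quality_filter
#' @return A list of class `ccl_prep`: collapsed `reads` and `stats`
#'   (`n_input`, `n_discarded_quality`, `n_discarded_no_barcode`,
#'   `n_discarded_short`, `n_kept`).
#' @export
prep_reads <- function(reads, adapter = "AGATCGGAAGAGCACACGTCT",
                       min_overlap = 5, max_mismatch_rate = 0.1,
                       barcode_len = 3, min_len = 16, min_mean_phred = 20,
                       collapse_on = c("barcode_sequence", "sequence")) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_tbl(reads)
  n_input <- nrow(reads)
  reads <- quality_filter(reads, min_mean_phred)
  n_qual <- attr(reads, "n_discarded_quality")
  reads <- trim_adapter(reads, adapter, min_overlap, max_mismatch_rate)
  reads <- strip_barcode(reads, barcode_len)
  n_nobc <- attr(reads, "n_discarded_short")
  prep <- collapse_and_filter(reads, min_len, collapse_on)
  prep$stats <- c(list(n_input = n_input, n_discarded_quality = n_qual,
                       n_discarded_no_barcode = n_nobc),
                  prep$stats[c("n_kept", "n_discarded_short",
                               "n_reads_collapsed")])
  prep
}

#' Write collapsed reads as FASTA with dup-count headers
#'
#' Headers take the form `readid|dup=N|bc=XYZ`.
#'
#' @param prep A `ccl_prep` object (or its `reads` tibble).
#' @param path Output FASTA path.
#' @export
write_collapsed_fasta <- function(prep, path) {
  reads <- if (inherits(prep, "ccl_prep")) prep$reads else prep
  bc <- if ("barcode" %in% names(reads)) reads$barcode else rep("", nrow(reads))
  writeLines(paste0(">", reads$read_id, "|dup=", reads$dup_count, "|bc=", bc,
                    "\n", reads$sequence), path)
  invisible(path)
}
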