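# Classification of cleaned reads into chimera / miRNA-only / CLIP / ncRNA /
# unmapped / ambiguous, via word-seeded local alignment in transcript space.

# Ungapped Karlin-Altschul lambda for a match/mismatch scoring with uniform
# base composition: solves sum p_i p_j exp(lambda * s_ij) = 1.  K is the
# tabulated ungapped value for the blastn-like +2/-3 scoring.
ka_params <- function(match = 2, mismatch = -3, K = 0.41) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-6, 5), tol = 1e-10)$root
  list(lambda = lambda, K = K)
}

#' Find the best miRNA alignment within each read
#'
#' Word-seeded Smith-Waterman local alignment of every mature miRNA against
#' each read (sense strand only), blastn-like scoring (match +2, mismatch -3,
#' gap open -5, gap extend -2), ungapped Karlin-Altschul E-values; the best
#' hit is kept if its E-value is below `evalue_max`.  Ties are broken by
#' higher identity, longer alignment, then lexicographic miRNA id.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param mirnas Tibble with `mirna_id`, `sequence` (RNA or DNA spelling).
#' @param evalue_max Keep hits with E-value strictly below this (default 0.4).
#' @param word_size Seed word length; a read sharing no word of this length
#'   with a miRNA is never aligned against it.
#' @param match,mismatch,gap_open,gap_extend Alignment scores/penalties.
#' @return Tibble with one row per read with a passing hit: `read_id`,
#'   `mirna_id`, read and miRNA intervals (0-based half-open), `matches`,
#'   `mismatches`, `gaps`, `score`, `evalue`.
#' @export
find_mirna_in_read <- function(reads, mirnas, evalue_max = 0.4, word_size = 11,
                               match = 2, mismatch = -3, gap_open = 5,
                               gap_extend = 2) {
  if (nrow(mirnas) == 0) abort("empty mirnome", class = "clearclipr_config_error")
  mirnas <- dplyr::arrange(mirnas, .data$mirna_id)
  ka <- ka_params(match, mismatch)
  # E-values follow the screen's geometry: each mature miRNA is the query and
  # the cleaned reads are the database.
  db_len <- sum(nchar(reads$sequence))
  hits <- cpp_mirna_scan(as_dna(reads$sequence), as_dna(mirnas$sequence),
                         as.integer(word_size), as.integer(match),
                         as.integer(mismatch), as.integer(gap_open),
                         as.integer(gap_extend), ka$lambda, ka$K,
                         as.double(db_len), evalue_max)
  tibble::tibble(
    read_id = reads$read_id[hits$read],
    mirna_id = mirnas$mirna_id[hits$mirna],
    read_start = hits$q_start, read_end = hits$q_end,
    mirna_start = hits$s_start, mirna_end = hits$s_end,
    matches = hits$matches, mismatches = hits$mismatches, gaps = hits$gaps,
    score = hits$score, evalue = hits$evalue)
}

#' Split a read with a miRNA hit into miRNA and target-candidate parts
#'
#' The residual sequence flanking the miRNA span becomes the target candidate.
#' If residues exist on both sides, the longer side is the target provided the
#' shorter side is below `max_slack` nt (linker slack); otherwise the read is
#' flagged ambiguous.  Reads whose residuals are all shorter than
#' `min_target_len` are miRNA-only.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param hits Output of [find_mirna_in_read()].
#' @param min_target_len Minimum target-candidate length (nt).
#' @param max_slack Longest tolerated residual on the non-target side (nt).
#' @return Tibble: `read_id`, `mirna_id`, `status` (`target`, `mirna_only`,
#'   `ambiguous`), `orientation` (`mir_first`/`mir_last`), `target_segment`,
#'   `target_offset` (0-based start of the segment within the read).
#' @export
split_read <- function(reads, hits, min_target_len = 16, max_slack = 6) {
  x <- dplyr::inner_join(hits, reads[c("read_id", "sequence")], by = "read_id")
  len <- nchar(x$sequence)
  left <- x$read_start
  right <- len - x$read_end
  target_right <- right >= left
  short_side <- pmin(left, right)
  long_side <- pmax(left, right)
  status <- dplyr::case_when(
    long_side < min_target_len ~ "mirna_only",
    short_side >= max_slack ~ "ambiguous",
    TRUE ~ "target")
  orientation <- ifelse(target_right, "mir_first", "mir_last")
  off <- ifelse(target_right, x$read_end, 0L)
  seg <- substr(x$sequence, off + 1L, ifelse(target_right, len, x$read_start))
  tibble::tibble(read_id = x$read_id, mirna_id = x$mirna_id,
                 status = status,
                 orientation = ifelse(status == "target", orientation, NA),
                 target_segment = ifelse(status == "target", seg, NA),
                 target_offset = ifelse(status == "target", as.integer(off),
                                        NA_integer_))
}

#' Map sequence segments to the transcriptome
#'
#' k-mer-seeded banded local alignment against all transcripts.  Segments
#' hitting rRNA/tRNA/miRNA-locus transcripts are flagged `ncrna`; segments
#' whose best score is attained at more than one distinct locus are flagged
#' `multimapped`.
#'
#' @param segments Tibble with `id`, `sequence`.
#' @param transcripts Tibble with `transcript_id`, `sequence`.
#' @param annotation Annotation tibble (`transcript_id`, `feature`, `start`,
#'   `end`); features `rRNA`, `tRNA`, `miRNA_locus` mark ncRNA transcripts.
#' @param evalue_max E-value threshold (default 0.4, as for the miRNA scan).
#' @param seed_k Seed k-mer length.
#' @param band Band half-width around the seed diagonal.
#' @inheritParams find_mirna_in_read
#' @return Tibble: `id`, `transcript_id` (NA if unmapped), `t_start`, `t_end`,
#'   `q_start`, `q_end` (0-based half-open), alignment counts, `score`,
#'   `evalue`, `multimapped`, `is_ncrna`.
#' @export
map_target <- function(segments, transcripts, annotation, evalue_max = 0.4,
                       seed_k = 12, band = 16, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2) {
  ka <- ka_params(match, mismatch)
  db_len <- sum(nchar(transcripts$sequence))
  m <- cpp_target_map(as_dna(segments$sequence), as_dna(transcripts$sequence),
                      as.integer(seed_k), as.integer(match),
                      as.integer(mismatch), as.integer(gap_open),
                      as.integer(gap_extend), as.integer(band),
                      ka$lambda, ka$K, as.double(db_len), evalue_max)
  nc_ids <- unique(annotation$transcript_id[
    annotation$feature %in% c("rRNA", "tRNA", "miRNA_locus")])
  tid <- ifelse(is.na(m$transcript), NA_character_,
                transcripts$transcript_id[m$transcript])
  tibble::tibble(
    id = segments$id,
    transcript_id = tid,
    t_start = ifelse(is.na(tid), NA_integer_, m$t_start),
    t_end = ifelse(is.na(tid), NA_integer_, m$t_end),
    q_start = ifelse(is.na(tid), NA_integer_, m$q_start),
    q_end = ifelse(is.na(tid), NA_integer_, m$q_end),
    matches = m$matches, mismatches = m$mismatches, gaps = m$gaps,
    score = m$score, evalue = m$evalue,
    multimapped = !is.na(tid) & m$n_best > 1,
    is_ncrna = !is.na(tid) & tid %in% nc_ids)
}

#' Assign a transcript region to an interval by the midpoint rule
#'
#' @param annotation Annotation tibble with 5UTR/CDS/3UTR rows.
#' @param transcript_id,start,end Vectors describing 0-based half-open
#'   intervals on transcripts.
#' @return Character vector in `{5UTR, CDS, 3UTR}` (NA when the transcript has
#'   no mRNA annotation).
#' @export
annotate_region <- function(annotation, transcript_id, start, end) {
  mid <- (start + pmax(end - 1L, start)) %/% 2L
  ann <- annotation[annotation$feature %in% c("5UTR", "CDS", "3UTR"), ]
  q <- tibble::tibble(transcript_id = transcript_id, mid = mid,
                      .row = seq_along(transcript_id))
  j <- dplyr::inner_join(q, ann, by = "transcript_id",
                         relationship = "many-to-many") |>
    dplyr::filter(.data$mid >= .data$start, .data$mid < .data$end) |>
    dplyr::distinct(.data$.row, .keep_all = TRUE)
  out <- rep(NA_character_, length(transcript_id))
  out[j$.row] <- j$feature
  out
}

#' Classify cleaned reads and call miRNA-mRNA chimeras
#'
#' Full classification chain: locate a miRNA in each read, split off the
#' target candidate, map it (or, for reads without a miRNA, the whole read)
#' to the transcriptome, and discard ncRNA hits.  Every read receives exactly
#' one class in `{chimera, mirna_only, clip, ncrna, unmapped, ambiguous}`.
#'
#' @param reads Collapsed reads (tibble with `read_id`, `sequence`, and
#'   optionally `dup_count`), e.g. from [prep_reads()].
#' @param mirnas,transcripts,annotation Reference tables as in [map_target()].
#' @param evalue_max E-value threshold for both alignment stages.
#' @param min_target_len Minimum target-candidate length (nt).
#' @inheritParams find_mirna_in_read
#' @inheritParams map_target
#' @return A list of class `ccl_calls`: `chimeras` (one row per chimeric read:
#'   `read_id`, `mirna_id`, `orientation`, target interval on the transcript,
#'   `ligation_offset` within the target segment, `region`, `multimapped`,
#'   `dup_count`), `clip` (read, transcript, interval, region, `multimapped`,
#'   `dup_count`), `classes` (`read_id`, `class`, `dup_count`) and `stats`.
#' @export
call_chimeras <- function(reads, mirnas, transcripts, annotation,
                          evalue_max = 0.4, min_target_len = 16,
                          word_size = 11, seed_k = 12, band = 16) {
  if (!"dup_count" %in% names(reads)) reads$dup_count <- 1L
  hits <- find_mirna_in_read(reads, mirnas, evalue_max, word_size)
  sp <- split_read(reads, hits, min_target_len)
  cls <- tibble::tibble(read_id = reads$read_id, class = NA_character_)
  cls$class[cls$read_id %in% sp$read_id[sp$status == "mirna_only"]] <- "mirna_only"
  cls$class[cls$read_id %in% sp$read_id[sp$status == "ambiguous"]] <- "ambiguous"

  # chimera candidates: map the target segment
  cand <- sp[sp$status == "target", ]
  chim <- NULL
  if (nrow(cand) > 0) {
    mt <- map_target(tibble::tibble(id = cand$read_id,
                                    sequence = cand$target_segment),
                     transcripts, annotation, evalue_max, seed_k, band)
    cand <- dplyr::bind_cols(cand, mt[, setdiff(names(mt), "id")])
    cls$class[cls$read_id %in% cand$read_id[cand$is_ncrna]] <- "ncrna"
    cls$class[cls$read_id %in%
                cand$read_id[is.na(cand$transcript_id)]] <- "unmapped"
    ok <- cand[!is.na(cand$transcript_id) & !cand$is_ncrna, ]
    if (nrow(ok) > 0) {
      cls$class[cls$read_id %in% ok$read_id] <- "chimera"
      chim <- tibble::tibble(
        read_id = ok$read_id, mirna_id = ok$mirna_id,
        orientation = ok$orientation,
        target_segment = ok$target_segment,
        transcript_id = ok$transcript_id,
        t_start = ok$t_start, t_end = ok$t_end,
        ligation_offset = ifelse(ok$orientation == "mir_first", 0L,
                                 nchar(ok$target_segment)),
        region = annotate_region(annotation, ok$transcript_id, ok$t_start,
                                 ok$t_end),
        multimapped = ok$multimapped,
        score = ok$score, evalue = ok$evalue)
      chim$dup_count <- reads$dup_count[match(chim$read_id, reads$read_id)]
    }
  }

  # reads without a usable miRNA hit: map the whole read
  rest_ids <- cls$read_id[is.na(cls$class)]
  clip <- NULL
  if (length(rest_ids) > 0) {
    rest <- reads[match(rest_ids, reads$read_id), ]
    mt <- map_target(tibble::tibble(id = rest$read_id,
                                    sequence = rest$sequence),
                     transcripts, annotation, evalue_max, seed_k, band)
    cls$class[cls$read_id %in% mt$id[mt$is_ncrna]] <- "ncrna"
    cls$class[cls$read_id %in% mt$id[is.na(mt$transcript_id)]] <- "unmapped"
    okc <- mt[!is.na(mt$transcript_id) & !mt$is_ncrna, ]
    if (nrow(okc) > 0) {
      cls$class[cls$read_id %in% okc$id] <- "clip"
      clip <- tibble::tibble(
        read_id = okc$id, transcript_id = okc$transcript_id,
        t_start = okc$t_start, t_end = okc$t_end,
        region = annotate_region(annotation, okc$transcript_id, okc$t_start,
                                 okc$t_end),
        multimapped = okc$multimapped)
      clip$dup_count <- reads$dup_count[match(clip$read_id, reads$read_id)]
    }
  }
  cls$dup_count <- reads$dup_count
  stats <- as.list(table(factor(cls$class,
                                levels = c("chimera", "mirna_only", "clip",
                                           "ncrna", "unmapped", "ambiguous"))))
  structure(list(chimeras = chim %||% empty_chimeras(),
                 clip = clip %||% empty_clip(),
                 classes = cls, stats = stats),
            class = "ccl_calls")
}

empty_chimeras <- function() {
  tibble::tibble(read_id = character(0), mirna_id = character(0),
                 orientation = character(0), target_segment = character(0),
                 transcript_id = character(0), t_start = integer(0),
                 t_end = integer(0), ligation_offset = integer(0),
                 region = character(0), multimapped = logical(0),
                 score = integer(0), evalue = numeric(0),
                 dup_count = integer(0))
}

empty_clip <- function() {
  tibble::tibble(read_id = character(0), transcript_id = character(0),
                 t_start = integer(0), t_end = integer(0),
                 region = character(0), multimapped = logical(0),
                 dup_count = integer(0))
}
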