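# Collapse chimera records into interactions, attach peak support, summarize
# read-class and region composition.

#' Cluster chimeras into miRNA-target interactions
#'
#' Chimeras with the same miRNA and transitively overlapping target intervals
#' on the same transcript are merged into one interaction; multimapped
#' chimeras are excluded.  When a `timepoint` column is present, interactions
#' are built per time point.
#'
#' @param chimeras Chimera table from [call_chimeras()] (optionally with a
#'   `timepoint` column).
#' @return Tibble: `interaction_id`, `timepoint`, `mirna_id`,
#'   `transcript_id`, `site_start`, `site_end` (union span, 0-based
#'   half-open), `unique_reads`, `region`, `member_read_ids` (list-column).
#' @export
build_interactions <- function(chimeras) {
  x <- chimeras[!isTRUE_or_col(chimeras$multimapped), , drop = FALSE]
  if (!"timepoint" %in% names(x)) x$timepoint <- "all"
  if (nrow(x) == 0) {
    return(tibble::tibble(interaction_id = character(0), timepoint = character(0),
                          mirna_id = character(0), transcript_id = character(0),
                          site_start = integer(0), site_end = integer(0),
                          unique_reads = integer(0), region = character(0),
                          member_read_ids = list()))
  }
  x <- dplyr::arrange(x, .data$timepoint, .data$mirna_id, .data$transcript_id,
                      .data$t_start, .data$t_end, .data$read_id)
  out <- x |>
    dplyr::group_by(.data$timepoint, .data$mirna_id, .data$transcript_id) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$t_start + 1L, end = d$t_end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, red)
      grp <- integer(nrow(d))
      grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
      purrr::map_dfr(seq_along(red), function(ci) {
        m <- which(grp == ci)
        reg <- sort(table(d$region[m]), decreasing = TRUE)
        tibble::tibble(
          site_start = IRanges::start(red)[ci] - 1L,
          site_end = IRanges::end(red)[ci],
          unique_reads = length(m),
          region = if (length(reg)) names(reg)[1] else NA_character_,
          member_read_ids = list(sort(d$read_id[m])))
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$timepoint, .data$mirna_id, .data$transcript_id,
                   .data$site_start)
  out$interaction_id <- sprintf("%s|%s|%d", out$mirna_id, out$transcript_id,
                                out$site_start)
  dplyr::relocate(out, "interaction_id")
}

isTRUE_or_col <- function(x) if (is.null(x)) FALSE else x

#' Flag interactions overlapping a significant binding peak
#'
#' `peak_supported` is true when the interaction's site interval overlaps a
#' significant peak on the same transcript (and time point) by at least 1 nt.
#' The height and summit of the best-overlapping significant peak are
#' attached for downstream normalization.
#'
#' @param interactions Output of [build_interactions()].
#' @param peaks Output of [call_peaks()].
#' @return `interactions` with `peak_supported`, `peak_height`,
#'   `peak_summit` columns.
#' @export
attach_peak_support <- function(interactions, peaks) {
  sig <- peaks[peaks$significant, , drop = FALSE]
  interactions$peak_supported <- FALSE
  interactions$peak_height <- NA_real_
  interactions$peak_summit <- NA_real_
  if (nrow(sig) == 0 || nrow(interactions) == 0) return(interactions)
  if (!"timepoint" %in% names(sig)) sig$timepoint <- "all"
  for (i in seq_len(nrow(interactions))) {
    cand <- sig[sig$transcript_id == interactions$transcript_id[i] &
                  sig$timepoint == interactions$timepoint[i] &
                  sig$start < interactions$site_end[i] &
                  sig$end > interactions$site_start[i], , drop = FALSE]
    if (nrow(cand)) {
      b <- which.max(cand$height)
      interactions$peak_supported[i] <- TRUE
      interactions$peak_height[i] <- cand$height[b]
      interactions$peak_summit[i] <- cand$summit[b]
    }
  }
  interactions
}

#' Read-class and transcript-region composition
#'
#' Class fractions are weighted by `dup_count` so they describe the raw
#' (pre-collapse) library; `ambiguous` and `unmapped` reads are reported as
#' `other`.  Region fractions are computed separately for chimeric targets
#' and CLIP reads.
#'
#' @param calls A `ccl_calls` object from [call_chimeras()].
#' @return A list of class `ccl_composition`: `classes` and `regions`
#'   tibbles with `n` (raw reads) and `fraction`.
#' @export
composition_summary <- function(calls) {
  cl <- calls$classes
  cl$group <- dplyr::recode(cl$class, ambiguous = "other", unmapped = "other")
  classes <- cl |>
    dplyr::count(.data$group, wt = .data$dup_count, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::rename(class = "group")
  region_tab <- function(d, what) {
    if (is.null(d) || nrow(d) == 0) {
      return(tibble::tibble(set = character(0), region = character(0),
                            n = numeric(0), fraction = numeric(0)))
    }
    d |>
      dplyr::filter(!is.na(.data$region)) |>
      dplyr::count(.data$region, wt = .data$dup_count, name = "n") |>
      dplyr::mutate(fraction = .data$n / sum(.data$n), set = what) |>
      dplyr::relocate("set")
  }
  regions <- dplyr::bind_rows(region_tab(calls$chimeras, "chimera_targets"),
                              region_tab(calls$clip, "clip_reads"))
  structure(list(classes = classes, regions = regions),
            class = "ccl_composition")
}
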