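# Perturbation-validation statistics: cumulative-distribution comparison of
# fold-changes (Kolmogorov-Smirnov) and translational efficiency.

#' Compare fold-change distributions of two transcript sets
#'
#' Two-sample Kolmogorov-Smirnov test on log2 fold-changes, with the
#' empirical CDF curves for plotting.
#'
#' @param table Tibble `transcript_id`, `log2fc`, `set_label`.
#' @param set_a,set_b Labels of the two (disjoint) sets to compare.
#' @return A list of class `ccl_cdf`: `statistic` (KS D), `p_value`,
#'   `curves` (tibble `set`, `log2fc`, `cdf`), `n_a`, `n_b`.
#' @export
cdf_compare <- function(table, set_a = "target", set_b = "nontarget") {
  a_ids <- table$transcript_id[table$set_label == set_a]
  b_ids <- table$transcript_id[table$set_label == set_b]
  if (length(intersect(a_ids, b_ids))) {
    abort("sets overlap", class = "clearclipr_config_error")
  }
  a <- table$log2fc[table$set_label == set_a]
  b <- table$log2fc[table$set_label == set_b]
  if (!length(a) || !length(b)) abort("both sets must be nonempty")
  ks <- suppressWarnings(ks.test(a, b))
  curves <- dplyr::bind_rows(
    tibble::tibble(set = set_a, log2fc = sort(a),
                   cdf = seq_along(a) / length(a)),
    tibble::tibble(set = set_b, log2fc = sort(b),
                   cdf = seq_along(b) / length(b)))
  structure(list(statistic = unname(ks$statistic), p_value = ks$p.value,
                 curves = curves, n_a = length(a), n_b = length(b),
                 set_a = set_a, set_b = set_b),
            class = "ccl_cdf")
}

# Median-of-ratios size factors (one per count column).
size_factors_mor <- function(counts) {
  m <- as.matrix(counts)
  logm <- log(m)
  logm[!is.finite(logm)] <- NA
  ref <- rowMeans(logm)
  apply(logm, 2, function(col) exp(median(col - ref, na.rm = TRUE)))
}

#' Translational efficiency from ribosome-footprint and mRNA counts
#'
#' Each assay is normalized by median-of-ratios size factors and then brought
#' to a common library scale (each normalized matrix is divided by its mean
#' normalized column total), so TE -- the normalized ribosome count divided
#' by the normalized mRNA count per transcript and sample -- is invariant to
#' global scaling of either assay.  Transcripts with fewer than `count_floor`
#' raw counts in every sample of either assay are dropped.
#'
#' @param ribo,mrna Tibbles: `transcript_id` plus one numeric column per
#'   sample (matching columns in both tables).
#' @param count_floor Minimum raw count (see above).
#' @return Tibble `transcript_id`, `sample`, `te`, with attribute
#'   `dropped_transcripts`.
#' @export
translational_efficiency <- function(ribo, mrna, count_floor = 10) {
  samples <- intersect(setdiff(names(ribo), "transcript_id"),
                       setdiff(names(mrna), "transcript_id"))
  if (!length(samples)) abort("no shared sample columns")
  common <- intersect(ribo$transcript_id, mrna$transcript_id)
  r <- ribo[match(common, ribo$transcript_id), samples, drop = FALSE]
  m <- mrna[match(common, mrna$transcript_id), samples, drop = FALSE]
  sr <- size_factors_mor(r)
  sm <- size_factors_mor(m)
  rn <- sweep(as.matrix(r), 2, sr, "/")
  mn <- sweep(as.matrix(m), 2, sm, "/")
  rn <- rn / mean(colSums(rn))
  mn <- mn / mean(colSums(mn))
  keep <- apply(as.matrix(r), 1, max) >= count_floor &
    apply(as.matrix(m), 1, max) >= count_floor &
    apply(mn, 1, min) > 0
  dropped <- common[!keep]
  te <- rn[keep, , drop = FALSE] / mn[keep, , drop = FALSE]
  out <- tibble::as_tibble(te) |>
    dplyr::mutate(transcript_id = common[keep], .before = 1) |>
    tidyr::pivot_longer(-"transcript_id", names_to = "sample",
                        values_to = "te")
  attr(out, "dropped_transcripts") <- dropped
  out
}

#' Per-transcript TE ratio between two conditions
#'
#' @param te Output of [translational_efficiency()].
#' @param treated,control Regular expressions matching sample names of the
#'   two conditions.
#' @return Tibble `transcript_id`, `te_treated`, `te_control`, `te_ratio`.
#' @export
te_ratio <- function(te, treated = "^treated", control = "^control") {
  te |>
    dplyr::mutate(condition = dplyr::case_when(
      grepl(treated, .data$sample) ~ "treated",
      grepl(control, .data$sample) ~ "control",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$condition)) |>
    dplyr::group_by(.data$transcript_id, .data$condition) |>
    dplyr::summarise(te = mean(.data$te), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "te",
                       names_prefix = "te_") |>
    dplyr::filter(.data$te_control > 0) |>
    dplyr::mutate(te_ratio = .data$te_treated / .data$te_control)
}
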