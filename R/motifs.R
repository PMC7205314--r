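# Seed-match density around ligation sites, per-miRNA 7-mer enrichment with
# ZOOPS counting and hypergeometric tests, motif-register mapping onto the
# miRNA, and per-time-point motif-usage matrices.

#' Reverse complement of the miRNA seed (nucleotides 2-7 by default)
#'
#' @param mirna_seq miRNA sequence(s) (RNA or DNA).
#' @param from,to 1-based miRNA positions of the seed.
#' @return DNA reverse-complement seed match string(s).
#' @export
seed_rc <- function(mirna_seq, from = 2, to = 7) {
  rc_dna(substr(as_dna(mirna_seq), from, to))
}

#' Density of canonical seed matches relative to the ligation site
#'
#' For each chimera, occurrences of the reverse complement of its miRNA's
#' seed (nt 2-7) are located on the transcript within `window_nt` of the
#' ligation site (the target-fragment boundary that was ligated to the
#' miRNA); offsets are aggregated into a per-position density normalized per
#' chimera.  The control repeats the computation after a shuffled
#' reassignment of targets to different miRNAs.
#'
#' @param chimeras Chimera table with `mirna_id`, `transcript_id`, `t_start`,
#'   `t_end`, `orientation`.
#' @param mirnas Tibble `mirna_id`, `sequence`.
#' @param transcripts Tibble `transcript_id`, `sequence`.
#' @param window_nt Window half-width around the ligation site (nt).
#' @param shuffle_seed Seed for the shuffled control.
#' @return Tibble: `offset` (-window..window), `real`, `shuffled`
#'   (occurrences per chimera).
#' @export
seed_match_density <- function(chimeras, mirnas, transcripts, window_nt = 100,
                               shuffle_seed = 1) {
  one_density <- function(ch) {
    mseq <- stats::setNames(mirnas$sequence, mirnas$mirna_id)
    tseq <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
    counts <- numeric(2 * window_nt + 1)
    for (i in seq_len(nrow(ch))) {
      seed <- seed_rc(mseq[[ch$mirna_id[i]]])
      lig <- if (ch$orientation[i] == "mir_first") ch$t_start[i] else ch$t_end[i]
      s <- tseq[[ch$transcript_id[i]]]
      lo <- max(0L, lig - window_nt)
      hi <- min(nchar(s), lig + window_nt + nchar(seed))
      win <- substr(s, lo + 1L, hi)
      hitpos <- gregexpr(seed, win, fixed = TRUE)[[1]]
      if (hitpos[1] == -1) next
      off <- (hitpos - 1L) + lo - lig
      off <- off[off >= -window_nt & off <= window_nt]
      counts[off + window_nt + 1] <- counts[off + window_nt + 1] + 1
    }
    counts / max(1L, nrow(ch))
  }
  real <- one_density(chimeras)
  shuf <- one_density(shuffled_null(chimeras, seed = shuffle_seed))
  tibble::tibble(offset = -window_nt:window_nt, real = real, shuffled = shuf)
}

zoops_counts <- function(seqs, k) {
  km <- lapply(as_dna(seqs), function(s) unique(kmers_of(s, k)))
  table(unlist(km))
}

# Per-column information content (bits) of exact k-mer instances is 2 by
# construction; computed from the instance profile for completeness.
kmer_information_content <- function(instances) {
  if (!length(instances)) return(0)
  k <- nchar(instances[1])
  cols <- vapply(seq_len(k), function(i) {
    p <- table(factor(substr(instances, i, i), levels = DNA_BASES))
    p <- p / sum(p)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  mean(cols)
}

#' Overrepresented k-mers in one miRNA's targets
#'
#' ZOOPS counting (each target counts at most once per k-mer) against a
#' background set, hypergeometric p-values, Bonferroni correction over all
#' 4^k possible k-mers.
#'
#' @param targets Character vector of target sequences for one miRNA.
#' @param background Character vector of background sequences (conventionally
#'   five times the target count, sampled from other miRNAs' targets).
#' @param k k-mer length.
#' @param alpha Significance threshold on the corrected p-value.
#' @param min_targets Minimum number of targets; below this the miRNA is
#'   skipped (returns zero rows).
#' @return Tibble sorted by p-value: `kmer`, `n_targets_with_motif`,
#'   `n_targets`, `background_rate`, `pvalue`, `corrected_pvalue`,
#'   `information_content`, `passing`.
#' @export
enrich_kmers <- function(targets, background, k = 7, alpha = 0.05,
                         min_targets = 30) {
  empty <- tibble::tibble(kmer = character(0), n_targets_with_motif = integer(0),
                          n_targets = integer(0), background_rate = numeric(0),
                          pvalue = numeric(0), corrected_pvalue = numeric(0),
                          information_content = numeric(0), passing = logical(0))
  if (length(targets) < min_targets) return(empty)
  tc <- zoops_counts(targets, k)
  if (!length(tc)) return(empty)
  bc <- zoops_counts(background, k)
  n_t <- length(targets); n_b <- length(background)
  kmer <- names(tc)
  x <- as.integer(tc)
  bg <- as.integer(bc[kmer]); bg[is.na(bg)] <- 0L
  white <- x + bg
  p <- stats::phyper(x - 1L, white, n_t + n_b - white, n_t, lower.tail = FALSE)
  padj <- pmin(1, p * 4^k)
  out <- tibble::tibble(kmer = kmer, n_targets_with_motif = x,
                        n_targets = n_t, background_rate = bg / max(1L, n_b),
                        pvalue = p, corrected_pvalue = padj,
                        information_content = 2,
                        passing = padj < alpha) |>
    dplyr::arrange(.data$pvalue, dplyr::desc(.data$n_targets_with_motif),
                   .data$kmer)
  out
}

#' Map a motif k-mer onto miRNA positions (register)
#'
#' Slides the k-mer along the reverse-complemented miRNA, counts matching
#' positions at each offset, and reports registers with at least
#' `min_matches` of `k` matches, translated into 1-based miRNA 5'->3'
#' positions (best register first).
#'
#' @param kmer Motif sequence (length <= miRNA length).
#' @param mirna miRNA sequence.
#' @param min_matches Minimum matching positions to report a register.
#' @return Tibble: `register_start` (1-based miRNA position of the 5'-most
#'   complementary base), `register_end`, `matches`.
#' @export
map_motif_register <- function(kmer, mirna, min_matches = 6) {
  kmer <- as_dna(kmer); mirna <- as_dna(mirna)
  k <- nchar(kmer); L <- nchar(mirna)
  if (k > L) abort("kmer longer than miRNA")
  rcm <- rc_dna(mirna)
  kc <- strsplit(kmer, "")[[1]]
  offs <- 0:(L - k)
  matches <- vapply(offs, function(o) {
    sum(strsplit(substr(rcm, o + 1, o + k), "")[[1]] == kc)
  }, numeric(1))
  keep <- matches >= min_matches
  tibble::tibble(register_start = L - (offs[keep] + k - 1L),
                 register_end = L - offs[keep],
                 matches = as.integer(matches[keep])) |>
    dplyr::arrange(dplyr::desc(.data$matches), .data$register_start)
}

#' Motif-usage matrix across miRNA positions and time points
#'
#' For every (miRNA, time point) with at least `min_targets` unique targets,
#' k-mers are tested for enrichment against a background sampled from other
#' miRNAs' targets (`bg_times` times the target count, seeded).  Motifs are
#' retained when the corrected p-value is below `alpha`, the best register
#' matches at least `register_min` of `k` positions, and the instance
#' information content is at least `ic_min` bits per position.  Cells give
#' the proportion of the miRNA's targets carrying a retained motif whose
#' register covers the position; miRNAs absent (or below `min_targets`) at a
#' time point give NA.
#'
#' @param chimera_targets Tibble with `mirna_id`, `timepoint`,
#'   `target_segment` (one row per unique chimera).
#' @param mirnas Tibble `mirna_id`, `sequence`.
#' @param k k-mer length.
#' @param min_targets Minimum unique targets per (miRNA, time point).
#' @param alpha Corrected-p threshold.
#' @param ic_min Minimum information content (bits/position).
#' @param register_min Minimum register matches (of `k`).
#' @param bg_times Background size as a multiple of the target count.
#' @param top_only Keep only the top passing motif per (miRNA, time point).
#' @param seed Seed for background sampling.
#' @return A list of class `ccl_usage`: `usage` (long tibble `mirna_id`,
#'   `position`, `timepoint`, `proportion`) and `motifs` (per-cell motif
#'   table with registers).
#' @export
usage_by_timepoint <- function(chimera_targets, mirnas, k = 7,
                               min_targets = 30, alpha = 0.05, ic_min = 1.5,
                               register_min = 6, bg_times = 5,
                               top_only = TRUE, seed = 1) {
  mseq <- stats::setNames(mirnas$sequence, mirnas$mirna_id)
  tps <- unique(chimera_targets$timepoint)
  mirs <- sort(unique(chimera_targets$mirna_id))
  motif_rows <- list()
  usage_rows <- list()
  with_seed(seed, {
    for (tp in tps) {
      d <- chimera_targets[chimera_targets$timepoint == tp, ]
      for (mi in mirs) {
        targ <- d$target_segment[d$mirna_id == mi]
        L <- nchar(mseq[[mi]])
        if (length(targ) < min_targets) {
          usage_rows[[length(usage_rows) + 1]] <- tibble::tibble(
            mirna_id = mi, position = seq_len(L), timepoint = tp,
            proportion = NA_real_)
          next
        }
        other <- d$target_segment[d$mirna_id != mi]
        n_bg <- min(length(other), bg_times * length(targ))
        bg <- sample(other, n_bg, replace = length(other) < n_bg)
        enr <- enrich_kmers(targ, bg, k = k, alpha = alpha,
                            min_targets = min_targets)
        enr <- enr[enr$passing & enr$information_content >= ic_min, ]
        cover <- numeric(L)
        kept <- 0L
        if (nrow(enr)) {
          for (r in seq_len(nrow(enr))) {
            regs <- map_motif_register(enr$kmer[r], mseq[[mi]], register_min)
            if (!nrow(regs)) next
            kept <- kept + 1L
            prop <- enr$n_targets_with_motif[r] / enr$n_targets[r]
            span <- regs$register_start[1]:regs$register_end[1]
            span <- span[span >= 1 & span <= L]
            cover[span] <- pmax(cover[span], prop)
            motif_rows[[length(motif_rows) + 1]] <- dplyr::mutate(
              enr[r, ], mirna_id = mi, timepoint = tp,
              register_start = regs$register_start[1],
              register_end = regs$register_end[1],
              register_matches = regs$matches[1], .before = 1)
            if (top_only) break
          }
        }
        usage_rows[[length(usage_rows) + 1]] <- tibble::tibble(
          mirna_id = mi, position = seq_len(L), timepoint = tp,
          proportion = cover)
      }
    }
  })
  structure(list(usage = dplyr::bind_rows(usage_rows),
                 motifs = dplyr::bind_rows(motif_rows)),
            class = "ccl_usage")
}
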