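#' Simulation configuration for synthetic chimeric CLIP libraries
#'
#' Builds the configuration object consumed by [sim_reference()],
#' [sim_plant_interactions()] and [sim_library()].  Defaults emulate the
#' statistical structure of a chimeric Argonaute CLIP experiment in adult
#' female mosquitoes: a read-class mix with ~1.7% miRNA-mRNA chimeras, ~77%
#' CLIP-only mRNA reads, ~10% miRNA-only reads and ~11% structural ncRNA, five
#' reproductive time points, target fragments of ~42 nt, a degenerate 3-nt
#' 5' barcode and the standard Illumina 3' adapter.
#'
#' @param n_transcripts Number of mRNA transcripts in the toy transcriptome.
#' @param transcript_len_range Min/max transcript length (nt).
#' @param utr_fractions Named proportions of transcript length allocated to
#'   `5UTR`, `CDS` and `3UTR`; must sum to 1.
#' @param n_ncrna Number of high-GC rRNA/tRNA decoy transcripts.
#' @param n_mirnas Number of mature miRNAs.
#' @param mirna_len_range Min/max mature miRNA length (nt).
#' @param n_interactions Number of planted miRNA-target interactions.
#' @param site_class_mix Proportions over site classes `canonical`,
#'   `supplementary`, `central`, `seedless`; must sum to 1.
#' @param timepoints Ordered time-point labels.
#' @param n_reads Total reads per simulated library (including PCR duplicates).
#' @param read_class_mix Proportions over read classes `chimera`, `clip`,
#'   `mirna_only`, `ncrna`, `junk`; must sum to 1.
#' @param chimera_orientation_mix Proportions for `mir_first` vs `mir_last`.
#' @param target_segment_len List with `mean`, `sd`, `min` of the truncated
#'   normal target-fragment length distribution (nt).
#' @param site_offset_nt Distance (nt) from the ligation junction to the
#'   planted complementary window within a chimera's target fragment.
#' @param site_offset_jitter SD (nt) of Gaussian jitter on that distance.
#' @param registers Named list of `c(from, to)` 1-based miRNA positions whose
#'   reverse complement is planted for each non-seedless site class.
#' @param pcr_dup_rate Proportion of reads that are PCR duplicates of another
#'   read in the same library.
#' @param error_rate Per-base substitution error probability (applied to each
#'   unique molecule before duplication, i.e. amplification-stage errors).
#' @param read_length Sequencer read length (nt); inserts plus adapter are
#'   truncated to this length.
#' @param adapter 3' adapter DNA sequence.
#' @param barcode_len Length of the degenerate 5' barcode.
#' @param clip_background_frac Fraction of CLIP reads placed uniformly on
#'   transcripts rather than over planted sites.
#' @param expression_meanlog,expression_sdlog Log-normal parameters for the
#'   simulated mRNA abundance table.
#' @param rng_seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A list of class `ccl_config`.
#' @export
sim_config <- function(n_transcripts = 300,
                       transcript_len_range = c(500, 3000),
                       utr_fractions = c(`5UTR` = 0.1, CDS = 0.5, `3UTR` = 0.4),
                       n_ncrna = 20,
                       n_mirnas = 50,
                       mirna_len_range = c(21, 23),
                       n_interactions = 300,
                       site_class_mix = c(canonical = 0.6, supplementary = 0.15,
                                          central = 0.15, seedless = 0.1),
                       timepoints = c("3hPE", "30hPE", "120hPE", "24hPBM", "48hPBM"),
                       n_reads = 50000,
                       read_class_mix = c(chimera = 0.0170, clip = 0.7707,
                                          mirna_only = 0.1030, ncrna = 0.1096,
                                          junk = 0) / 1.0003,
                       chimera_orientation_mix = c(mir_first = 0.7, mir_last = 0.3),
                       target_segment_len = list(mean = 42, sd = 10, min = 16),
                       site_offset_nt = 20,
                       site_offset_jitter = 3,
                       registers = list(canonical = c(2, 8),
                                        supplementary = c(13, 19),
                                        central = c(9, 15)),
                       pcr_dup_rate = 0.2,
                       error_rate = 0.005,
                       read_length = 100,
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       barcode_len = 3,
                       clip_background_frac = 0.3,
                       expression_meanlog = log(50),
                       expression_sdlog = 1,
                       rng_seed = 1) {
  check_proportions(utr_fractions, "utr_fractions")
  check_proportions(site_class_mix, "site_class_mix")
  check_proportions(read_class_mix, "read_class_mix")
  check_proportions(chimera_orientation_mix, "chimera_orientation_mix")
  stopifnot(n_transcripts >= 1, n_mirnas >= 1,
            transcript_len_range[1] <= transcript_len_range[2],
            mirna_len_range[1] <= mirna_len_range[2],
            pcr_dup_rate >= 0, pcr_dup_rate < 1, error_rate >= 0,
            target_segment_len$min >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "ccl_config")
}

#' Generate a toy reference: transcriptome, annotation and mirnome
#'
#' Transcripts carry contiguous 5'UTR/CDS/3'UTR blocks whose lengths follow
#' `utr_fractions`.  ncRNA decoys are GC-rich so that mis-mapping is
#' detectable.  miRNA sequences are unique.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ccl_reference` with tibbles `transcripts`
#'   (`transcript_id`, `sequence`, `length`, `type`), `annotation`
#'   (`transcript_id`, `feature`, `start`, `end`; 0-based half-open) and
#'   `mirnas` (`mirna_id`, `sequence`, `length`).
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "ccl_config"))
  with_seed(config$rng_seed, {
    n <- config$n_transcripts
    lens <- sample(config$transcript_len_range[1]:config$transcript_len_range[2],
                   n, replace = TRUE)
    tx_id <- sprintf("TX%04d", seq_len(n))
    tx_seq <- random_dna(lens)
    len5 <- round(config$utr_fractions[["5UTR"]] * lens)
    lenc <- round(config$utr_fractions[["CDS"]] * lens)
    ann <- tibble::tibble(
      transcript_id = rep(tx_id, each = 3),
      feature = rep(c("5UTR", "CDS", "3UTR"), n),
      start = as.integer(rbind(0, len5, len5 + lenc)),
      end = as.integer(rbind(len5, len5 + lenc, lens)))
    nc <- config$n_ncrna
    if (nc > 0) {
      nc_len <- sample(100:1500, nc, replace = TRUE)
      nc_id <- sprintf("NC%03d", seq_len(nc))
      nc_seq <- random_dna(nc_len, prob = c(0.1, 0.4, 0.4, 0.1))
      nc_feat <- rep(c("rRNA", "tRNA"), length.out = nc)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        transcript_id = nc_id, feature = nc_feat,
        start = 0L, end = as.integer(nc_len)))
    } else {
      nc_id <- character(0); nc_seq <- character(0); nc_len <- integer(0)
    }
    mlen <- sample(config$mirna_len_range[1]:config$mirna_len_range[2],
                   config$n_mirnas, replace = TRUE)
    mseq <- random_dna(mlen)
    while (anyDuplicated(mseq)) {
      i <- which(duplicated(mseq))
      mseq[i] <- random_dna(mlen[i])
    }
    transcripts <- tibble::tibble(
      transcript_id = c(tx_id, nc_id),
      sequence = c(tx_seq, nc_seq),
      length = c(as.integer(lens), as.integer(nc_len)),
      type = c(rep("mRNA", n), rep("ncRNA", nc)))
    mirnas <- tibble::tibble(
      mirna_id = sprintf("miR-%03d", seq_len(config$n_mirnas)),
      sequence = mseq, length = as.integer(mlen)) |>
      dplyr::arrange(.data$mirna_id)
    structure(list(transcripts = transcripts, annotation = ann,
                   mirnas = mirnas, config = config),
              class = "ccl_reference")
  })
}

# Register interval (1-based inclusive) for a site class.
class_register <- function(class, config) {
  if (class == "seedless") return(NULL)
  config$registers[[class]]
}

#' Plant ground-truth miRNA-target interactions into a reference
#'
#' Canonical-seed sites receive the reverse complement of miRNA nucleotides
#' 2-8 (which contains the 2-7 seed match), 3'-supplementary sites the reverse
#' complement of nucleotides 13-19, central sites of 9-15 (registers are
#' configurable).  Seedless sites are guaranteed to contain no 6-mer
#' complementary to miRNA nucleotides 1-8.  Each interaction receives a
#' stage-activity profile drawn from time-point-peaked archetypes, scaled by a
#' log-normal miRNA abundance weight (so chimera frequency tracks miRNA
#' abundance, as observed in real libraries).
#'
#' @param reference A [sim_reference()] object.
#' @param config A [sim_config()] object.
#' @return A list of class `ccl_truth`: `reference` (with site sequences
#'   written into the transcripts), `interactions` tibble (0-based half-open
#'   `site_start`/`site_end`, `site_class`, `archetype`, one `activity_*`
#'   column per time point, `mirna_weight`), `mirna_weights`, and `skipped`.
#' @export
sim_plant_interactions <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "ccl_reference"))
  with_seed(config$rng_seed + 1L, {
    tx <- dplyr::filter(reference$transcripts, .data$type == "mRNA")
    mir <- reference$mirnas
    n_tp <- length(config$timepoints)
    weights <- stats::setNames(rlnorm(nrow(mir), 0, 1), mir$mirna_id)
    classes <- sample(names(config$site_class_mix), config$n_interactions,
                      replace = TRUE, prob = config$site_class_mix)
    seqs <- stats::setNames(tx$sequence, tx$transcript_id)
    occupied <- stats::setNames(vector("list", nrow(tx)), tx$transcript_id)
    rows <- vector("list", config$n_interactions)
    skipped <- integer(0)
    for (i in seq_len(config$n_interactions)) {
      m_i <- sample.int(nrow(mir), 1, prob = weights)
      cls <- classes[i]
      reg <- class_register(cls, config)
      site_len <- if (is.null(reg)) 7L else reg[2] - reg[1] + 1L
      placed <- FALSE
      for (try in 1:50) {
        t_i <- sample.int(nrow(tx), 1)
        tid <- tx$transcript_id[t_i]
        tlen <- tx$length[t_i]
        if (tlen < site_len + 2) next
        pos <- sample.int(tlen - site_len + 1L, 1) - 1L  # 0-based start
        iv <- c(pos, pos + site_len)
        occ <- occupied[[tid]]
        clash <- any(vapply(occ, function(o) iv[1] < o[2] && o[1] < iv[2],
                            logical(1)))
        if (clash) next
        mseq <- mir$sequence[m_i]
        if (is.null(reg)) {
          # seedless: random window with no 6-mer complementary to nt 1-8
          banned <- rc_dna(substring(mseq, 1:3, 6:8))
          repeat {
            win <- random_dna(site_len)
            ctx <- paste0(substr(seqs[[tid]], max(1, pos - 5), pos),
                          win,
                          substr(seqs[[tid]], pos + site_len + 1,
                                 min(tlen, pos + site_len + 6)))
            if (!any(vapply(banned, function(b) grepl(b, ctx, fixed = TRUE),
                            logical(1)))) break
          }
          site_seq <- win
        } else {
          site_seq <- rc_dna(substr(mseq, reg[1], reg[2]))
        }
        substr(seqs[[tid]], pos + 1L, pos + site_len) <- site_seq
        occupied[[tid]] <- c(occ, list(iv))
        arch <- sample.int(n_tp, 1)
        act <- exp(-((seq_len(n_tp) - arch)^2) / (2 * 0.8^2))
        act <- act / max(act) * rlnorm(1, 0, 0.3)
        rows[[i]] <- tibble::tibble(
          interaction_id = sprintf("INT%04d", i),
          mirna_id = mir$mirna_id[m_i], transcript_id = tid,
          site_start = as.integer(pos), site_end = as.integer(pos + site_len),
          site_class = cls,
          register_start = if (is.null(reg)) NA_integer_ else as.integer(reg[1]),
          register_end = if (is.null(reg)) NA_integer_ else as.integer(reg[2]),
          archetype = as.integer(arch),
          mirna_weight = unname(weights[mir$mirna_id[m_i]]),
          !!!stats::setNames(as.list(act), paste0("activity_", config$timepoints)))
        placed <- TRUE
        break
      }
      if (!placed) {
        skipped <- c(skipped, i)
        warn(sprintf("interaction %d could not be placed; skipped", i))
      }
    }
    interactions <- dplyr::bind_rows(rows)
    ref2 <- reference
    idx <- match(names(seqs), ref2$transcripts$transcript_id)
    ref2$transcripts$sequence[idx] <- unname(seqs)
    structure(list(reference = ref2, interactions = interactions,
                   mirna_weights = weights, skipped = skipped,
                   config = config),
              class = "ccl_truth")
  })
}

# Truncated-normal fragment lengths (rounded, lower-truncated).
frag_lengths <- function(n, spec) {
  l <- round(rnorm(n, spec$mean, spec$sd))
  pmax(l, spec$min)
}

#' Simulate one sequencing library for a time point
#'
#' Each read is a 3-nt degenerate barcode, an insert and the 3' adapter,
#' truncated at the configured read length.  Chimeric inserts concatenate a
#' full mature miRNA with a target fragment overlapping the planted site
#' (miR-first or miR-last); CLIP inserts sample fragments around the sites of
#' interactions active at the time point (plus a uniform background); PCR
#' duplicates replicate the (barcode, insert) pair exactly; substitution
#' errors are applied to each unique molecule.
#'
#' @param truth A [sim_plant_interactions()] object.
#' @param timepoint One of `config$timepoints`.
#' @param config Configuration; defaults to the one stored in `truth`.
#' @param seed Seed for this library; defaults to a stable offset of
#'   `config$rng_seed` and the time-point index.
#' @return A list of class `ccl_library`: `reads` tibble (`read_id`,
#'   `sequence`, `quality`) and `labels` tibble (one row per read: true
#'   `class`, `mirna_id`, `transcript_id`, fragment interval, `orientation`,
#'   `interaction_id`, `barcode`, `insert`, `is_duplicate`).
#' @export
sim_library <- function(truth, timepoint, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "ccl_truth"))
  tp_i <- match(timepoint, config$timepoints)
  if (is.na(tp_i)) abort(sprintf("unknown timepoint '%s'", timepoint))
  seed <- seed %||% (config$rng_seed + 100L + tp_i)
  ref <- truth$reference
  tx <- dplyr::filter(ref$transcripts, .data$type == "mRNA")
  ncs <- dplyr::filter(ref$transcripts, .data$type == "ncRNA")
  mir <- ref$mirnas
  ints <- truth$interactions
  act <- ints[[paste0("activity_", timepoint)]]
  int_w <- ints$mirna_weight * act
  with_seed(seed, {
    n_unique <- max(1L, round(config$n_reads * (1 - config$pcr_dup_rate)))
    cls <- sample(names(config$read_class_mix), n_unique, replace = TRUE,
                  prob = config$read_class_mix)
    n_cls <- table(factor(cls, levels = names(config$read_class_mix)))
    out <- vector("list", n_unique)
    lab <- vector("list", n_unique)
    mk_label <- function(class, mirna = NA_character_, tid = NA_character_,
                         fs = NA_integer_, fe = NA_integer_,
                         orient = NA_character_, int_id = NA_character_) {
      list(class = class, mirna_id = mirna, transcript_id = tid,
           frag_start = fs, frag_end = fe, orientation = orient,
           interaction_id = int_id)
    }
    tx_seq <- stats::setNames(tx$sequence, tx$transcript_id)
    tx_len <- stats::setNames(tx$length, tx$transcript_id)
    for (u in seq_len(n_unique)) {
      cl <- cls[u]
      if (cl == "chimera" && nrow(ints) > 0 && sum(int_w) > 0) {
        i <- sample.int(nrow(ints), 1, prob = int_w)
        tid <- ints$transcript_id[i]
        tlen <- tx_len[[tid]]
        slen <- ints$site_end[i] - ints$site_start[i]
        orient <- sample(names(config$chimera_orientation_mix), 1,
                         prob = config$chimera_orientation_mix)
        L <- frag_lengths(1, config$target_segment_len)
        off <- max(0L, round(config$site_offset_nt +
                               rnorm(1, 0, config$site_offset_jitter)))
        L <- max(L, off + slen + 1L)
        if (orient == "mir_first") {
          fs <- ints$site_start[i] - off
        } else {
          fs <- ints$site_end[i] + off - L
        }
        fs <- max(0L, min(fs, tlen - L))
        if (fs < 0L) { fs <- 0L; L <- min(L, tlen) }
        fe <- min(tlen, fs + L)
        frag <- substr(tx_seq[[tid]], fs + 1L, fe)
        mseq <- mir$sequence[match(ints$mirna_id[i], mir$mirna_id)]
        insert <- if (orient == "mir_first") paste0(mseq, frag) else paste0(frag, mseq)
        lab[[u]] <- mk_label("chimera", ints$mirna_id[i], tid,
                             as.integer(fs), as.integer(fe), orient,
                             ints$interaction_id[i])
        out[[u]] <- insert
      } else if (cl == "clip" && nrow(tx) > 0) {
        if (nrow(ints) > 0 && sum(int_w) > 0 &&
            runif(1) > config$clip_background_frac) {
          i <- sample.int(nrow(ints), 1, prob = int_w)
          tid <- ints$transcript_id[i]
          tlen <- tx_len[[tid]]
          L <- frag_lengths(1, config$target_segment_len)
          mid <- (ints$site_start[i] + ints$site_end[i]) %/% 2 +
            round(rnorm(1, 0, 10))
          fs <- max(0L, min(round(mid - L / 2), tlen - L))
          int_id <- ints$interaction_id[i]
        } else {
          t_i <- sample.int(nrow(tx), 1)
          tid <- tx$transcript_id[t_i]
          tlen <- tx_len[[tid]]
          L <- frag_lengths(1, config$target_segment_len)
          L <- min(L, tlen)
          fs <- sample.int(max(1L, tlen - L + 1L), 1) - 1L
          int_id <- NA_character_
        }
        fe <- min(tlen, fs + L)
        lab[[u]] <- mk_label("clip", NA, tid, as.integer(fs), as.integer(fe),
                             int_id = int_id)
        out[[u]] <- substr(tx_seq[[tid]], fs + 1L, fe)
      } else if (cl == "mirna_only") {
        m_i <- sample.int(nrow(mir), 1, prob = truth$mirna_weights[mir$mirna_id])
        lab[[u]] <- mk_label("mirna_only", mir$mirna_id[m_i])
        out[[u]] <- mir$sequence[m_i]
      } else if (cl == "ncrna" && nrow(ncs) > 0) {
        t_i <- sample.int(nrow(ncs), 1)
        tlen <- ncs$length[t_i]
        L <- min(frag_lengths(1, config$target_segment_len), tlen)
        fs <- sample.int(max(1L, tlen - L + 1L), 1) - 1L
        fe <- min(tlen, fs + L)
        lab[[u]] <- mk_label("ncrna", NA, ncs$transcript_id[t_i],
                             as.integer(fs), as.integer(fe))
        out[[u]] <- substr(ncs$sequence[t_i], fs + 1L, fe)
      } else {
        L <- frag_lengths(1, config$target_segment_len)
        lab[[u]] <- mk_label("junk")
        out[[u]] <- random_dna(L)
      }
    }
    inserts <- mutate_seq(unlist(out), config$error_rate)
    barcodes <- random_dna(rep(config$barcode_len, n_unique))
    labels <- dplyr::bind_rows(lapply(lab, tibble::as_tibble))
    labels$barcode <- barcodes
    labels$insert <- inserts
    labels$is_duplicate <- FALSE
    n_dup <- config$n_reads - n_unique
    if (n_dup > 0) {
      src <- sample.int(n_unique, n_dup, replace = TRUE)
      dup <- labels[src, ]
      dup$is_duplicate <- TRUE
      labels <- dplyr::bind_rows(labels, dup)
    }
    labels$read_id <- sprintf("%s_read%06d", timepoint, seq_len(nrow(labels)))
    seqs <- substr(paste0(labels$barcode, labels$insert, config$adapter),
                   1L, config$read_length)
    reads <- tibble::tibble(read_id = labels$read_id, sequence = seqs,
                            quality = phred_string(nchar(seqs)))
    structure(list(reads = reads,
                   labels = dplyr::relocate(labels, "read_id"),
                   timepoint = timepoint, seed = seed),
              class = "ccl_library")
  })
}

#' Simulate per-time-point mRNA abundance
#'
#' @param reference A reference (possibly from a `ccl_truth`).
#' @param config Configuration.
#' @return Tibble `transcript_id`, `timepoint`, `abundance` (arbitrary
#'   abundance units, log-normal).
#' @export
sim_expression <- function(reference, config = reference$config) {
  tx <- dplyr::filter(reference$transcripts, .data$type == "mRNA")
  with_seed(config$rng_seed + 50L, {
    tidyr::expand_grid(transcript_id = tx$transcript_id,
                       timepoint = config$timepoints) |>
      dplyr::mutate(abundance = rlnorm(dplyr::n(), config$expression_meanlog,
                                       config$expression_sdlog))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits transcript and miRNA FASTA, annotation and ground-truth TSVs, one
#' FASTQ plus read-label TSV per time point, an expression TSV and a manifest
#' JSON recording the configuration and seed.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @param timepoints Time points to simulate (default all configured ones).
#' @return Invisibly, a list with the `ccl_truth` and the file paths.
#' @export
sim_dataset <- function(config, dir, timepoints = config$timepoints) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- sim_reference(config)
  truth <- sim_plant_interactions(ref, config)
  tx <- truth$reference$transcripts
  fa_tx <- file.path(dir, "transcripts.fa")
  writeLines(paste0(">", tx$transcript_id, "\n", tx$sequence), fa_tx)
  fa_mir <- file.path(dir, "mirnas.fa")
  writeLines(paste0(">", ref$mirnas$mirna_id, "\n", ref$mirnas$sequence), fa_mir)
  readr::write_tsv(truth$reference$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(truth$interactions, file.path(dir, "ground_truth.tsv"))
  expr <- sim_expression(truth$reference, config)
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  fq <- character(0)
  for (tp in timepoints) {
    lib <- sim_library(truth, tp, config)
    f <- file.path(dir, paste0("library_", tp, ".fastq"))
    writeLines(paste0("@", lib$reads$read_id, "\n", lib$reads$sequence,
                      "\n+\n", lib$reads$quality), f)
    readr::write_tsv(lib$labels, file.path(dir, paste0("labels_", tp, ".tsv")))
    fq <- c(fq, f)
  }
  cfg <- unclass(config)
  cfg$registers <- lapply(cfg$registers, as.integer)
  jsonlite::write_json(list(config = cfg, seed = config$rng_seed,
                            timepoints = timepoints),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, expression = expr, dir = dir, fastq = fq))
}

#' Synthetic interaction-by-time-point profile matrix with planted archetypes
#'
#' Rows follow one of `n_archetypes` temporal programs (each peaked at evenly
#' spaced time points) plus Gaussian noise; used to exercise the SOM and
#' clustering stages against planted truth.
#'
#' @param n Number of rows (interactions).
#' @param timepoints Column labels.
#' @param n_archetypes Number of planted programs.
#' @param noise_sd Gaussian noise SD added to the archetype profile.
#' @param seed RNG seed.
#' @return A list: `matrix` (tibble with `interaction_id` + one column per
#'   time point) and `archetype` (integer vector of planted labels).
#' @export
sim_profile_matrix <- function(n = 400,
                               timepoints = c("3hPE", "30hPE", "120hPE",
                                              "24hPBM", "48hPBM"),
                               n_archetypes = 4, noise_sd = 0.25, seed = 13) {
  with_seed(seed, {
    d <- length(timepoints)
    centers <- seq(1, d, length.out = n_archetypes)
    lab <- sample.int(n_archetypes, n, replace = TRUE)
    prof <- t(vapply(lab, function(k) {
      exp(-((seq_len(d) - centers[k])^2) / (2 * 0.6^2))
    }, numeric(d)))
    prof <- prof + matrix(rnorm(n * d, 0, noise_sd), n, d)
    m <- tibble::as_tibble(stats::setNames(as.data.frame(prof), timepoints))
    m <- dplyr::mutate(m, interaction_id = sprintf("I%04d", seq_len(n)),
                       .before = 1)
    list(matrix = m, archetype = lab)
  })
}

#' Synthetic log2 fold-change table with planted derepression
#'
#' @param n_targets,n_nontargets Set sizes.
#' @param shift Mean log2 fold-change added to targets.
#' @param sd Residual SD of log2 fold-changes.
#' @param seed RNG seed.
#' @return Tibble `transcript_id`, `log2fc`, `set_label`.
#' @export
sim_foldchange_table <- function(n_targets = 200, n_nontargets = 2000,
                                 shift = 0.5, sd = 1, seed = 1) {
  with_seed(seed, {
    tibble::tibble(
      transcript_id = sprintf("TX%05d", seq_len(n_targets + n_nontargets)),
      log2fc = c(rnorm(n_targets, shift, sd), rnorm(n_nontargets, 0, sd)),
      set_label = rep(c("target", "nontarget"), c(n_targets, n_nontargets)))
  })
}

#' Synthetic ribosome-footprint and mRNA count tables with a planted TE shift
#'
#' Counts are negative-binomial around log-normal transcript means; treatment
#' ribosome counts of target transcripts are multiplied by `te_fold`, and
#' whole-library scale factors are applied so size-factor normalization is
#' actually exercised.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_targets Number of transcripts with the planted TE change.
#' @param te_fold Fold change in translational efficiency for targets
#'   (treatment vs control).
#' @param seed RNG seed.
#' @return A list of tibbles `ribo` and `mrna` (columns `transcript_id`,
#'   `control_1`, `control_2`, `treated_1`, `treated_2`) plus `targets`.
#' @export
sim_ribo_counts <- function(n_transcripts = 2000, n_targets = 300,
                            te_fold = 2, seed = 1) {
  n_targets <- min(n_targets, n_transcripts)
  with_seed(seed, {
    ids <- sprintf("TX%05d", seq_len(n_transcripts))
    targets <- ids[seq_len(n_targets)]
    mu <- rlnorm(n_transcripts, log(200), 1)
    draw <- function(mu, scale = 1) {
      as.integer(stats::rnbinom(length(mu), mu = mu * scale, size = 20))
    }
    fold <- ifelse(ids %in% targets, te_fold, 1)
    ribo <- tibble::tibble(
      transcript_id = ids,
      control_1 = draw(mu), control_2 = draw(mu, 1.3),
      treated_1 = draw(mu * fold, 0.8), treated_2 = draw(mu * fold, 1.1))
    mrna <- tibble::tibble(
      transcript_id = ids,
      control_1 = draw(mu, 1.1), control_2 = draw(mu, 0.9),
      treated_1 = draw(mu), treated_2 = draw(mu, 1.2))
    list(ribo = ribo, mrna = mrna, targets = targets)
  })
}
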