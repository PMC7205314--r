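# End-to-end orchestration over a dataset directory (as written by
# sim_dataset() or assembled by hand): prep -> chimeras -> peaks ->
# interactions -> energetics -> motifs -> dynamics, with a reproducibility
# manifest.

read_reference_dir <- function(dir) {
  fa <- function(f) {
    x <- Biostrings::readDNAStringSet(file.path(dir, f))
    tibble::tibble(id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
  }
  tx <- fa("transcripts.fa") |>
    dplyr::rename(transcript_id = "id") |>
    dplyr::mutate(length = nchar(.data$sequence))
  mir <- fa("mirnas.fa") |> dplyr::rename(mirna_id = "id")
  ann <- readr::read_tsv(file.path(dir, "annotation.tsv"),
                         show_col_types = FALSE)
  list(transcripts = tx, mirnas = mir, annotation = ann)
}

#' Run the full analysis over a dataset directory
#'
#' Expects the layout written by [sim_dataset()]: `transcripts.fa`,
#' `mirnas.fa`, `annotation.tsv`, `expression.tsv` and one
#' `library_<timepoint>.fastq` per time point.  Runs preprocessing, chimera
#' calling, peak calling, interaction building with peak support, duplex
#' energetics with the shuffled null, seed-density and motif-usage analyses,
#' and the dynamics matrix with SOM and stage correlations.  All outputs are
#' TSV/JSON under `out_dir`; reruns with the same inputs and seed are
#' byte-identical.
#'
#' @param input_dir Dataset directory.
#' @param out_dir Output directory (created).
#' @param seed Global seed; per-stage seeds are stable offsets of it.
#' @param evalue_max,alpha,min_targets Key stage parameters.
#' @param mfe_flank Transcript flank (nt) for duplex scoring.
#' @param som_grid SOM grid (used when enough interactions are present).
#' @return Invisibly, a list with the main result tables.
#' @export
run_all <- function(input_dir, out_dir, seed = 1, evalue_max = 0.4,
                    alpha = 0.01, min_targets = 30, mfe_flank = 10,
                    som_grid = c(8, 8)) {
  if (!dir.exists(input_dir)) {
    abort(sprintf("input directory not found: %s", input_dir),
          class = "clearclipr_missing_input")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- read_reference_dir(input_dir)
  fq <- sort(list.files(input_dir, pattern = "^library_.*\\.fastq$",
                        full.names = TRUE))
  if (!length(fq)) {
    abort("no library_<timepoint>.fastq files found",
          class = "clearclipr_missing_input")
  }
  tps <- sub("^library_(.*)\\.fastq$", "\\1", basename(fq))
  chim_all <- list(); clip_all <- list(); class_all <- list()
  prep_stats <- list()
  for (i in seq_along(fq)) {
    prep <- prep_reads(fq[i])
    calls <- call_chimeras(prep$reads, ref$mirnas, ref$transcripts,
                           ref$annotation, evalue_max = evalue_max)
    chim_all[[i]] <- dplyr::mutate(calls$chimeras, timepoint = tps[i])
    clip_all[[i]] <- dplyr::mutate(calls$clip, timepoint = tps[i])
    class_all[[i]] <- dplyr::mutate(calls$classes, timepoint = tps[i])
    prep_stats[[tps[i]]] <- c(prep$stats, calls$stats)
  }
  chim <- dplyr::bind_rows(chim_all)
  clip <- dplyr::bind_rows(clip_all)
  readr::write_tsv(dplyr::select(chim, -dplyr::any_of("member_read_ids")),
                   file.path(out_dir, "chimeras.tsv"))
  readr::write_tsv(clip, file.path(out_dir, "clip_reads.tsv"))
  readr::write_tsv(dplyr::bind_rows(class_all),
                   file.path(out_dir, "read_classes.tsv"))

  peaks <- call_peaks(clip, chim, ref$transcripts, alpha = alpha)
  readr::write_tsv(peaks, file.path(out_dir, "peaks.tsv"))

  ints <- build_interactions(chim) |> attach_peak_support(peaks)
  readr::write_tsv(dplyr::mutate(ints, member_read_ids = vapply(
    .data$member_read_ids, paste, character(1), collapse = ",")),
    file.path(out_dir, "interactions.tsv"))

  # duplex energetics vs shuffled null
  energies <- NULL
  if (nrow(ints) >= 2 && length(unique(ints$mirna_id)) >= 2) {
    model <- default_energy_model()
    mir_seq <- stats::setNames(ref$mirnas$sequence, ref$mirnas$mirna_id)
    pairs <- tibble::tibble(
      interaction_id = ints$interaction_id,
      mirna_id = ints$mirna_id,
      mirna_seq = unname(mir_seq[ints$mirna_id]),
      target_seq = site_sequences(ints, ref$transcripts, mfe_flank))
    real <- duplex_energies(pairs, model)
    nullp <- shuffled_null(pairs, seed = seed + 11L)
    nullp$mirna_seq <- unname(mir_seq[nullp$mirna_id])
    nullr <- duplex_energies(nullp, model)
    gap <- energy_gap(real$mfe, nullr$mfe, n_perm = 10000, seed = seed + 12L)
    energies <- dplyr::select(real, "interaction_id", "mirna_id", "mfe",
                              "n_pairs")
    readr::write_tsv(energies, file.path(out_dir, "duplex_energies.tsv"))
    jsonlite::write_json(unclass(glance(gap)), file.path(out_dir,
                                                         "energy_gap.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # seed-match density and motif usage
  if (nrow(chim) >= 2 && length(unique(chim$mirna_id)) >= 2) {
    dens <- seed_match_density(chim, ref$mirnas, ref$transcripts,
                               shuffle_seed = seed + 21L)
    readr::write_tsv(dens, file.path(out_dir, "seed_density.tsv"))
    usage <- usage_by_timepoint(
      dplyr::select(chim, "mirna_id", "timepoint", "target_segment"),
      ref$mirnas, min_targets = min_targets, seed = seed + 22L)
    readr::write_tsv(usage$usage, file.path(out_dir, "motif_usage.tsv"))
    if (nrow(usage$motifs)) {
      readr::write_tsv(usage$motifs, file.path(out_dir, "motifs.tsv"))
    }
  }

  # dynamics
  expr_path <- file.path(input_dir, "expression.tsv")
  if (!file.exists(expr_path)) {
    abort(sprintf("expression table not found: %s", expr_path),
          class = "clearclipr_missing_input")
  }
  expression <- readr::read_tsv(expr_path, show_col_types = FALSE)
  mat <- normalize_matrix(ints, expression)
  readr::write_tsv(tibble::as_tibble(mat), file.path(out_dir, "matrix.tsv"))
  if (nrow(mat) >= 8) {
    z <- zscore_rows(mat)
    som <- som_fit(z, grid = som_grid, seed = seed + 31L)
    readr::write_tsv(som$tile_of, file.path(out_dir, "som_tiles.tsv"))
    sc <- stage_correlation(mat)
    readr::write_tsv(tibble::as_tibble(sc, rownames = "timepoint"),
                     file.path(out_dir, "stage_correlation.tsv"))
  }

  manifest <- list(
    input_dir = normalizePath(input_dir), seed = seed,
    parameters = list(evalue_max = evalue_max, alpha = alpha,
                      min_targets = min_targets, mfe_flank = mfe_flank,
                      som_grid = som_grid),
    timepoints = tps, stage_stats = prep_stats,
    package_version = as.character(utils::packageVersion("clearclipr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(chimeras = chim, clip = clip, peaks = peaks,
                 interactions = ints, energies = energies, matrix = mat,
                 manifest = manifest))
}
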