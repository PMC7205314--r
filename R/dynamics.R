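# Temporal dynamics of interactions: mRNA-normalized peak-height matrix,
# z-normalization, self-organizing-map gridding, stage correlations and
# hierarchical clustering of annotated subsets.

#' Join per-time-point interactions into a dynamics identity
#'
#' Interactions from different time points with the same miRNA and transcript
#' and overlapping site intervals receive one shared `interaction_id`.
#'
#' @param interactions Interaction table with `timepoint` column.
#' @return `interactions` with `interaction_id` replaced by the cross-time
#'   identity.
#' @export
join_interactions_across_timepoints <- function(interactions) {
  if (nrow(interactions) == 0) return(interactions)
  interactions |>
    dplyr::group_by(.data$mirna_id, .data$transcript_id) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$site_start + 1L, end = d$site_end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, red)
      grp <- integer(nrow(d))
      grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
      d$interaction_id <- sprintf("%s|%s|%d", key$mirna_id, key$transcript_id,
                                  IRanges::start(red)[grp] - 1L)
      d
    }) |>
    dplyr::ungroup()
}

#' Interaction-by-time-point matrix of mRNA-normalized peak heights
#'
#' Peak-supported interactions only; each cell is the supporting peak height
#' divided by the transcript's mRNA abundance at that time point (floored at
#' `floor` to avoid division blow-ups).  Interactions on transcripts missing
#' from the expression table are dropped (logged as an attribute); missing
#' time points give 0.
#'
#' @param interactions Interaction table with `timepoint`, `peak_supported`,
#'   `peak_height` (from [attach_peak_support()]).
#' @param expression Tibble `transcript_id`, `timepoint`, `abundance`.
#' @param floor Minimum abundance used as a denominator.
#' @param log_ratio Use `log2((height + 1) / abundance)` instead of the plain
#'   ratio.
#' @return Tibble of class `ccl_matrix`: `interaction_id`, `mirna_id`,
#'   `transcript_id`, then one numeric column per time point (ordered as the
#'   `timepoints` attribute).
#' @export
normalize_matrix <- function(interactions, expression, floor = 0.1,
                             log_ratio = FALSE) {
  x <- interactions[interactions$peak_supported, , drop = FALSE]
  x <- join_interactions_across_timepoints(x)
  tps <- unique(expression$timepoint)
  covered <- x$transcript_id %in% expression$transcript_id
  dropped <- unique(x$transcript_id[!covered])
  x <- x[covered, , drop = FALSE]
  long <- x |>
    dplyr::left_join(expression, by = c("transcript_id", "timepoint")) |>
    dplyr::mutate(value = if (log_ratio) {
      log2((.data$peak_height + 1) / pmax(.data$abundance, floor))
    } else {
      .data$peak_height / pmax(.data$abundance, floor)
    }) |>
    dplyr::group_by(.data$interaction_id, .data$mirna_id, .data$transcript_id,
                    .data$timepoint) |>
    dplyr::summarise(value = max(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "timepoint",
                             values_from = "value", values_fill = 0)
  for (tp in setdiff(tps, names(wide))) wide[[tp]] <- 0
  wide <- wide[, c("interaction_id", "mirna_id", "transcript_id", tps)]
  wide <- dplyr::arrange(wide, .data$interaction_id)
  attr(wide, "timepoints") <- tps
  attr(wide, "dropped_transcripts") <- dropped
  class(wide) <- c("ccl_matrix", class(wide))
  wide
}

matrix_values <- function(mat, timepoints = NULL) {
  tps <- timepoints %||% attr(mat, "timepoints") %||%
    setdiff(names(mat), c("interaction_id", "mirna_id", "transcript_id"))
  m <- as.matrix(mat[, tps])
  rownames(m) <- if ("interaction_id" %in% names(mat)) mat$interaction_id else as.character(seq_len(nrow(m)))
  m
}

#' Row-wise z-normalization
#'
#' Subtracts the row mean and divides by the row SD; constant rows become
#' all-zero.
#'
#' @param mat A `ccl_matrix` tibble or a plain numeric matrix.
#' @return Same shape as the input.
#' @export
zscore_rows <- function(mat) {
  is_tbl <- is.data.frame(mat)
  m <- if (is_tbl) matrix_values(mat) else mat
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s < 1e-12, 1, s)
  z[abs(s) < 1e-12, ] <- 0
  if (!is_tbl) return(z)
  out <- mat
  out[, colnames(m)] <- tibble::as_tibble(z)
  out
}

#' Fit a self-organizing map to temporal interaction profiles
#'
#' Batch Kohonen SOM on the row profiles: codebook seeded from random rows,
#' Gaussian neighborhood whose radius decays linearly from 3/4 of the grid
#' span to 2/5 of it (floored at 1), learning rate decaying linearly over a
#' fixed number of epochs, best-matching-unit tile assignment.  The final
#' radius is kept proportional to the grid so that interactions sharing a
#' temporal program settle in a compact tile neighborhood instead of
#' spreading over the whole map.  Fully deterministic under the seed.
#'
#' @param mat A `ccl_matrix` tibble or numeric matrix (rows = interactions).
#' @param grid `c(rows, cols)` of the tile grid.
#' @param epochs Training epochs.
#' @param lr Initial learning rate (decays linearly to `lr/10`).
#' @param radius `c(initial, final)` neighborhood radii; defaults to
#'   `c(0.75, 0.4) * max(grid)` (final floored at 1).
#' @param seed RNG seed.
#' @return A list of class `ccl_som`: `grid`, `tile_of` (tibble
#'   `interaction_id`, `tile`, `tile_row`, `tile_col`), `codebook`
#'   (tiles x time points), `tile_mean` (observed mean profile per tile),
#'   `quantization_error`, `seed`.
#' @export
som_fit <- function(mat, grid = c(8, 8), epochs = 50, lr = 0.5,
                    radius = NULL, seed = 1) {
  m <- if (is.data.frame(mat)) matrix_values(mat) else mat
  n <- nrow(m); d <- ncol(m)
  if (n == 0) abort("empty matrix")
  u <- grid[1] * grid[2]
  if (u < 4) abort("grid must have at least 4 tiles")
  if (u > 10 * n) warn("grid has more than 10x as many tiles as rows (sparse map)")
  coords <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                  rep(seq_len(grid[2]), each = grid[1]))
  ud <- as.matrix(dist(coords))  # inter-tile grid distances
  radius <- radius %||% c(0.75 * max(grid), max(1, 0.4 * max(grid)))
  r0 <- radius[1]; rf <- radius[2]
  with_seed(seed, {
    init <- m[sample.int(n, u, replace = n < u), , drop = FALSE]
    code <- init
    for (e in seq_len(epochs)) {
      frac <- if (epochs > 1) (e - 1) / (epochs - 1) else 0
      radius_e <- rf + (r0 - rf) * (1 - frac)
      rate <- lr * (1 - 0.9 * frac)
      d2 <- outer(rowSums(m^2), rowSums(code^2), "+") - 2 * m %*% t(code)
      bmu <- max.col(-d2, ties.method = "first")
      h <- exp(-(ud^2) / (2 * radius_e^2))  # tiles x tiles
      w <- h[bmu, , drop = FALSE]         # rows x tiles
      denom <- colSums(w)
      target <- t(w) %*% m / ifelse(denom < 1e-12, 1, denom)
      upd <- denom > 1e-12
      code[upd, ] <- code[upd, ] + rate * (target[upd, , drop = FALSE] -
                                             code[upd, , drop = FALSE])
    }
    d2 <- outer(rowSums(m^2), rowSums(code^2), "+") - 2 * m %*% t(code)
    bmu <- max.col(-d2, ties.method = "first")
    qe <- mean(sqrt(pmax(d2[cbind(seq_len(n), bmu)], 0)))
    tile_mean <- code
    for (t in seq_len(u)) {
      i <- which(bmu == t)
      if (length(i)) tile_mean[t, ] <- colMeans(m[i, , drop = FALSE])
    }
    structure(list(
      grid = grid,
      tile_of = tibble::tibble(interaction_id = rownames(m) %||%
                                 as.character(seq_len(n)),
                               tile = bmu,
                               tile_row = coords[bmu, 1],
                               tile_col = coords[bmu, 2]),
      codebook = code, tile_mean = tile_mean, tile_coords = coords,
      quantization_error = qe, epochs = epochs, seed = seed),
      class = "ccl_som")
  })
}

#' Topographic statistic of a SOM fit
#'
#' Ratio of the mean profile distance between grid-adjacent tiles to the mean
#' distance between random tile pairs; values below 1 indicate the expected
#' topology preservation.
#'
#' @param som A `ccl_som` object.
#' @return Named numeric: `adjacent`, `random`, `ratio`.
#' @export
som_topographic_stat <- function(som) {
  ud <- as.matrix(dist(som$tile_coords))
  pd <- as.matrix(dist(som$codebook))
  adj <- pd[ud > 0 & ud < 1.5]
  rnd <- pd[ud > 0]
  c(adjacent = mean(adj), random = mean(rnd), ratio = mean(adj) / mean(rnd))
}

#' Pearson correlation between time points
#'
#' @param mat A `ccl_matrix` tibble or numeric matrix.
#' @return Symmetric correlation matrix (time points x time points); columns
#'   with zero variance give NA entries.
#' @export
stage_correlation <- function(mat) {
  m <- if (is.data.frame(mat)) matrix_values(mat) else mat
  if (nrow(m) < 2) abort("need at least 2 rows")
  v <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  r[v < 1e-12, ] <- NA
  r[, v < 1e-12] <- NA
  diag(r) <- ifelse(v < 1e-12, NA, 1)
  r
}

#' Hierarchical clustering of interaction profiles
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' z-normalized rows, optionally restricted to a user-supplied category.
#' Rows are sorted by id before clustering so the result is invariant to
#' input order.
#'
#' @param mat A `ccl_matrix` tibble.
#' @param categories Optional tibble `transcript_id`, `category`.
#' @param category Category to keep (required when `categories` given).
#' @param linkage Agglomeration method.
#' @return A list of class `ccl_hclust`: `hclust`, `leaf_order` (interaction
#'   ids) and `ids`.
#' @export
hcluster_profiles <- function(mat, categories = NULL, category = NULL,
                              linkage = "average") {
  x <- mat
  if (!is.null(categories)) {
    keep <- categories$transcript_id[is.null(category) |
                                       categories$category == category]
    x <- x[x$transcript_id %in% keep, , drop = FALSE]
  }
  x <- dplyr::arrange(x, .data$interaction_id)
  m <- matrix_values(x)
  if (nrow(m) < 2) {
    return(structure(list(hclust = NULL, leaf_order = rownames(m),
                          ids = rownames(m)), class = "ccl_hclust"))
  }
  z <- zscore_rows(m)
  hc <- hclust(dist(z), method = linkage)
  structure(list(hclust = hc, leaf_order = rownames(m)[hc$order],
                 ids = rownames(m)), class = "ccl_hclust")
}

#' Export a dendrogram in Newick format
#'
#' @param x A `ccl_hclust` object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(x, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("package 'ape' is required for Newick export")
  }
  if (is.null(x$hclust)) {
    writeLines(paste0("(", paste(x$ids, collapse = ","), ");"), path)
  } else {
    ape::write.tree(ape::as.phylo(x$hclust), file = path)
  }
  invisible(path)
}

#' Cut SOM tiles into discrete temporal programs
#'
#' k-medoids clustering of tile mean profiles, occupancy-weighted: each
#' interaction is represented by its tile's mean profile, so heavily occupied
#' tiles dominate the medoids and sparse boundary tiles cannot distort the
#' cut.
#'
#' @param som A `ccl_som` object.
#' @param k Number of programs.
#' @return Tibble `interaction_id`, `tile`, `program`.
#' @export
som_program_cut <- function(som, k) {
  if (!requireNamespace("cluster", quietly = TRUE)) {
    abort("package 'cluster' is required for som_program_cut")
  }
  x <- som$tile_mean[som$tile_of$tile, , drop = FALSE]
  km <- cluster::pam(x, k = k, pamonce = 5)
  tibble::tibble(interaction_id = som$tile_of$interaction_id,
                 tile = som$tile_of$tile,
                 program = as.integer(km$clustering))
}
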