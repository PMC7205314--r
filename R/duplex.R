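# Intermolecular miRNA:target duplex stability: nearest-neighbor minimum free
# energy by dynamic programming, an exhaustive reference implementation, a
# shuffled-reassignment null, and the real-vs-null energy gap.

#' Nearest-neighbor energy model for RNA/RNA duplexes
#'
#' Loads the stacking free-energy table shipped with the package (Watson-Crick
#' block from the standard 37 degC nearest-neighbor set; G:U wobble stacks use
#' a simplified uniform parameterization) together with bulge/internal-loop
#' penalties, duplex initiation and terminal AU/GU penalties.
#'
#' @param stack_file TSV with columns `pair5`, `pair3`, `dG` (kcal/mol);
#'   pair names are miRNA-base first (e.g. `GU` is miRNA G paired to target U).
#' @param init_dG Duplex initiation penalty (kcal/mol).
#' @param au_end_dG Terminal AU/GU penalty (kcal/mol), applied at each helix
#'   end.
#' @param max_loop Maximum unpaired bases in a bulge/internal loop.
#' @return A list of class `ccl_energy_model`: `stack` (6x6 matrix over pair
#'   types AU, UA, CG, GC, GU, UG), `bulge`, `internal` (penalty by total
#'   loop length), `init_dG`, `au_end_dG`, `max_loop`.
#' @export
default_energy_model <- function(stack_file = system.file("extdata",
                                                          "rna_stack_dg.tsv",
                                                          package = "clearclipr"),
                                 init_dG = 4.09, au_end_dG = 0.45,
                                 max_loop = 15) {
  tab <- readr::read_tsv(stack_file, show_col_types = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(match(tab$pair5, pairs), match(tab$pair3, pairs))] <- tab$dG
  if (anyNA(stack)) abort("incomplete stacking table")
  bulge <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.6, 4.7, 4.8, 4.9, 5.0, 5.1,
             5.2, 5.3, 5.4)
  internal <- c(3.0, 1.5, 1.8, 2.0, 2.2, 2.5, 2.7, 2.9, 3.1, 3.3, 3.5, 3.6,
                3.7, 3.8, 3.9)
  len <- max(max_loop, 15)
  structure(list(stack = stack,
                 bulge = c(bulge, rep(5.4, len))[seq_len(len)],
                 internal = c(internal, rep(3.9, len))[seq_len(len)],
                 init_dG = init_dG, au_end_dG = au_end_dG,
                 max_loop = as.integer(max_loop)),
            class = "ccl_energy_model")
}

seq_to_code <- function(x) {
  v <- utf8ToInt(as_rna(x))
  code <- match(v, utf8ToInt("ACGU")) - 1L
  if (anyNA(code)) abort("sequences must be over {A,C,G,U} (or DNA T)")
  code
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Dynamic program over all non-crossing intermolecular pairings (miRNA read
#' 5'->3', target 3'->5') with nearest-neighbor stacking, bulge/internal-loop
#' penalties bounded by `max_loop`, duplex initiation and terminal AU/GU
#' penalties.  Ties are broken towards more paired bases, then the leftmost
#' pairing.  A duplex whose optimum is above 0 kcal/mol is reported unstable
#' (sentinel: `mfe = 0`, empty pairing).
#'
#' @param mirna,target RNA (or DNA) sequences, lengths >= 2.
#' @param model A [default_energy_model()].
#' @return A list of class `ccl_duplex`: `mfe` (kcal/mol) and `pairing`
#'   (tibble of 0-based `mirna_pos`, `target_pos`).
#' @export
duplex_mfe <- function(mirna, target, model = default_energy_model()) {
  m <- seq_to_code(mirna); t <- seq_to_code(target)
  if (length(m) < 2 || length(t) < 2) abort("sequences must have length >= 2")
  r <- cpp_duplex_mfe(m, t, model$stack, model$bulge, model$internal,
                      model$init_dG, model$au_end_dG, model$max_loop)
  structure(list(mfe = r$mfe,
                 pairing = tibble::tibble(mirna_pos = r$mirna_pos,
                                          target_pos = r$target_pos)),
            class = "ccl_duplex")
}

#' @export
print.ccl_duplex <- function(x, ...) {
  cat(sprintf("duplex: %d pairs, MFE %.2f kcal/mol\n", nrow(x$pairing), x$mfe))
  invisible(x)
}

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

pair_type_chr <- function(a, b) match(paste0(a, b), PAIR_TYPES) - 1L

duplex_pair_matrix <- function(mirna, target) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  t <- rev(strsplit(as_rna(target), "")[[1]])  # walk target 3'->5'
  outer(seq_along(m), seq_along(t),
        Vectorize(function(i, j) {
          p <- pair_type_chr(m[i], t[j]); if (is.na(p)) -1L else p
        }))
}

duplex_end_pen <- function(p, model) {
  if (p %in% c(0, 1, 4, 5)) model$au_end_dG else 0
}

#' Reference duplex MFE (independent pure-R implementation)
#'
#' Top-down memoized recursion over "first pair, then continuation" under the
#' same energy model; written independently of the compiled bottom-up program
#' and used to validate it.  Its own correctness is checked against
#' exhaustive enumeration of all non-crossing pairings (internal
#' `duplex_enum_mfe`) on very short sequences.
#'
#' @inheritParams duplex_mfe
#' @return The minimum free energy (kcal/mol), with the same unstable
#'   sentinel (0) as [duplex_mfe()].
#' @export
duplex_mfe_reference <- function(mirna, target, model = default_energy_model()) {
  pt <- duplex_pair_matrix(mirna, target)
  n <- nrow(pt); nt <- ncol(pt)
  memo <- matrix(NA_real_, n, nt)
  # h(i, j): minimal energy from pair (i, j) onward, closing terminal penalty
  # included at termination.
  h <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- duplex_end_pen(pt[i, j], model)  # terminate helix here
    for (ii in seq(i + 1, min(n, i + 1 + model$max_loop))) {
      if (ii > n) break
      for (jj in seq(j + 1, min(nt, j + 1 + model$max_loop))) {
        if (jj > nt) break
        p <- pt[ii, jj]
        if (p < 0) next
        a <- ii - i - 1; b <- jj - j - 1
        if (a + b > model$max_loop) next
        step <- if (a == 0 && b == 0) model$stack[pt[i, j] + 1, p + 1]
        else if (a == 0 || b == 0) model$bulge[a + b]
        else model$internal[a + b]
        v <- step + h(ii, jj)
        if (v < best) best <- v
      }
    }
    memo[i, j] <<- best
    best
  }
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(nt)) {
    if (pt[i, j] >= 0) {
      v <- model$init_dG + duplex_end_pen(pt[i, j], model) + h(i, j)
      if (v < best) best <- v
    }
  }
  if (!is.finite(best) || best > 0) 0 else best
}

# Exhaustive enumeration over every non-crossing pairing; exponential, used
# only to validate duplex_mfe_reference on very short inputs.
duplex_enum_mfe <- function(mirna, target, model = default_energy_model()) {
  pt <- duplex_pair_matrix(mirna, target)
  n <- nrow(pt); nt <- ncol(pt)
  best <- Inf
  rec <- function(i, j, e, last_p) {
    total <- e + duplex_end_pen(last_p, model) + model$init_dG
    if (total < best) best <<- total
    if (i > n || j > nt) return()
    for (ii in i:n) for (jj in j:nt) {
      p <- pt[ii, jj]
      if (p < 0) next
      a <- ii - i; b <- jj - j
      if (a + b > model$max_loop) next
      step <- if (a == 0 && b == 0) model$stack[last_p + 1, p + 1]
      else if (a == 0 || b == 0) model$bulge[a + b]
      else model$internal[a + b]
      rec(ii + 1, jj + 1, e + step, p)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(nt)) {
    if (pt[i, j] >= 0) rec(i + 1, j + 1, duplex_end_pen(pt[i, j], model), pt[i, j])
  }
  if (!is.finite(best) || best > 0) 0 else best
}

#' Minimum free energies for a table of miRNA-target pairs
#'
#' @param pairs Tibble with `mirna_seq`, `target_seq`.
#' @param model A [default_energy_model()].
#' @return `pairs` with `mfe` and `n_pairs` columns.
#' @export
duplex_energies <- function(pairs, model = default_energy_model()) {
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    duplex_mfe(pairs$mirna_seq[i], pairs$target_seq[i], model)
  })
  pairs$mfe <- vapply(res, function(r) r$mfe, numeric(1))
  pairs$n_pairs <- vapply(res, function(r) nrow(r$pairing), integer(1))
  pairs
}

#' Extract target site sequences with transcript flanks
#'
#' @param interactions Tibble with `transcript_id`, `site_start`, `site_end`.
#' @param transcripts Tibble with `transcript_id`, `sequence`.
#' @param flank Flank (nt) added on each side, bounded by transcript ends.
#' @return Character vector of site sequences.
#' @export
site_sequences <- function(interactions, transcripts, flank = 10) {
  seqs <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
  vapply(seq_len(nrow(interactions)), function(i) {
    s <- seqs[[interactions$transcript_id[i]]]
    substr(s, max(1L, interactions$site_start[i] + 1L - flank),
           min(nchar(s), interactions$site_end[i] + flank))
  }, character(1))
}

#' Randomly reassign each target to a different miRNA (shuffled null)
#'
#' Derangement-style control: every target keeps its sequence but receives a
#' miRNA whose identity differs from its own, uniformly at random and
#' deterministic under the seed.
#'
#' @param interactions Tibble with `mirna_id` (and any target columns).
#' @param seed RNG seed.
#' @param max_iter Resampling bound for resolving residual self-assignments.
#' @return `interactions` with `mirna_id` replaced by the reassigned miRNA
#'   (original kept as `mirna_id_original`).
#' @export
shuffled_null <- function(interactions, seed = 1, max_iter = 1000) {
  ids <- interactions$mirna_id
  if (length(unique(ids)) < 2) {
    abort("shuffled_null needs >= 2 distinct miRNAs",
          class = "clearclipr_config_error")
  }
  n <- length(ids)
  with_seed(seed, {
    perm <- sample.int(n)
    for (it in seq_len(max_iter)) {
      bad <- which(ids[perm] == ids)
      if (!length(bad)) break
      if (length(bad) == 1) {
        j <- sample(setdiff(seq_len(n), bad), 1)
        perm[c(bad, j)] <- perm[c(j, bad)]
      } else {
        perm[bad] <- perm[sample(bad)]
      }
    }
    bad <- which(ids[perm] == ids)
    # resolve stragglers by pairwise swaps with compatible positions
    for (b in bad) {
      ok <- which(ids[perm] != ids[b] & ids[perm[b]] != ids)
      ok <- setdiff(ok, b)
      if (length(ok)) {
        j <- ok[sample.int(length(ok), 1)]
        perm[c(b, j)] <- perm[c(j, b)]
      }
    }
    out <- interactions
    out$mirna_id_original <- ids
    out$mirna_id <- ids[perm]
    out
  })
}

#' Energy gap between real and shuffled interactions
#'
#' Difference in median and mean minimum free energy between the real
#' assignments and the shuffled null, with a label-permutation p-value for
#' the mean difference.
#'
#' @param real,null Numeric vectors of MFEs (kcal/mol).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return A list of class `ccl_energy_gap`: `delta_median`, `delta_mean`,
#'   `p_mean` (two-sided), `n_real`, `n_null`, `n_perm`.
#' @export
energy_gap <- function(real, null, n_perm = 10000, seed = 1) {
  if (!length(real) || !length(null)) abort("both samples must be nonempty")
  d_med <- median(real) - median(null)
  d_mean <- mean(real) - mean(null)
  pool <- c(real, null)
  n1 <- length(real)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) {
      i <- sample.int(length(pool), n1)
      mean(pool[i]) - mean(pool[-i])
    }, numeric(1))
    p <- (sum(abs(perm) >= abs(d_mean)) + 1) / (n_perm + 1)
  })
  structure(list(delta_median = d_med, delta_mean = d_mean, p_mean = p,
                 n_real = length(real), n_null = length(null),
                 n_perm = n_perm),
            class = "ccl_energy_gap")
}
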