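# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small simulated dataset + one prepared/classified library.
small_run <- function() {
  cached("small_run", {
    cfg <- sim_config(n_transcripts = 120, n_ncrna = 10, n_mirnas = 25,
                      n_interactions = 120, n_reads = 6000, rng_seed = 11)
    ref <- sim_reference(cfg)
    truth <- sim_plant_interactions(ref, cfg)
    lib <- sim_library(truth, "120hPE", cfg)
    prep <- prep_reads(lib$reads)
    calls <- call_chimeras(prep$reads, truth$reference$mirnas,
                           truth$reference$transcripts,
                           truth$reference$annotation)
    list(cfg = cfg, truth = truth, lib = lib, prep = prep, calls = calls)
  })
}

# Random DNA helper with independent implementation (no package internals).
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Independent reverse complement via Biostrings.
rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

read_tbl <- function(seqs, quality = NULL, prefix = "r") {
  tibble::tibble(
    read_id = sprintf("%s%04d", prefix, seq_along(seqs)),
    sequence = seqs,
    quality = quality %||% vapply(nchar(seqs), function(l)
      paste(rep("F", l), collapse = ""), character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
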