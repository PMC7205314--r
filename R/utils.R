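# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of DNA strings (vectorized).
rc_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Accept RNA or DNA spelling; internal representation is DNA (T).
as_dna <- function(x) chartr("U", "T", toupper(x))

as_rna <- function(x) chartr("T", "U", toupper(x))

# One random DNA string per element of `len`.
random_dna <- function(len, prob = rep(0.25, 4)) {
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

check_proportions <- function(p, what, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must be nonnegative and sum to 1 (got sum %.12f)",
                  what, sum(p)), class = "clearclipr_config_error")
  }
  invisible(p)
}

# All k-mers of a string, in order.
kmers_of <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

# Apply substitution errors at per-base rate; substitutions are uniform over
# the three alternative bases.
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  vapply(x, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

phred_string <- function(len, phred = 37L) {
  vapply(len, function(l) {
    paste(rep(rawToChar(as.raw(phred + 33L)), l), collapse = "")
  }, character(1))
}

mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (!nchar(q)) return(0)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}
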