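# internal helpers shared across modules

.DNA_ALPHABET <- c("A", "C", "G", "T")

# single uppercase ACGT string; ambiguity codes (incl. N) are rejected
assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains characters outside A/C/G/T (N and other ambiguity codes are rejected)",
         call. = FALSE)
  seq
}

random_dna <- function(n) {
  paste(sample(.DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# presentation rounding: half-up (Table-style), not banker's
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# all k-mers of a string, in order; empty if shorter than k
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# 0-based half-open circular extraction; end0 may run past the sequence end (wraps once)
circ_substr <- function(seq, start0, end0) {
  L <- nchar(seq)
  stopifnot(all(start0 >= 0), all(start0 < L), all(end0 >= start0), all(end0 - start0 <= L))
  substring(paste0(seq, seq), start0 + 1L, end0)
}

# run code under a temporary RNG state; NULL seed leaves the global stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# most frequent value (ties -> smallest); NAs dropped
int_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}
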