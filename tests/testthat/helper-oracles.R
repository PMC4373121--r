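# Independent oracles: plain string manipulation and textbook formulas,
# sharing no code with the package's integer-coded counting path.

oracle_string_reverse <- function(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))

oracle_revcomp <- function(x)
  oracle_string_reverse(chartr("ACGT", "TGCA", x))

oracle_equivalent <- function(kmer, alphabet) {
  if (alphabet == "base") oracle_revcomp(kmer)
  else oracle_string_reverse(kmer)
}

oracle_canonical <- function(kmer, alphabet)
  pmin(kmer, oracle_equivalent(kmer, alphabet))

# tally canonical k-mers of a character vector of reads in a plain named
# vector; windows containing an ambiguous symbol are skipped
oracle_count <- function(symbols, k, alphabet = "base") {
  ambiguous <- if (alphabet == "base") "N" else "."
  tally <- c()
  for (s in symbols) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1), k:n)
    w <- w[!grepl(ambiguous, w, fixed = TRUE)]
    if (!length(w)) next
    cw <- oracle_canonical(w, alphabet)
    t <- table(cw)
    for (lab in names(t))
      tally[lab] <- (if (lab %in% names(tally)) tally[[lab]] else 0) + t[[lab]]
  }
  tally
}

# profile counts as a named vector restricted to non-zero bins
profile_nonzero <- function(profile) {
  v <- profile$counts
  names(v) <- profile$space$bin_label
  v[v > 0]
}

oracle_entropy <- function(counts, n_classes = length(counts)) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(n_classes)
}

# Spearman for tie-free vectors via the classical d^2 formula
oracle_spearman <- function(a, b) {
  n <- length(a)
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

random_read_strings <- function(n_reads, max_len, alphabet = "base",
                                p_ambiguous = 0) {
  syms <- if (alphabet == "base") c("A", "C", "G", "T") else
    c("0", "1", "2", "3")
  amb <- if (alphabet == "base") "N" else "."
  vapply(seq_len(n_reads), function(i) {
    len <- sample(1:max_len, 1)
    ch <- sample(syms, len, replace = TRUE)
    if (p_ambiguous > 0) {
      hit <- runif(len) < p_ambiguous
      ch[hit] <- amb
    }
    paste(ch, collapse = "")
  }, character(1))
}

# small deterministic profile fixture
toy_profile <- function(counts, k = 4, alphabet = "base", id = "toy") {
  sp <- kmer_space(k, alphabet)
  stopifnot(length(counts) == sp$n_bins)
  kmer_profile(sp, counts, id)
}
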