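# Canonical k-mer space: every length-k string over the 4-symbol alphabet is
# assigned to one bin, merging each k-mer with its strand-equivalent partner
# (reverse complement in base space; plain reversal in colour space, since
# SOLiD colours are complement-invariant). Internally a k-mer is the base-4
# integer code of its symbols (A/0 = 0 ... T/3 = 3, first symbol most
# significant), so the numeric order of codes is the lexicographic order of
# the strings.

.code_to_string <- function(code, k, alphabet) {
  syms <- if (alphabet == "base") c("A", "C", "G", "T") else
    c("0", "1", "2", "3")
  out <- matrix("", nrow = length(code), ncol = k)
  for (j in k:1) {
    out[, j] <- syms[code %% 4 + 1]
    code <- code %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

# digit-reversed code; complement digits too when complement = TRUE
.equiv_code <- function(code, k, complement) {
  out <- numeric(length(code))
  x <- code
  for (j in seq_len(k)) {
    d <- x %% 4
    if (complement) d <- 3 - d
    out <- out * 4 + d
    x <- x %/% 4
  }
  out
}

#' Build a canonical k-mer space
#'
#' Enumerates all `4^k` k-mers over the chosen alphabet and groups each with
#' its strand-equivalent partner: the reverse complement for base-space
#' sequences, the plain reversal for colour-space (SOLiD) sequences, where
#' the colour encoding is invariant under complementation. Each equivalence
#' class is one bin, labelled by its lexicographically smallest member.
#'
#' For the base alphabet the number of bins is `(4^k + P) / 2` with
#' `P = 4^(k/2)` self-reverse-complementary (palindromic) k-mers when `k` is
#' even and `P = 0` otherwise; `k = 4` gives the 136 canonical
#' tetranucleotide classes.
#'
#' @param k word length, an integer in 1..12 (the method targets small k;
#'   default 4).
#' @param alphabet `"base"` or `"colour"`.
#' @return An object of class `kmer_space` with fields `k`, `alphabet`,
#'   `n_bins`, `bin_label` (character vector of canonical k-mers) and an
#'   internal code-to-bin lookup.
#' @examples
#' sp <- kmer_space(4)
#' sp$n_bins  # 136
#' @export
kmer_space <- function(k = 4L, alphabet = c("base", "colour")) {
  alphabet <- match.arg(alphabet)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 12L)
    stop("k must be an integer between 1 and 12")
  codes <- seq_len(4^k) - 1
  equiv <- .equiv_code(codes, k, complement = alphabet == "base")
  canon <- pmin(codes, equiv)
  ucanon <- sort(unique(canon))
  bin_of_code <- match(canon, ucanon)
  structure(list(k = k, alphabet = alphabet,
                 n_bins = length(ucanon),
                 bin_label = .code_to_string(ucanon, k, alphabet),
                 bin_of_code = bin_of_code),
            class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("kmer_space: k=%d, %s alphabet, %d canonical bins\n",
              x$k, x$alphabet, x$n_bins))
  invisible(x)
}

.same_space <- function(a, b) {
  a$k == b$k && a$alphabet == b$alphabet && a$n_bins == b$n_bins
}

# symbol -> base-4 digit lookup over raw char codes; NA for anything else
.digit_lookup <- function(alphabet) {
  lut <- rep(NA_real_, 256L)
  if (alphabet == "base") {
    lut[utf8ToInt("A")] <- 0
    lut[utf8ToInt("C")] <- 1
    lut[utf8ToInt("G")] <- 2
    lut[utf8ToInt("T")] <- 3
  } else {
    lut[utf8ToInt("0")] <- 0
    lut[utf8ToInt("1")] <- 1
    lut[utf8ToInt("2")] <- 2
    lut[utf8ToInt("3")] <- 3
  }
  lut
}

#' Map a k-mer to its canonical bin
#'
#' Returns the bin index (1-based) of a k-mer, identical for a k-mer and its
#' strand-equivalent partner (reverse complement in base space, reversal in
#' colour space). Vectorised over `kmer`.
#'
#' @param kmer character vector of length-`k` strings over the space's
#'   alphabet; ambiguous symbols (`N`, `.`) are not allowed here.
#' @param space a [kmer_space()].
#' @return Integer vector of bin indices in `1..space$n_bins`.
#' @examples
#' sp <- kmer_space(4)
#' canonical_bin("ATTC", sp) == canonical_bin("GAAT", sp)
#' @export
canonical_bin <- function(kmer, space) {
  stopifnot(inherits(space, "kmer_space"))
  if (any(nchar(kmer) != space$k))
    stop("k-mer length must equal k = ", space$k)
  lut <- .digit_lookup(space$alphabet)
  code <- vapply(kmer, function(s) {
    d <- lut[utf8ToInt(s)]
    if (anyNA(d))
      stop("k-mer '", s, "' contains an invalid or ambiguous symbol")
    sum(d * 4^((space$k - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
  space$bin_of_code[code + 1]
}
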